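#' Scorer configuration
#'
#' Hyperparameters of the dual-channel hyperedge scorer.  The separating
#' channel looks at each candidate tuple in isolation (multi-head
#' self-attention plus a per-vertex MLP, aligned by a KL loss); the coupling
#' channel propagates vertex features through the shared hyperedges by
#' degree-normalized hypergraph convolution.  Both are fused per vertex and
#' the per-vertex sigmoid scores are averaged into the tuple probability.
#'
#' @param d embedding dimension (must match the encoder output; default 64).
#' @param n_heads attention heads (`d` must be divisible by it).
#' @param dropout dropout rate on the MLP hidden layers and the fusion
#'   layer, used only during training.
#' @param lambda_kl weight of the KL alignment loss.
#' @param slope negative slope of the leaky rectifier in the convolution.
#' @param use_she,use_che enable the separating / coupling channel.  The
#'   ablation variants are `use_she = FALSE` ("noSHE") and
#'   `use_che = FALSE` ("noCHE").
#' @param merge how the attention and MLP embeddings combine into the
#'   discrete embedding `D`: elementwise `"mean"` (default) or `"concat"`.
#' @param hconv_layers number of convolution layers (default 3).
#' @param max_order tuples are padded to this many slots (default 6).
#' @return object of class `mci_config`.
#' @export
mci_config <- function(d = 64L, n_heads = 4L, dropout = 0.4,
                       lambda_kl = 1.0, slope = 0.01,
                       use_she = TRUE, use_che = TRUE,
                       merge = c("mean", "concat"),
                       hconv_layers = 3L, max_order = 6L) {
  merge <- match.arg(merge)
  if (d %% n_heads != 0L) stop("d must be divisible by n_heads")
  if (!use_she && !use_che) stop("at least one channel must be enabled")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  dD <- if (merge == "mean") d else 2L * d
  structure(list(d = as.integer(d), n_heads = as.integer(n_heads),
                 head_dim = as.integer(d / n_heads), dropout = dropout,
                 lambda_kl = lambda_kl, slope = slope,
                 use_she = use_she, use_che = use_che, merge = merge,
                 hconv_layers = as.integer(hconv_layers),
                 max_order = as.integer(max_order),
                 d_fuse_in = (if (use_she) dD else 0L) +
                             (if (use_che) d else 0L)),
            class = "mci_config")
}

#' Initialize scorer parameters
#' @param cfg an [mci_config].
#' @param seed RNG seed for the Glorot-uniform initialization.
#' @return named list of parameter arrays (class `mci_params`).
#' @export
mci_init <- function(cfg, seed = 1L) {
  set.seed(seed)
  d <- cfg$d
  p <- list()
  if (cfg$use_she) {
    p$Wq <- .glorot(d, d); p$Wk <- .glorot(d, d); p$Wv <- .glorot(d, d)
    p$Wo <- .glorot(d, d)
    p$W1 <- .glorot(d, d); p$b1 <- numeric(d)
    p$W2 <- .glorot(d, d); p$b2 <- numeric(d)
    p$W3 <- .glorot(d, d); p$b3 <- numeric(d)
  }
  if (cfg$use_che)
    for (t in seq_len(cfg$hconv_layers))
      p[[paste0("Wt", t)]] <- .glorot(d, d)
  p$Wf <- .glorot(cfg$d_fuse_in, d); p$bf <- numeric(d)
  p$ws <- .glorot(d, 1L); p$bs <- 0
  structure(p, class = "mci_params")
}

#' Pad labeled samples into a tuple batch
#'
#' Tuples of order 3..`max_order` are padded to `max_order` slots; the mask
#' marks real vertices and padded slots contribute to no sum, softmax or
#' average anywhere downstream.
#'
#' @param samples a `labeled_samples` data.frame (or any data.frame with a
#'   `bins` list column and optionally `label`).
#' @param emb N x d matrix of vertex embeddings `f(x)`.
#' @param max_order padded tuple length.
#' @return object of class `tuple_batch`: list with `Xs` (list of
#'   `max_order` B x d matrices), `mask` (B x max_order), `vid`
#'   (B x max_order, 1-based vertex ids; padded slots hold 1), `labels`,
#'   `l` (real slots per tuple) and `B`.
#' @export
build_batch <- function(samples, emb, max_order = 6L) {
  B <- nrow(samples)
  vid <- matrix(1L, B, max_order)
  mask <- matrix(0, B, max_order)
  for (b in seq_len(B)) {
    tp <- samples$bins[[b]]
    k <- length(tp)
    if (k > max_order) stop("tuple order exceeds max_order")
    vid[b, seq_len(k)] <- tp
    mask[b, seq_len(k)] <- 1
  }
  Xs <- lapply(seq_len(max_order), function(s)
    emb[vid[, s], , drop = FALSE] * mask[, s])
  structure(list(Xs = Xs, mask = mask, vid = vid,
                 labels = if ("label" %in% names(samples))
                   as.numeric(samples$label) else NULL,
                 l = rowSums(mask), B = B, max_order = max_order),
            class = "tuple_batch")
}

#' Hypergraph convolution propagation operator
#'
#' Precomputes the symmetric normalized propagation
#' `A = Dv^{-1/2} H W De^{-1} H^T Dv^{-1/2}` in factored sparse form.
#' Vertices of zero degree use the pseudo-inverse convention (their rows
#' stay zero).
#'
#' @param graph a `hypergraph` from [build_hypergraph()].
#' @return object of class `hconv_op` with fields `Hn` (sparse
#'   `Dv^{-1/2} H`) and `ew` (`W De^{-1}` diagonal as a vector).
#' @export
hconv_operator <- function(graph) {
  dv_is <- ifelse(graph$dv > 0, 1 / sqrt(graph$dv), 0)
  de_i <- ifelse(graph$de > 0, 1 / graph$de, 0)
  Hn <- Matrix::Diagonal(x = dv_is) %*% graph$H
  structure(list(Hn = Hn, ew = graph$w * de_i, n_bins = graph$n_bins),
            class = "hconv_op")
}

# A %*% X in factored form (A is symmetric, so this also serves as t(A) %*% X)
.prop <- function(op, X) {
  if (ncol(op$Hn) == 0L) return(matrix(0, nrow(X), ncol(X)))
  as.matrix(op$Hn %*% (op$ew * Matrix::crossprod(op$Hn, X)))
}

#' Hypergraph convolution
#'
#' Applies `layers` rounds of `X <- act(A X Wt)` where `A` is the symmetric
#' degree-normalized propagation of [hconv_operator()] and `act` a leaky
#' rectifier (or identity, for inspecting the raw propagation).
#'
#' @param X N x d input matrix (vertex feature embeddings).
#' @param graph a `hypergraph` or a precomputed `hconv_op`.
#' @param weights list of d x d layer weight matrices (`NULL` entries or a
#'   NULL list mean identity weights).
#' @param layers number of layers (defaults to `length(weights)`).
#' @param activation `"lrelu"` or `"identity"`.
#' @param slope leaky-rectifier negative slope.
#' @param cache if TRUE, returns the full forward cache (internal use).
#' @return N x d matrix of structural embeddings (or a cache list).
#' @export
hconv <- function(X, graph, weights = NULL, layers = NULL,
                  activation = c("lrelu", "identity"), slope = 0.01,
                  cache = FALSE) {
  activation <- match.arg(activation)
  op <- if (inherits(graph, "hconv_op")) graph else hconv_operator(graph)
  if (nrow(X) != op$n_bins) stop("X rows must equal the vertex count")
  if (is.null(layers)) layers <- max(length(weights), 1L)
  Xs <- vector("list", layers + 1L); Xs[[1L]] <- X
  Pre <- AX <- vector("list", layers)
  for (t in seq_len(layers)) {
    AX[[t]] <- .prop(op, Xs[[t]])
    W <- if (!is.null(weights) && length(weights) >= t) weights[[t]] else NULL
    Pre[[t]] <- if (is.null(W)) AX[[t]] else AX[[t]] %*% W
    Xs[[t + 1L]] <- if (activation == "lrelu") .lrelu(Pre[[t]], slope)
                    else Pre[[t]]
  }
  if (cache) list(out = Xs[[layers + 1L]], Xs = Xs, Pre = Pre, AX = AX)
  else Xs[[layers + 1L]]
}

#' Multi-head self-attention embeddings of a tuple batch
#'
#' For every real vertex i the attention scores `e_ij = (Wq' x_i)'(Wk' x_j)`
#' over the other real vertices j are softmax-normalized and used to average
#' the value projections; head outputs are concatenated, projected, and
#' passed through tanh.  Padded slots and the self pair are excluded from
#' the softmax.
#'
#' @param batch a `tuple_batch`.
#' @param params an `mci_params` list (uses `Wq`, `Wk`, `Wv`, `Wo`).
#' @param cfg an [mci_config].
#' @return list with `Ed` (list of B x d matrices per slot, zero rows for
#'   padded slots) and `alpha` (per head, per slot, B x max_order attention
#'   rows summing to 1 over allowed pairs) plus the internal cache.
#' @export
attention_embed <- function(batch, params, cfg) {
  n <- batch$max_order; B <- batch$B; d <- cfg$d; dh <- cfg$head_dim
  heads <- lapply(seq_len(cfg$n_heads), function(h) {
    hc <- ((h - 1L) * dh + 1L):(h * dh)
    Q <- lapply(batch$Xs, function(x) x %*% params$Wq[, hc, drop = FALSE])
    K <- lapply(batch$Xs, function(x) x %*% params$Wk[, hc, drop = FALSE])
    V <- lapply(batch$Xs, function(x) x %*% params$Wv[, hc, drop = FALSE])
    alpha <- O <- vector("list", n)
    for (i in seq_len(n)) {
      E <- matrix(-Inf, B, n)
      for (j in seq_len(n)) {
        if (j == i) next
        # log of the 0/1 allow mask is 0 or -Inf: masked pairs drop out
        E[, j] <- rowSums(Q[[i]] * K[[j]]) +
          log(batch$mask[, i] * batch$mask[, j])
      }
      mx <- apply(E, 1L, max)
      ex <- exp(E - ifelse(is.finite(mx), mx, 0))
      ex[!is.finite(ex)] <- 0
      den <- rowSums(ex)
      a <- ex / ifelse(den > 0, den, 1)
      o <- matrix(0, B, dh)
      for (j in seq_len(n)) if (j != i) o <- o + a[, j] * V[[j]]
      alpha[[i]] <- a; O[[i]] <- o
    }
    list(Q = Q, K = K, V = V, alpha = alpha, O = O)
  })
  Ed <- EdPre <- Ocat <- vector("list", n)
  for (i in seq_len(n)) {
    Ocat[[i]] <- do.call(cbind, lapply(heads, function(hd) hd$O[[i]]))
    EdPre[[i]] <- Ocat[[i]] %*% params$Wo
    Ed[[i]] <- tanh(EdPre[[i]]) * batch$mask[, i]
  }
  list(Ed = Ed, alpha = lapply(heads, `[[`, "alpha"),
       cache = list(heads = heads, Ocat = Ocat, EdPre = EdPre))
}

#' Per-vertex MLP embeddings of a tuple batch
#'
#' `E_I,i = W3 relu(W2 relu(W1 x_i + b1) + b2) + b3`, applied to each vertex
#' independently of the other tuple members.
#'
#' @param batch a `tuple_batch`.
#' @param params an `mci_params` list (uses `W1..W3`, `b1..b3`).
#' @param cfg an [mci_config].
#' @param drop optional list of dropout masks (training only; internal).
#' @return list with `EI` (list of B x d matrices per slot) and the cache.
#' @export
mlp_embed <- function(batch, params, cfg, drop = NULL) {
  n <- batch$max_order
  pre1 <- h1 <- pre2 <- h2 <- EI <- vector("list", n)
  for (s in seq_len(n)) {
    pre1[[s]] <- sweep(batch$Xs[[s]] %*% params$W1, 2L, params$b1, "+")
    a1 <- .relu(pre1[[s]])
    if (!is.null(drop)) a1 <- a1 * drop$m1[[s]]
    h1[[s]] <- a1
    pre2[[s]] <- sweep(a1 %*% params$W2, 2L, params$b2, "+")
    a2 <- .relu(pre2[[s]])
    if (!is.null(drop)) a2 <- a2 * drop$m2[[s]]
    h2[[s]] <- a2
    EI[[s]] <- sweep(a2 %*% params$W3, 2L, params$b3, "+")
  }
  list(EI = EI, cache = list(pre1 = pre1, h1 = h1, pre2 = pre2, h2 = h2))
}

#' KL alignment loss between the two separating-channel views
#'
#' The attention and MLP embeddings are masked-mean-pooled per tuple,
#' softmax-normalized over the embedding dimension, and compared by the
#' one-directional base-2 Kullback-Leibler divergence, averaged over the
#' batch.  Zero when the two views agree; always non-negative.
#'
#' @param Ed,EI lists of per-slot B x d matrices (see [attention_embed()],
#'   [mlp_embed()]).
#' @param mask B x max_order mask of real slots.
#' @return scalar loss.
#' @export
kl_align <- function(Ed, EI, mask) {
  pooled <- .kl_pool(Ed, EI, mask)
  mean(rowSums(pooled$P * pooled$r) / log(2))
}

.kl_pool <- function(Ed, EI, mask) {
  l <- rowSums(mask)
  a <- Reduce(`+`, lapply(seq_along(Ed), function(s) Ed[[s]] * mask[, s])) / l
  b <- Reduce(`+`, lapply(seq_along(EI), function(s) EI[[s]] * mask[, s])) / l
  P <- .softmax_rows(a); Q <- .softmax_rows(b)
  list(P = P, Q = Q, r = log(P) - log(Q), a = a, b = b, l = l)
}

#' Fuse channel embeddings and score a tuple batch
#'
#' Per real vertex, the discrete embedding (mean or concatenation of the
#' attention and MLP views) is concatenated with the vertex's structural
#' embedding, passed through a rectified dense layer and a scalar sigmoid
#' head; the tuple probability is the masked mean of the per-vertex scores.
#'
#' @param Ed,EI per-slot embedding lists (ignored when the separating
#'   channel is disabled; pass NULL).
#' @param S N x d structural embedding matrix (NULL when the coupling
#'   channel is disabled).
#' @param batch a `tuple_batch`.
#' @param params an `mci_params` list.
#' @param cfg an [mci_config].
#' @param drop optional fusion dropout masks (internal).
#' @return list with `p` (B-vector of probabilities in (0,1)), `p_slot`,
#'   and the forward cache.
#' @export
fuse_and_score <- function(Ed, EI, S, batch, params, cfg, drop = NULL) {
  n <- batch$max_order
  z <- pref <- hf <- vector("list", n)
  p_slot <- matrix(0, batch$B, n)
  for (s in seq_len(n)) {
    parts <- list()
    if (cfg$use_she)
      parts[[length(parts) + 1L]] <-
        if (cfg$merge == "mean") (Ed[[s]] + EI[[s]]) / 2
        else cbind(Ed[[s]], EI[[s]])
    if (cfg$use_che)
      parts[[length(parts) + 1L]] <- S[batch$vid[, s], , drop = FALSE]
    z[[s]] <- do.call(cbind, parts)
    pref[[s]] <- sweep(z[[s]] %*% params$Wf, 2L, params$bf, "+")
    a <- .relu(pref[[s]])
    if (!is.null(drop)) a <- a * drop$mf[[s]]
    hf[[s]] <- a
    p_slot[, s] <- .sigmoid(as.vector(a %*% params$ws) + params$bs)
  }
  p <- rowSums(p_slot * batch$mask) / batch$l
  list(p = p, p_slot = p_slot, cache = list(z = z, pref = pref, hf = hf))
}

#' Binary cross-entropy plus KL alignment loss
#'
#' `L = -(1/B) sum(y log p + (1-y) log(1-p)) + lambda_kl * kl`, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p predicted probabilities.
#' @param labels binary labels.
#' @param kl scalar KL alignment loss.
#' @param lambda_kl its weight.
#' @return scalar total loss, with attribute `bce`.
#' @export
total_loss <- function(p, labels, kl = 0, lambda_kl = 1) {
  eps <- 1e-7
  ph <- pmin(pmax(p, eps), 1 - eps)
  bce <- -mean(labels * log(ph) + (1 - labels) * log(1 - ph))
  structure(bce + lambda_kl * kl, bce = bce)
}

#' Binarize probability scores
#'
#' A tuple is called a hyperedge when its score reaches the threshold
#' (`p >= t`, the membership rule at the conventional t = 0.5).
#'
#' @param p probabilities in `[0, 1]`.
#' @param t threshold.
#' @return integer vector of 0/1 labels.
#' @export
classify <- function(p, t = 0.5) as.integer(p >= t)

# ---------------------------------------------------------------------------
# full forward + backward pass (training core)

# draws inverted-dropout masks for one batch
.draw_dropout <- function(batch, cfg) {
  if (cfg$dropout <= 0) return(NULL)
  keep <- 1 - cfg$dropout
  mk <- function() lapply(seq_len(batch$max_order), function(s)
    matrix(stats::rbinom(batch$B * cfg$d, 1L, keep), batch$B, cfg$d) / keep)
  masks <- list(mf = mk())
  if (cfg$use_she) { masks$m1 <- mk(); masks$m2 <- mk() }
  masks
}

# Forward pass; S/hcache supplied by caller when the coupling channel is on.
.mci_forward <- function(params, cfg, batch, hcache = NULL, drop = NULL) {
  att <- mlp <- pooled <- NULL
  kl <- 0
  Ed <- EI <- NULL
  if (cfg$use_she) {
    att <- attention_embed(batch, params, cfg)
    mlp <- mlp_embed(batch, params, cfg, drop)
    Ed <- att$Ed; EI <- mlp$EI
    pooled <- .kl_pool(Ed, EI, batch$mask)
    kl <- mean(rowSums(pooled$P * pooled$r) / log(2))
  }
  S <- if (cfg$use_che) hcache$out else NULL
  fs <- fuse_and_score(Ed, EI, S, batch, params, cfg, drop)
  list(att = att, mlp = mlp, pooled = pooled, kl = kl, fs = fs, p = fs$p)
}

# Backward pass: returns gradients for every parameter.
.mci_backward <- function(params, cfg, batch, fw, hcache, op, drop = NULL) {
  B <- batch$B; n <- batch$max_order; d <- cfg$d
  y <- batch$labels
  eps <- 1e-7
  p <- fw$p
  ph <- pmin(pmax(p, eps), 1 - eps)
  dp <- ifelse(p > eps & p < 1 - eps,
               -(y / ph - (1 - y) / (1 - ph)) / B, 0)
  g <- lapply(params, function(p) p * 0)

  dD <- vector("list", n)       # grad wrt discrete embedding per slot
  dSacc <- if (cfg$use_che) matrix(0, op$n_bins, d) else NULL
  dDwidth <- if (cfg$use_she) (if (cfg$merge == "mean") d else 2L * d) else 0L
  fs <- fw$fs
  for (s in seq_len(n)) {
    dp_s <- dp * batch$mask[, s] / batch$l
    dlog <- dp_s * fs$p_slot[, s] * (1 - fs$p_slot[, s])
    hfd <- fs$cache$hf[[s]]
    g$ws <- g$ws + crossprod(hfd, dlog)
    g$bs <- g$bs + sum(dlog)
    dhf <- outer(dlog, as.vector(params$ws))
    if (!is.null(drop)) dhf <- dhf * drop$mf[[s]]
    dpref <- dhf * (fs$cache$pref[[s]] > 0)
    g$Wf <- g$Wf + crossprod(fs$cache$z[[s]], dpref)
    g$bf <- g$bf + colSums(dpref)
    dz <- dpref %*% t(params$Wf)
    if (cfg$use_she) dD[[s]] <- dz[, seq_len(dDwidth), drop = FALSE]
    if (cfg$use_che) {
      dS_s <- dz[, dDwidth + seq_len(d), drop = FALSE]
      rs <- rowsum(dS_s, group = batch$vid[, s])
      rows <- as.integer(rownames(rs))
      dSacc[rows, ] <- dSacc[rows, , drop = FALSE] + rs
    }
  }

  if (cfg$use_she) {
    # KL pooling gradients
    pooled <- fw$pooled
    coef <- cfg$lambda_kl / (B * log(2))
    da <- coef * pooled$P * (pooled$r - rowSums(pooled$P * pooled$r))
    db <- coef * (pooled$Q - pooled$P)
    dEd <- dEI <- vector("list", n)
    for (s in seq_len(n)) {
      if (cfg$merge == "mean") {
        dEd[[s]] <- dD[[s]] / 2
        dEI[[s]] <- dD[[s]] / 2
      } else {
        dEd[[s]] <- dD[[s]][, seq_len(d), drop = FALSE]
        dEI[[s]] <- dD[[s]][, d + seq_len(d), drop = FALSE]
      }
      w <- batch$mask[, s] / pooled$l
      dEd[[s]] <- dEd[[s]] + da * w
      dEI[[s]] <- dEI[[s]] + db * w
    }

    # attention backward
    att <- fw$att
    dh <- cfg$head_dim
    dOcat <- vector("list", n)
    for (i in seq_len(n)) {
      dEdPre <- dEd[[i]] * batch$mask[, i] * (1 - tanh(att$cache$EdPre[[i]])^2)
      g$Wo <- g$Wo + crossprod(att$cache$Ocat[[i]], dEdPre)
      dOcat[[i]] <- dEdPre %*% t(params$Wo)
    }
    for (h in seq_len(cfg$n_heads)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      hd <- att$cache$heads[[h]]
      dQ <- dK <- dV <- lapply(seq_len(n), function(s) matrix(0, B, dh))
      for (i in seq_len(n)) {
        dOh <- dOcat[[i]][, hc, drop = FALSE]
        a <- hd$alpha[[i]]
        dalpha <- matrix(0, B, n)
        for (j in seq_len(n)) {
          if (j == i) next
          dalpha[, j] <- rowSums(dOh * hd$V[[j]])
          dV[[j]] <- dV[[j]] + a[, j] * dOh
        }
        dE <- a * (dalpha - rowSums(a * dalpha))
        for (j in seq_len(n)) {
          if (j == i) next
          dQ[[i]] <- dQ[[i]] + dE[, j] * hd$K[[j]]
          dK[[j]] <- dK[[j]] + dE[, j] * hd$Q[[i]]
        }
      }
      for (s in seq_len(n)) {
        g$Wq[, hc] <- g$Wq[, hc] + crossprod(batch$Xs[[s]], dQ[[s]])
        g$Wk[, hc] <- g$Wk[, hc] + crossprod(batch$Xs[[s]], dK[[s]])
        g$Wv[, hc] <- g$Wv[, hc] + crossprod(batch$Xs[[s]], dV[[s]])
      }
    }

    # MLP backward
    mc <- fw$mlp$cache
    for (s in seq_len(n)) {
      dEIs <- dEI[[s]]
      g$W3 <- g$W3 + crossprod(mc$h2[[s]], dEIs)
      g$b3 <- g$b3 + colSums(dEIs)
      dh2 <- dEIs %*% t(params$W3)
      if (!is.null(drop)) dh2 <- dh2 * drop$m2[[s]]
      dpre2 <- dh2 * (mc$pre2[[s]] > 0)
      g$W2 <- g$W2 + crossprod(mc$h1[[s]], dpre2)
      g$b2 <- g$b2 + colSums(dpre2)
      dh1 <- dpre2 %*% t(params$W2)
      if (!is.null(drop)) dh1 <- dh1 * drop$m1[[s]]
      dpre1 <- dh1 * (mc$pre1[[s]] > 0)
      g$W1 <- g$W1 + crossprod(batch$Xs[[s]], dpre1)
      g$b1 <- g$b1 + colSums(dpre1)
    }
  }

  if (cfg$use_che) {
    # hconv backward through the cached layer stack
    dX <- dSacc
    for (t in rev(seq_len(cfg$hconv_layers))) {
      dPre <- dX * .lrelu_grad(hcache$Pre[[t]], cfg$slope)
      nm <- paste0("Wt", t)
      g[[nm]] <- g[[nm]] + crossprod(hcache$AX[[t]], dPre)
      dX <- .prop(op, dPre %*% t(params[[nm]]))
    }
  }
  g
}

# Loss and gradients for one batch (the unit the optimizer consumes).
.mci_loss_grads <- function(params, cfg, batch, op, X0, drop = NULL) {
  hcache <- if (cfg$use_che)
    hconv(X0, op, weights = params[paste0("Wt", seq_len(cfg$hconv_layers))],
          layers = cfg$hconv_layers, slope = cfg$slope, cache = TRUE)
  else NULL
  fw <- .mci_forward(params, cfg, batch, hcache, drop)
  loss <- total_loss(fw$p, batch$labels, fw$kl, cfg$lambda_kl)
  grads <- .mci_backward(params, cfg, batch, fw, hcache, op, drop)
  list(loss = as.numeric(loss), bce = attr(loss, "bce"), kl = fw$kl,
       p = fw$p, grads = grads)
}

#' Score candidate tuples with a trained model
#'
#' Evaluation-mode forward pass (no dropout): returns the probability that
#' each tuple forms a hyperedge.
#'
#' @param model an `mci_model` from [train_mci()] (or a list with `params`,
#'   `cfg`, `emb`, `graph_op`).
#' @param samples a `labeled_samples` data.frame (labels optional).
#' @param batch_size tuples per forward pass.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_mci <- function(model, samples, batch_size = 1024L) {
  n <- nrow(samples)
  hcache <- .model_hconv(model)
  p <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    batch <- build_batch(samples[idx, , drop = FALSE], model$emb,
                         model$cfg$max_order)
    fw <- .mci_forward(model$params, model$cfg, batch, hcache, drop = NULL)
    p[idx] <- fw$p
  }
  p
}

.model_hconv <- function(model) {
  if (!model$cfg$use_che) return(NULL)
  hconv(model$emb, model$graph_op,
        weights = model$params[paste0("Wt", seq_len(model$cfg$hconv_layers))],
        layers = model$cfg$hconv_layers, slope = model$cfg$slope,
        cache = TRUE)
}
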