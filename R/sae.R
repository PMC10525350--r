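#' Train a stacked autoencoder on per-bin features
#'
#' Greedy layer-wise pre-training: an autoencoder with a rectified-linear
#' encoder `y = relu(W' x + b)` and a linear decoder is trained to minimize
#' the mean squared reconstruction error `1/N sum_i ||x_i - z_i||^2`; its
#' hidden activations then become the input of the next layer's autoencoder.
#' The last hidden layer (width 64 by default) is the vertex feature
#' embedding `f(x)` consumed by the scorer.
#'
#' Features are z-score standardized per track before encoding (peak counts
#' have very different scales across tracks); because standardized targets
#' are signed, the decoder's output layer is linear rather than rectified.
#'
#' @param features a `feature_table`.
#' @param widths hidden-layer widths, outermost first (default `c(128, 64)`;
#'   the final width is the embedding dimension).
#' @param epochs training epochs per layer.
#' @param lr Adam learning rate.
#' @param seed RNG seed (weights and batch order).
#' @param batch_size minibatch size.
#' @return object of class `sae`: list of encoder layers (`W`, `b`), the
#'   per-track standardization (`center`, `scale`), `widths`, and the
#'   per-layer reconstruction `loss_curve`s.
#' @export
train_sae <- function(features, widths = c(128L, 64L), epochs = 100L,
                      lr = 1e-3, seed = 1L, batch_size = 64L) {
  X <- as.matrix(features$values)
  if (ncol(X) < 1L) stop("need at least one feature track")
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  X <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  set.seed(seed)
  layers <- vector("list", length(widths))
  curves <- vector("list", length(widths))
  input <- X
  for (l in seq_along(widths)) {
    fit <- .train_ae_layer(input, widths[l], epochs, lr, batch_size)
    layers[[l]] <- fit$layer
    curves[[l]] <- fit$loss_curve
    input <- .relu(sweep(input %*% fit$layer$W, 2L, fit$layer$b, "+"))
  }
  structure(list(layers = layers, center = center, scale = scale,
                 widths = widths, loss_curves = curves), class = "sae")
}

# one autoencoder layer: relu encoder, linear decoder, Adam on MSE
.train_ae_layer <- function(X, width, epochs, lr, batch_size) {
  nin <- ncol(X); n <- nrow(X)
  params <- list(W = .glorot(nin, width), b = numeric(width),
                 Wd = .glorot(width, nin), bd = numeric(nin))
  st <- .adam_init(params)
  loss_curve <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ordr <- sample.int(n)
    tot <- 0
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ordr[s:min(s + batch_size - 1L, n)]
      xb <- X[idx, , drop = FALSE]
      pre <- sweep(xb %*% params$W, 2L, params$b, "+")
      h <- .relu(pre)
      z <- sweep(h %*% params$Wd, 2L, params$bd, "+")
      err <- z - xb
      loss <- sum(err^2) / length(idx)
      if (!is.finite(loss)) stop("non-finite autoencoder loss at epoch ", ep)
      tot <- tot + loss * length(idx)
      dz <- 2 * err / length(idx)
      g <- list(Wd = crossprod(h, dz), bd = colSums(dz))
      dh <- dz %*% t(params$Wd)
      dpre <- dh * (pre > 0)
      g$W <- crossprod(xb, dpre)
      g$b <- colSums(dpre)
      upd <- .adam_step(params, g, st, lr)
      params <- upd$params; st <- upd$state
    }
    loss_curve[ep] <- tot / n
  }
  list(layer = params[c("W", "b")], loss_curve = loss_curve)
}

#' Encode features into vertex embeddings
#'
#' Pure function: applies the standardization and the frozen rectified
#' encoder stack of a trained [train_sae()] model.
#'
#' @param sae a trained `sae`.
#' @param features a `feature_table` with the same track width as training.
#' @return N x `widths[last]` real matrix of embeddings `f(x_i)`.
#' @export
sae_encode <- function(sae, features) {
  X <- as.matrix(features$values)
  if (ncol(X) != length(sae$center))
    stop("feature width does not match the trained encoder")
  X <- sweep(sweep(X, 2L, sae$center), 2L, sae$scale, "/")
  for (layer in sae$layers)
    X <- .relu(sweep(X %*% layer$W, 2L, layer$b, "+"))
  X
}

#' Reconstruction loss of a feature matrix under an encoder/decoder pair
#'
#' Mean over rows of the squared reconstruction error, the objective
#' minimized during autoencoder pre-training.  Exposed mainly for testing
#' and diagnostics.
#'
#' @param X input matrix (rows = samples).
#' @param Z reconstruction matrix of identical shape.
#' @return scalar loss `1/N sum_i ||x_i - z_i||^2`.
#' @export
recon_loss <- function(X, Z) {
  stopifnot(all(dim(X) == dim(Z)))
  sum((X - Z)^2) / nrow(X)
}
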