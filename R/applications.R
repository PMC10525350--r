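#' Pairwise interaction likelihood matrix
#'
#' Scores every unordered pair of genomic bins with the trained model (the
#' pair is padded and masked as an order-2 tuple, so attention reduces to
#' the single available neighbor) and reshapes the probabilities into a
#' symmetric N x N likelihood matrix with unit diagonal (self-contact is
#' undefined by the model; the identity choice leaves the diagonal of a
#' contact matrix untouched by denoising).
#'
#' @param model a trained `mci_model`.
#' @param bins a [genome_bins] (N must match the model's embeddings).
#' @param batch_size pairs per forward pass.
#' @return object of class `likelihood_matrix`: list with dense `values`
#'   (N x N, entries in `[0, 1]`) and `bins`; attribute `n_evaluations`
#'   records the `choose(N, 2)` model calls.
#' @export
pairwise_likelihood <- function(model, bins, batch_size = 4096L) {
  n <- bins$n_bins
  if (n != nrow(model$emb)) stop("bins do not match the model's embeddings")
  pr <- utils::combn(n, 2L)
  pairs <- data.frame(key = paste(pr[1L, ], pr[2L, ], sep = ","))
  pairs$bins <- lapply(seq_len(ncol(pr)), function(c) pr[, c])
  p <- predict_mci(model, pairs, batch_size = batch_size)
  m <- matrix(0, n, n)
  m[cbind(pr[1L, ], pr[2L, ])] <- p
  m <- m + t(m)
  diag(m) <- 1
  out <- structure(list(values = m, bins = bins),
                   class = "likelihood_matrix")
  attr(out, "n_evaluations") <- ncol(pr)
  out
}

#' Denoise a contact matrix by likelihood weighting
#'
#' Element-wise product of the model's likelihood matrix and the observed
#' contact matrix.  Because likelihoods are at most 1, no entry is ever
#' increased; symmetry and non-negativity are preserved.
#'
#' @param likelihood a `likelihood_matrix` (from [pairwise_likelihood()]).
#' @param contacts a [contact_matrix] on the same binning.
#' @return a denoised [contact_matrix].
#' @export
denoise_contacts <- function(likelihood, contacts) {
  if (!identical(dim(likelihood$values), dim(contacts$values)))
    stop("likelihood and contact matrices must have the same dimension")
  vals <- contacts$values * likelihood$values
  contact_matrix(vals, contacts$bins)
}

#' Per-vertex embeddings from a trained model
#'
#' For compartment-level analysis each bin is represented by its own
#' feature pathway: the MLP view of its encoded features (the attention
#' view needs tuple context and is omitted) and, when the coupling channel
#' is on, its structural embedding from the hypergraph convolution over the
#' full positive hypergraph.  By default the concatenation is passed
#' through the trained fusion layer (`stage = "fused"`, N x d); with
#' `stage = "concat"` the raw pre-fusion concatenation is returned.
#'
#' @param model a trained `mci_model`.
#' @param stage `"fused"` or `"concat"`.
#' @return N x d (fused) or N x (channels * d) matrix.
#' @export
extract_embeddings <- function(model, stage = c("fused", "concat")) {
  stage <- match.arg(stage)
  params <- model$params; cfg <- model$cfg
  parts <- list()
  if (cfg$use_she) {
    h1 <- .relu(sweep(model$emb %*% params$W1, 2L, params$b1, "+"))
    h2 <- .relu(sweep(h1 %*% params$W2, 2L, params$b2, "+"))
    EI <- sweep(h2 %*% params$W3, 2L, params$b3, "+")
    # the discrete embedding of an isolated vertex is its MLP view, padded
    # to the fusion layer's expected width under "mean" merge
    D <- if (cfg$merge == "mean") EI else cbind(EI, EI)
    parts$D <- D
  }
  if (cfg$use_che) parts$S <- .model_hconv(model)$out
  Z <- do.call(cbind, unname(parts))
  if (stage == "concat") return(Z)
  .relu(sweep(Z %*% params$Wf, 2L, params$bf, "+"))
}

#' PCA projection and compartment separation of bin embeddings
#'
#' Mean-centered principal component analysis of the embeddings.  When
#' per-bin compartment annotations are supplied, reports how well PC1
#' separates A from B bins -- the separation score is the AUC of PC1 as a
#' one-dimensional classifier, orientation-free (`max(a, 1 - a)`, since a
#' principal axis has arbitrary sign) -- and a per-chromosome clustering
#' diagnostic (share of PC1-PC2 variance explained by chromosome
#' centroids; near 0 means no chromosome-driven clustering).
#'
#' @param embeddings N x d matrix.
#' @param labels optional per-bin annotations; compartment letters are
#'   taken from their first character, so sub-compartment labels
#'   (A1, A2, B1, ...) collapse to A/B.
#' @param chroms optional per-bin chromosome names for the dispersion
#'   diagnostic.
#' @param n_components components to keep.
#' @return list with `projection` (N x n_components), `sdev`,
#'   `separation_auc` (NULL without labels), `chrom_variance_ratio`.
#' @export
pca_compartments <- function(embeddings, labels = NULL, chroms = NULL,
                             n_components = 2L) {
  if (nrow(embeddings) < n_components)
    stop("need at least n_components rows")
  if (all(apply(embeddings, 2L, stats::sd) == 0))
    stop("embeddings are constant; PCA undefined")
  pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE,
                      rank. = n_components)
  proj <- pc$x[, seq_len(n_components), drop = FALSE]
  sep <- NULL
  if (!is.null(labels)) {
    ab <- substr(as.character(labels), 1L, 1L)
    y <- as.integer(ab == "A")
    a <- auc_score(proj[, 1L], y)
    sep <- max(a, 1 - a)
  }
  disp <- NULL
  if (!is.null(chroms)) {
    nper <- as.vector(table(chroms))       # sorted by name, as is rowsum()
    ctr <- rowsum(proj, chroms) / nper
    between <- sum(nper * rowSums(
      (ctr - matrix(colMeans(proj), nrow(ctr), ncol(proj), byrow = TRUE))^2))
    total <- sum(sweep(proj, 2L, colMeans(proj))^2)
    disp <- between / total
  }
  list(projection = proj, sdev = pc$sdev, separation_auc = sep,
       chrom_variance_ratio = disp)
}
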