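# shared fixtures, built in code at test time

tiny_bins <- function() genome_bins(c("chr1", "chr2"), c(5e6, 3e6), 1e6)

# hyperedge_set from a list of integer tuples
edge_set <- function(bins_list, frequency = NULL) {
  d <- data.frame(key = vapply(bins_list, paste, "", collapse = ","),
                  order = lengths(bins_list),
                  frequency = frequency %||% rep(1L, length(bins_list)),
                  stringsAsFactors = FALSE)
  d$bins <- bins_list
  structure(d, class = c("hyperedge_set", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random hypergraph: M hyperedges of order 3..6 over N vertices
rand_hypergraph <- function(N, M, seed) {
  set.seed(seed)
  bins_list <- lapply(seq_len(M), function(i)
    sort(sample.int(N, sample(3:min(6, N), 1L))))
  list(edges = edge_set(bins_list), N = N)
}

# labeled_samples from a list of tuples
sample_set <- function(bins_list, labels) {
  d <- data.frame(key = vapply(bins_list, paste, "", collapse = ","),
                  order = lengths(bins_list), label = as.integer(labels),
                  stringsAsFactors = FALSE)
  d$bins <- bins_list
  structure(d, class = c("labeled_samples", "data.frame"))
}

# dense brute-force evaluation of the hypergraph convolution:
# X <- act(Dv^-1/2 H W De^-1 H' Dv^-1/2 X Wt), with pseudo-inverse on
# zero degrees -- independent of the package's factored sparse path
dense_hconv_oracle <- function(X, edges, N, weights = NULL, layers = 1L,
                               activation = "identity", slope = 0.01) {
  H <- matrix(0, N, nrow(edges))
  for (e in seq_len(nrow(edges))) H[edges$bins[[e]], e] <- 1
  w <- rep(1, nrow(edges))
  dv <- as.vector(H %*% w)
  de <- colSums(H)
  Dvi <- diag(ifelse(dv > 0, 1 / sqrt(dv), 0), N)
  Dei <- diag(ifelse(de > 0, 1 / de, 0), nrow = length(de))
  A <- Dvi %*% H %*% diag(w, nrow = length(w)) %*% Dei %*% t(H) %*% Dvi
  for (t in seq_len(layers)) {
    X <- A %*% X
    if (!is.null(weights)) X <- X %*% weights[[t]]
    if (activation == "lrelu") X <- ifelse(X > 0, X, slope * X)
  }
  X
}

# a small trained model on a planted world, memoized per test session
.mini_cache <- new.env(parent = emptyenv())
planted_mini <- function() {
  if (!is.null(.mini_cache$pipe)) return(.mini_cache$pipe)
  spec <- synthetic_spec(n_chroms = 2L, bins_per_chrom = 100L,
                         n_reads = 6000L, seed = 11L)
  .mini_cache$pipe <- mci_pipeline(
    spec, config = train_config(epochs = 5L, seed = 11L),
    cfg = mci_config(d = 32L, n_heads = 4L), sae_epochs = 20L,
    sae_widths = c(64L, 32L))
  .mini_cache$pipe
}
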