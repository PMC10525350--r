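#' Zero-truncated binomial draws
#'
#' Draws `k ~ Binomial(size, prob)` conditioned on `k >= 1`, by inverse-CDF
#' sampling restricted to the truncated support -- the distribution used to
#' pick how many vertices of a positive hyperedge to corrupt.
#'
#' @param n number of draws.
#' @param size binomial size (the hyperedge order).
#' @param prob replacement probability, in (0, 1).
#' @return integer vector of draws in `[1, size]`.
#' @export
rztbinom <- function(n, size, prob) {
  if (prob <= 0 || prob >= 1) stop("prob must be in (0, 1)")
  p0 <- stats::pbinom(0, size, prob)
  u <- stats::runif(n, min = p0, max = 1)
  as.integer(stats::qbinom(u, size, prob))
}

#' Mean of the zero-truncated binomial
#' @param size,prob binomial parameters.
#' @return `size * prob / (1 - (1 - prob)^size)`.
#' @export
ztbinom_mean <- function(size, prob) {
  size * prob / (1 - (1 - prob)^size)
}

# key helpers: positives are hashed by comma-joined bin strings
.tuple_key <- function(bins) paste(bins, collapse = ",")
.key_env <- function(keys) {
  e <- new.env(parent = emptyenv(), size = max(length(keys), 1L))
  for (k in keys) assign(k, TRUE, envir = e)
  e
}

#' Corrupt a positive hyperedge into a candidate negative
#'
#' Replaces `k` randomly chosen vertices; each replacement is drawn
#' uniformly from the same chromosome within `window` bins of the replaced
#' vertex (excluding bins already in the tuple), which keeps the 1D genomic
#' distance profile of negatives close to that of positives.  If the window
#' holds no candidates (tiny chromosome) it widens to the whole chromosome.
#' The corrupted tuple must be distinct, of unchanged order, and absent from
#' the positive set; up to `max_retries` attempts are made.
#'
#' @param edge_bins sorted integer tuple (a positive hyperedge).
#' @param k number of vertices to replace; must satisfy `1 <= k < order`.
#' @param bins a [genome_bins].
#' @param positives_env environment hashing positive keys (see
#'   [build_dataset()]), or NULL to skip the collision check.
#' @param window half-width of the replacement window, in bins.
#' @param max_retries attempts before giving up.
#' @return sorted integer tuple of the negative, or NULL when retries are
#'   exhausted.
#' @export
corrupt_edge <- function(edge_bins, k, bins, positives_env = NULL,
                         window = 20L, max_retries = 100L) {
  ord <- length(edge_bins)
  if (k < 1L || k >= ord) stop("k must satisfy 1 <= k < order")
  chrom_end <- cumsum(bins$bins_per_chrom)
  chrom_start <- c(0L, chrom_end[-length(chrom_end)]) + 1L  # 1-based global
  for (try in seq_len(max_retries)) {
    pos <- sample.int(ord, k)
    newt <- edge_bins
    ok <- TRUE
    for (p in pos) {
      v <- edge_bins[p]
      ci <- findInterval(v - 1L, c(0L, chrom_end), rightmost.closed = FALSE)
      lo <- max(v - window, chrom_start[ci])
      hi <- min(v + window, chrom_end[ci])
      cand <- setdiff(lo:hi, newt)
      if (!length(cand)) {  # widen to whole chromosome
        cand <- setdiff(chrom_start[ci]:chrom_end[ci], newt)
        if (!length(cand)) { ok <- FALSE; break }
      }
      newt[p] <- cand[sample.int(length(cand), 1L)]
    }
    if (!ok) next
    newt <- sort(newt)
    if (anyDuplicated(newt)) next
    if (identical(newt, edge_bins)) next
    if (!is.null(positives_env) &&
        !is.null(positives_env[[.tuple_key(newt)]])) next
    return(newt)
  }
  NULL
}

#' Build the labeled classification dataset
#'
#' Every filtered positive hyperedge enters once with label 1; `ratio` times
#' as many corrupted negatives (label 0) are generated, each by replacing a
#' zero-truncated-binomial number of vertices of a positive.  Draws with
#' `k = order` (which would leave no vertex fixed) are redrawn.  If an edge
#' exhausts its retries, a different randomly chosen positive is corrupted
#' instead so the exact ratio is always met.  No negative ever collides with
#' a positive, and corruption preserves the order, so per-order negative
#' counts are proportional to per-order positive counts.
#'
#' @param positives a `hyperedge_set` (see [count_and_filter()]).
#' @param bins a [genome_bins].
#' @param ratio negatives per positive (default 2).
#' @param p replacement probability of the zero-truncated binomial.
#' @param window replacement window half-width in bins.
#' @param seed RNG seed; the returned sample list is a deterministic
#'   function of (positives, seed).
#' @param max_retries per-edge corruption attempts.
#' @return data.frame of class `labeled_samples` with columns `key`, `order`,
#'   `label` and list column `bins`, shuffled deterministically; attribute
#'   `n_fallback` counts edges whose negatives came from a fallback positive.
#' @export
build_dataset <- function(positives, bins, ratio = 2L, p = 0.5,
                          window = 20L, seed = 1L, max_retries = 100L) {
  if (!nrow(positives)) stop("positives must be nonempty")
  set.seed(seed)
  pos_keys <- positives$key
  env <- .key_env(pos_keys)
  npos <- nrow(positives)
  n_neg <- as.integer(ratio) * npos
  neg <- vector("list", n_neg)
  neg_seen <- new.env(parent = emptyenv())
  n_fallback <- 0L
  if (n_neg > 0L) {
    src <- rep(seq_len(npos), as.integer(ratio))
    for (i in seq_len(n_neg)) {
      e <- positives$bins[[src[i]]]
      res <- NULL
      guard <- 0L
      while (is.null(res)) {
        ord <- length(e)
        k <- rztbinom(1L, ord, p)
        while (k >= ord) k <- rztbinom(1L, ord, p)  # keep >= 1 vertex fixed
        res <- corrupt_edge(e, k, bins, env, window, max_retries)
        if (is.null(res)) {           # fall back to another positive
          guard <- guard + 1L
          n_fallback <- n_fallback + 1L
          if (guard > 1000L)
            stop("could not generate enough negatives: shortfall at ",
                 n_neg - i + 1L, " remaining")
          e <- positives$bins[[sample.int(npos, 1L)]]
        }
      }
      neg[[i]] <- res
    }
  }
  all_bins <- c(positives$bins, neg)
  keys <- c(pos_keys, vapply(neg, .tuple_key, ""))
  lab <- c(rep(1L, npos), rep(0L, n_neg))
  ord <- lengths(all_bins)
  stopifnot(!any(keys[lab == 0L] %in% pos_keys))  # set-disjointness
  perm <- sample.int(length(keys))
  out <- data.frame(key = keys[perm], order = ord[perm], label = lab[perm],
                    stringsAsFactors = FALSE)
  out$bins <- all_bins[perm]
  attr(out, "n_fallback") <- n_fallback
  structure(out, class = c("labeled_samples", "data.frame"))
}

#' Write / read labeled samples as TSV
#' Columns: comma-joined bin tuple and binary label.
#' @param samples a `labeled_samples` data.frame.
#' @param path file path.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(data.frame(bins = samples$key, label = samples$label),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "integer"))
  bins_list <- lapply(strsplit(d$bins, ",", fixed = TRUE), as.integer)
  out <- data.frame(key = d$bins, order = lengths(bins_list),
                    label = d$label, stringsAsFactors = FALSE)
  out$bins <- bins_list
  structure(out, class = c("labeled_samples", "data.frame"))
}
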