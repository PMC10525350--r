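#' Bin a multi-way read into a tuple of distinct bin indices
#'
#' Each fragment is assigned to the bin containing its midpoint (the
#' standard disambiguation for fragments straddling a bin boundary), then
#' the bin indices are deduplicated and sorted ascending.  The tuple can be
#' shorter than the fragment list when fragments share a bin.
#'
#' @param read a `multiway_read` (see [as_multiway_reads()]).
#' @param bins a [genome_bins].
#' @return sorted integer vector of distinct 1-based global bin indices.
#' @export
bin_read <- function(read, bins) {
  fr <- read$fragments
  mid <- floor((fr$start + fr$end) / 2)
  sort(unique(global_bin(bins, fr$chrom, mid)))
}

#' Bin every read of a cluster table
#'
#' Vectorized version of [bin_read()] over a `cluster_frags` table.
#'
#' @param frags a `cluster_frags` data.frame.
#' @param bins a [genome_bins].
#' @return list of sorted distinct bin-index tuples, one per read.
#' @export
bin_cluster <- function(frags, bins) {
  if (!nrow(frags)) return(list())
  mid <- floor((frags$start + frags$end) / 2)
  gb <- global_bin(bins, frags$chrom, mid)
  lapply(split(gb, frags$read), function(v) sort(unique(v)))
}

# cache of combn index matrices, keyed "n:k"
.combn_cache <- new.env(parent = emptyenv())
.combn_idx <- function(n, k) {
  key <- paste0(n, ":", k)
  if (is.null(.combn_cache[[key]]))
    .combn_cache[[key]] <- utils::combn(n, k)
  .combn_cache[[key]]
}

#' Decompose a binned read into candidate hyperedges
#'
#' A read touching n distinct bins supports every subset of size
#' `min_order..min(max_order, n)` as a candidate hyperedge; reads with fewer
#' than `min_order` distinct bins contribute nothing.  Subsets are counted
#' once per read (a read cannot support the same tuple twice).
#'
#' @param tuple sorted distinct integer bin tuple.
#' @param min_order,max_order inclusive order window (defaults 3 and 6, the
#'   abundant orders in multi-way contact data).
#' @return list of sorted integer tuples (possibly empty).
#' @export
decompose_tuple <- function(tuple, min_order = 3L, max_order = 6L) {
  n <- length(tuple)
  if (n < min_order) return(list())
  out <- vector("list", 0L)
  for (k in min_order:min(max_order, n)) {
    idx <- .combn_idx(n, k)
    out <- c(out, lapply(seq_len(ncol(idx)), function(c) tuple[idx[, c]]))
  }
  out
}

# internal: decompose a list of read tuples into a character vector of
# comma-joined subset keys (fast path used by count_and_filter)
.decompose_keys <- function(tuples, min_order = 3L, max_order = 6L) {
  keys <- lapply(tuples, function(tp) {
    n <- length(tp)
    if (n < min_order) return(character(0))
    unlist(lapply(min_order:min(max_order, n), function(k) {
      idx <- .combn_idx(n, k)
      m <- matrix(tp[idx], nrow = k)
      do.call(paste, c(lapply(seq_len(k), function(r) m[r, ]), sep = ","))
    }), use.names = FALSE)
  })
  unlist(keys, use.names = FALSE)
}

#' Count candidate hyperedges and apply per-order frequency thresholds
#'
#' Occurrence frequencies are accumulated across reads; a distinct tuple is
#' retained when its frequency is `>=` the threshold for its order (the rule
#' used to balance sample sizes across orders; e.g. thresholds 12/4/3/3 for
#' orders 3/4/5/6 on deep real data).  Output ordering is deterministic:
#' ascending order, then lexicographic by bin indices.
#'
#' @param tuples list of sorted distinct bin tuples (one entry per read), or
#'   a character vector of precomputed comma-joined subset keys.
#' @param thresholds named numeric vector mapping order ("3".."6") to the
#'   minimum frequency; must cover every order in the window.
#' @param min_order,max_order order window.
#' @return a `hyperedge_set`: data.frame with columns `bins` (list column of
#'   integer tuples), `key` (comma-joined), `order`, `frequency`.
#' @export
count_and_filter <- function(tuples, thresholds,
                             min_order = 3L, max_order = 6L) {
  orders <- min_order:max_order
  if (!all(as.character(orders) %in% names(thresholds)))
    stop("thresholds must be defined for every order in [",
         min_order, ", ", max_order, "]")
  keys <- if (is.character(tuples)) tuples
          else .decompose_keys(tuples, min_order, max_order)
  if (!length(keys)) return(.empty_edge_set())
  tab <- table(keys)
  key <- names(tab)
  freq <- as.integer(tab)
  ord <- nchar(key) - nchar(gsub(",", "", key, fixed = TRUE)) + 1L
  keep <- freq >= thresholds[as.character(ord)]
  key <- key[keep]; freq <- freq[keep]; ord <- ord[keep]
  if (!length(key)) return(.empty_edge_set())
  bins_list <- lapply(strsplit(key, ",", fixed = TRUE), as.integer)
  # deterministic: order asc, then lexicographic on bin indices
  maxo <- max(ord)
  pad <- t(vapply(bins_list, function(b) c(b, rep(-1L, maxo - length(b))),
                  integer(maxo)))
  o <- do.call(order, c(list(ord), lapply(seq_len(maxo), function(c) pad[, c])))
  d <- data.frame(key = key[o], order = ord[o], frequency = freq[o],
                  stringsAsFactors = FALSE)
  d$bins <- bins_list[o]
  structure(d, class = c("hyperedge_set", "data.frame"))
}

.empty_edge_set <- function() {
  d <- data.frame(key = character(), order = integer(), frequency = integer(),
                  stringsAsFactors = FALSE)
  d$bins <- list()
  structure(d, class = c("hyperedge_set", "data.frame"))
}

#' Write / read a hyperedge set as TSV
#'
#' Columns: comma-joined 1-based bin indices, order, frequency.
#' @param edges a `hyperedge_set`.
#' @param path file path.
#' @export
write_hyperedges <- function(edges, path) {
  utils::write.table(
    data.frame(bins = edges$key, order = edges$order,
               frequency = edges$frequency),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hyperedges
#' @export
read_hyperedges <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "integer", "integer"))
  bins_list <- lapply(strsplit(d$bins, ",", fixed = TRUE), as.integer)
  out <- data.frame(key = d$bins, order = d$order, frequency = d$frequency,
                    stringsAsFactors = FALSE)
  out$bins <- bins_list
  structure(out, class = c("hyperedge_set", "data.frame"))
}

#' Build the hypergraph incidence and degree matrices
#'
#' Assembles the sparse binary incidence matrix `H` (N vertices x M
#' hyperedges), the hyperedge weight diagonal `W` (identity by default, or
#' frequency-proportional), the vertex weight diagonal `U` (identity; it is
#' defined in the formalism but enters no computation), and the degree
#' diagonals: vertex degree `Dv[i,i] = sum_e W[e,e] H[i,e]` and hyperedge
#' degree `De[e,e] = sum_i H[i,e]`.
#'
#' @param edges a `hyperedge_set`.
#' @param n_bins number of vertices N.
#' @param weight_by_frequency if TRUE, `W[e,e]` is the edge frequency
#'   normalized to mean 1; otherwise the identity.
#' @return object of class `hypergraph`: list with sparse `H`, numeric
#'   vectors `w`, `u`, `dv`, `de`, and `n_bins`, `n_edges`.
#' @export
build_hypergraph <- function(edges, n_bins, weight_by_frequency = FALSE) {
  m <- nrow(edges)
  if (m) {
    ii <- unlist(edges$bins, use.names = FALSE)
    if (any(ii < 1L | ii > n_bins)) stop("bin index exceeds n_bins")
    jj <- rep.int(seq_len(m), edges$order)
    H <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n_bins, m))
  } else {
    H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n_bins, 0L))
  }
  w <- if (weight_by_frequency && m) {
    f <- as.numeric(edges$frequency); f * m / sum(f)
  } else rep(1, m)
  dv <- as.numeric(H %*% w)
  de <- Matrix::colSums(H)
  structure(list(H = H, w = w, u = rep(1, n_bins), dv = dv, de = de,
                 n_bins = n_bins, n_edges = m),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("<hypergraph> N = %d vertices, M = %d hyperedges\n",
              x$n_bins, x$n_edges))
  invisible(x)
}
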