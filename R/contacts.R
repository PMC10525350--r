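#' Symmetric pairwise contact matrix
#'
#' Thin wrapper around a sparse symmetric non-negative N x N matrix tied to
#' a [genome_bins] coordinate system.
#'
#' @param values an N x N matrix (dense or `Matrix` sparse), symmetric and
#'   non-negative.
#' @param bins the [genome_bins] the rows/columns refer to.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, bins) {
  values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  if (nrow(values) != bins$n_bins || ncol(values) != bins$n_bins)
    stop("matrix dimension does not match n_bins")
  if (any(values@x < 0)) stop("contact values must be non-negative")
  if (!Matrix::isSymmetric(values, tol = 1e-8))
    stop("contact matrix must be symmetric")
  structure(list(values = values, bins = bins), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d x %d, %d nonzero entries\n",
              nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' Read a COO text contact matrix
#'
#' Three tab/space-separated columns `bin_i bin_j value` with 0-based global
#' bin indices.  Either triangle (or both) may be present; entries are
#' mirrored and duplicates are summed.
#'
#' @param path path to COO text.
#' @param bins a [genome_bins] giving N.
#' @return a [contact_matrix].
#' @export
read_contact_coo <- function(path, bins) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("i", "j", "x"),
                          colClasses = c("integer", "integer", "numeric"))
  n <- bins$n_bins
  if (nrow(df)) {
    if (any(df$i < 0L | df$i >= n | df$j < 0L | df$j >= n))
      stop("bin index out of range [0, ", n, ")")
    if (any(df$x < 0)) stop("contact values must be non-negative")
  }
  off <- df$i != df$j
  i <- c(df$i, df$j[off]) + 1L
  j <- c(df$j, df$i[off]) + 1L
  x <- c(df$x, df$x[off])
  m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  contact_matrix(m, bins)
}

#' Write a contact matrix as COO text
#'
#' Upper triangle (i <= j), tab-separated, 0-based indices; zero entries are
#' omitted.  `read_contact_coo(write_contact_coo(m))` is the identity.
#'
#' @param mat a [contact_matrix].
#' @param path output path.
#' @export
write_contact_coo <- function(mat, path) {
  tm <- methods::as(Matrix::triu(mat$values), "TsparseMatrix")
  keep <- tm@x != 0
  i <- tm@i[keep]; j <- tm@j[keep]; x <- tm@x[keep]
  o <- order(i, j)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(i))
    writeLines(sprintf("%d\t%d\t%s", i[o], j[o],
                       format(x[o], trim = TRUE, scientific = FALSE,
                              drop0trailing = TRUE)), con)
  invisible(path)
}

#' Decompose multi-way reads into a pairwise contact matrix
#'
#' Every read contributes one count to each unordered pair of distinct bins
#' it touches (the standard pairwise decomposition of a concatemer).
#'
#' @param frags a `cluster_frags` table from [read_cluster_file()].
#' @param bins a [genome_bins].
#' @return a [contact_matrix] of pairwise contact counts.
#' @export
reads_to_contacts <- function(frags, bins) {
  tuples <- bin_cluster(frags, bins)
  n <- bins$n_bins
  ii <- integer(0); jj <- integer(0)
  pair_i <- lapply(tuples, function(tp) {
    k <- length(tp)
    if (k < 2L) return(NULL)
    cmb <- utils::combn(tp, 2L)
    cbind(cmb[1L, ], cmb[2L, ])
  })
  pairs <- do.call(rbind, pair_i)
  if (is.null(pairs) || !nrow(pairs)) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
    return(contact_matrix(m, bins))
  }
  m <- Matrix::sparseMatrix(i = c(pairs[, 1], pairs[, 2]),
                            j = c(pairs[, 2], pairs[, 1]),
                            x = 1, dims = c(n, n))
  contact_matrix(m, bins)
}
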