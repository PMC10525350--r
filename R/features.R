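#' Count peaks per genomic bin
#'
#' Reads a BED/narrowPeak file (first three columns used) and counts, for
#' every bin, the peaks whose midpoint falls inside it.  Intervals on
#' chromosomes absent from the binning are skipped with a warning.
#'
#' @param path path to a BED-like file.
#' @param bins a [genome_bins].
#' @return integer vector of length `n_bins`; its sum equals the number of
#'   valid peaks.
#' @export
count_peaks <- function(path, bins) {
  bed <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) NULL)
  out <- integer(bins$n_bins)
  if (is.null(bed) || !nrow(bed)) return(out)
  chrom <- as.character(bed[[1]])
  start <- as.numeric(bed[[2]]); end <- as.numeric(bed[[3]])
  known <- chrom %in% bins$chrom_names
  if (any(!known))
    warning(sprintf("%d peak(s) on unknown chromosomes skipped in %s",
                    sum(!known), basename(path)))
  if (!any(known)) return(out)
  mid <- floor((start[known] + end[known]) / 2)
  gb <- global_bin(bins, chrom[known], mid)
  tab <- tabulate(gb, nbins = bins$n_bins)
  as.integer(tab)
}

#' Build a bins x tracks peak-count feature table
#'
#' @param bed_paths character vector of BED file paths; track names default
#'   to the file names without extension.
#' @param bins a [genome_bins].
#' @param track_names optional explicit track names.
#' @return object of class `feature_table`: list with integer matrix
#'   `values` (N x F) and `track_names`.
#' @export
feature_table <- function(bed_paths, bins, track_names = NULL) {
  if (is.null(track_names))
    track_names <- sub("\\.[^.]*$", "", basename(bed_paths))
  values <- vapply(bed_paths, count_peaks, integer(bins$n_bins), bins = bins)
  dim(values) <- c(bins$n_bins, length(bed_paths))
  colnames(values) <- track_names
  structure(list(values = values, track_names = track_names),
            class = "feature_table")
}

#' Feature table from an in-memory count matrix
#' @param counts N x F non-negative integer matrix.
#' @param track_names column identifiers.
#' @return a `feature_table`.
#' @export
feature_table_from_counts <- function(counts, track_names = colnames(counts)) {
  if (is.null(track_names))
    track_names <- sprintf("track%02d", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("peak counts must be non-negative")
  colnames(counts) <- track_names
  structure(list(values = counts, track_names = track_names),
            class = "feature_table")
}

#' Write / read a feature table as TSV (0-based bin id + one column per track)
#' @param features a `feature_table`.
#' @param path file path.
#' @export
write_features <- function(features, path) {
  d <- data.frame(bin = seq_len(nrow(features$values)) - 1L, features$values,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  feature_table_from_counts(m, colnames(d)[-1])
}
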