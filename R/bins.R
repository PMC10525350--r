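#' Fixed-width genomic bins across a genome
#'
#' A `genome_bins` object is the shared coordinate system of the package: an
#' ordered, global index over non-overlapping fixed-width bins laid across a
#' set of chromosomes.  Bin indices are 1-based in R; on-disk formats
#' (contact COO text, samples TSV) use 0-based indices for interoperability.
#'
#' @param chrom_names character vector of chromosome identifiers (unique).
#' @param chrom_sizes integer vector of chromosome lengths in base pairs.
#' @param bin_size bin width in base pairs (default 1 Mb, the resolution at
#'   which multi-way contacts are usually analysed).
#'
#' @return An object of class `genome_bins` with fields `chrom_names`,
#'   `chrom_sizes`, `bin_size`, `n_bins` and `offsets` (0-based global index
#'   of each chromosome's first bin).
#' @export
genome_bins <- function(chrom_names, chrom_sizes, bin_size = 1e6L) {
  chrom_names <- as.character(chrom_names)
  chrom_sizes <- as.numeric(chrom_sizes)
  if (length(chrom_names) != length(chrom_sizes))
    stop("chrom_names and chrom_sizes must have equal length")
  if (anyDuplicated(chrom_names))
    stop("duplicate chromosome name: ",
         paste(unique(chrom_names[duplicated(chrom_names)]), collapse = ", "))
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("chromosome sizes must be positive")
  bin_size <- as.numeric(bin_size)
  if (!is.finite(bin_size) || bin_size <= 0) stop("bin_size must be > 0")
  nb <- as.integer(ceiling(chrom_sizes / bin_size))
  offsets <- c(0L, cumsum(nb))[seq_along(nb)]
  names(offsets) <- chrom_names
  structure(list(
    chrom_names = chrom_names,
    chrom_sizes = stats::setNames(chrom_sizes, chrom_names),
    bin_size    = bin_size,
    n_bins      = sum(nb),
    bins_per_chrom = stats::setNames(nb, chrom_names),
    offsets     = offsets
  ), class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("<genome_bins> %d chromosomes, %d bins of %s bp\n",
              length(x$chrom_names), x$n_bins,
              format(x$bin_size, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Read a UCSC chrom.sizes file into a binning
#'
#' Two whitespace-separated columns: chromosome name and length in bp, in
#' file order (the file order defines the global bin order).
#'
#' @param path path to a chrom.sizes file.
#' @param bin_size bin width in base pairs.
#' @return a [genome_bins] object.
#' @export
read_chrom_sizes <- function(path, bin_size = 1e6L) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(toks, length, 0L) != 2L)
  if (length(bad))
    stop(sprintf("malformed chrom.sizes line %d: %s", lineno[bad[1]],
                 lines[bad[1]]))
  nm <- vapply(toks, `[[`, "", 1L)
  sz <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 2L)))
  bad <- which(!is.finite(sz) | sz != floor(sz))
  if (length(bad))
    stop(sprintf("malformed chrom.sizes line %d: non-integer length", lineno[bad[1]]))
  genome_bins(nm, sz, bin_size)
}

#' Write a chrom.sizes file
#' @param bins a [genome_bins] object.
#' @param path output path.
#' @export
write_chrom_sizes <- function(bins, path) {
  writeLines(sprintf("%s\t%d", bins$chrom_names,
                     as.integer(bins$chrom_sizes)), path)
  invisible(path)
}

#' Global bin index of genomic positions
#'
#' Coordinates are 0-based, half-open throughout the package.  Returns
#' 1-based global bin indices.
#'
#' @param bins a [genome_bins] object.
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 0-based base-pair positions.
#' @return integer vector of global bin indices in `[1, n_bins]`.
#' @export
global_bin <- function(bins, chrom, pos) {
  chrom <- as.character(chrom)
  unknown <- setdiff(unique(chrom), bins$chrom_names)
  if (length(unknown))
    stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  pos <- as.numeric(pos)
  if (any(pos < 0) || any(pos >= bins$chrom_sizes[chrom]))
    stop("position outside chromosome bounds")
  as.integer(bins$offsets[chrom] + floor(pos / bins$bin_size)) + 1L
}

#' Genomic interval of a global bin
#' @param bins a [genome_bins] object.
#' @param idx 1-based global bin indices.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open; `end` clipped to the chromosome length).
#' @export
bin_interval <- function(bins, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > bins$n_bins)) stop("bin index out of range")
  ends <- cumsum(bins$bins_per_chrom)
  ci <- findInterval(idx - 1L, c(0L, ends), rightmost.closed = FALSE)
  chrom <- bins$chrom_names[ci]
  local <- idx - 1L - bins$offsets[chrom]
  start <- local * bins$bin_size
  data.frame(chrom = chrom,
             start = start,
             end = pmin(start + bins$bin_size, bins$chrom_sizes[chrom]),
             row.names = NULL)
}
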