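#' Read a multi-way contact cluster file
#'
#' The cluster dialect maps one sequencing read (concatemer) per line: the
#' first whitespace-separated token is the read identifier, every following
#' token is a fragment `chrom:start-end` with 0-based half-open coordinates.
#' Empty lines are skipped (and counted in the `skipped` attribute).
#'
#' The reads are returned in columnar form -- a data.frame with one row per
#' fragment -- which is what every downstream step consumes.  Use
#' [as_multiway_reads()] for the one-record-per-read view.
#'
#' @param path path to a cluster file.
#' @return data.frame of class `cluster_frags` with columns `read` (integer
#'   read index in file order), `read_id`, `chrom`, `start`, `end`.
#' @export
read_cluster_file <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  n_skipped <- sum(!keep)
  if (n_skipped) message(sprintf("skipped %d empty line(s) in %s", n_skipped, path))
  lines <- lines[keep]
  if (!length(lines)) {
    out <- data.frame(read = integer(), read_id = character(),
                      chrom = character(), start = numeric(), end = numeric())
    class(out) <- c("cluster_frags", class(out))
    attr(out, "skipped") <- n_skipped
    return(out)
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfrag <- vapply(toks, length, 0L) - 1L
  if (any(nfrag < 1L))
    stop(sprintf("cluster line %d has no fragments", which(nfrag < 1L)[1]))
  read_id <- vapply(toks, `[[`, "", 1L)
  frag <- unlist(lapply(toks, `[`, -1L), use.names = FALSE)
  m <- regmatches(frag, regexec("^([^:]+):([0-9]+)-([0-9]+)$", frag))
  bad <- which(vapply(m, length, 0L) != 4L)
  if (length(bad))
    stop("malformed fragment token: ", frag[bad[1]])
  chrom <- vapply(m, `[[`, "", 2L)
  start <- as.numeric(vapply(m, `[[`, "", 3L))
  end   <- as.numeric(vapply(m, `[[`, "", 4L))
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    stop(sprintf("fragment with start >= end: %s", frag[i]))
  }
  out <- data.frame(read = rep.int(seq_along(toks), nfrag),
                    read_id = rep.int(read_id, nfrag),
                    chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("cluster_frags", class(out))
  attr(out, "skipped") <- n_skipped
  out
}

#' One-record-per-read view of a cluster table
#' @param frags a `cluster_frags` data.frame from [read_cluster_file()].
#' @return list of `multiway_read` objects, each a list with `read_id` and a
#'   `fragments` data.frame (`chrom`, `start`, `end`).
#' @export
as_multiway_reads <- function(frags) {
  idx <- split(seq_len(nrow(frags)), frags$read)
  lapply(idx, function(i) {
    structure(list(read_id = frags$read_id[i[1]],
                   fragments = frags[i, c("chrom", "start", "end"),
                                     drop = FALSE]),
              class = "multiway_read")
  })
}

#' Write a cluster file
#' @param frags a `cluster_frags` data.frame.
#' @param path output path.
#' @export
write_cluster_file <- function(frags, path) {
  idx <- split(seq_len(nrow(frags)), frags$read)
  lines <- vapply(idx, function(i) {
    paste(c(frags$read_id[i[1]],
            sprintf("%s:%d-%d", frags$chrom[i],
                    as.integer(frags$start[i]), as.integer(frags$end[i]))),
          collapse = " ")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
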