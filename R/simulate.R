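#' Specification of a planted synthetic world
#'
#' Defines a small genome with alternating A/B compartment blocks, multi-way
#' reads that preferentially stay within one compartment, and epigenomic
#' peak tracks whose Poisson rates differ between compartments.  All
#' randomness flows from `seed`; an identical spec yields byte-identical
#' outputs.
#'
#' The defaults are the planted benchmark world used throughout the test
#' suite: 3 chromosomes x 200 bins of 1 Mb, 20,000 reads with
#' intra-compartment bias 0.8, and a compartment peak-rate difference of 4
#' on top of a baseline Poisson mean of 1.
#'
#' @param n_chroms number of chromosomes.
#' @param bins_per_chrom bins per chromosome.
#' @param bin_size bin width in bp.
#' @param n_reads number of multi-way reads to simulate.
#' @param order_distribution probability vector over read orders 2..8.
#'   Concentrated on 3-6 with a tail at 7-8 so that higher-order reads
#'   exercise the decomposition step.
#' @param intra_compartment_bias probability beta that all fragments of a
#'   read fall in the same compartment.
#' @param n_tracks number of epigenomic peak tracks; half are "active"
#'   (A-enriched), the other half B-enriched.
#' @param signal_effect difference between the compartment Poisson peak-count
#'   means (enriched mean = `mu_baseline + signal_effect`).
#' @param mu_baseline Poisson mean of the depleted compartment.
#' @param mean_block geometric mean compartment block length, in bins.
#' @param seed integer seed driving every draw.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chroms = 3L, bins_per_chrom = 200L,
                           bin_size = 1e6, n_reads = 20000L,
                           order_distribution = c(`2` = 0.05, `3` = 0.40,
                                                  `4` = 0.25, `5` = 0.15,
                                                  `6` = 0.08, `7` = 0.05,
                                                  `8` = 0.02),
                           intra_compartment_bias = 0.8,
                           n_tracks = 6L, signal_effect = 4,
                           mu_baseline = 1, mean_block = 10,
                           seed = 1L) {
  stopifnot(n_chroms >= 1, bins_per_chrom >= 1, bin_size > 0, n_reads >= 0,
            n_tracks >= 1, signal_effect >= 0, mu_baseline >= 0,
            mean_block >= 1)
  if (abs(sum(order_distribution) - 1) > 1e-8)
    stop("order_distribution must sum to 1")
  if (intra_compartment_bias < 0 || intra_compartment_bias > 1)
    stop("intra_compartment_bias must be in [0, 1]")
  structure(list(n_chroms = as.integer(n_chroms),
                 bins_per_chrom = as.integer(bins_per_chrom),
                 bin_size = bin_size, n_reads = as.integer(n_reads),
                 order_distribution = order_distribution,
                 intra_compartment_bias = intra_compartment_bias,
                 n_tracks = as.integer(n_tracks),
                 signal_effect = signal_effect, mu_baseline = mu_baseline,
                 mean_block = mean_block, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a genome with planted A/B compartments
#'
#' Compartment labels are laid down in alternating contiguous blocks whose
#' lengths are geometric with mean `mean_block` bins (support >= 1), which
#' mimics the mixed boundary bins of real compartment maps and keeps the
#' downstream PCA separation nontrivial.
#'
#' @param spec a [synthetic_spec].
#' @return list with `bins` (a [genome_bins]) and `labels` (character vector
#'   in `{"A","B"}`, one per bin).
#' @export
simulate_genome <- function(spec) {
  bins <- genome_bins(paste0("chr", seq_len(spec$n_chroms)),
                      rep(spec$bins_per_chrom * spec$bin_size, spec$n_chroms),
                      spec$bin_size)
  set.seed(spec$seed)
  labels <- character(bins$n_bins)
  for (c in seq_len(spec$n_chroms)) {
    n <- spec$bins_per_chrom
    cur <- sample(c("A", "B"), 1L)
    filled <- 0L
    lab <- character(n)
    while (filled < n) {
      len <- 1L + stats::rgeom(1L, prob = 1 / spec$mean_block)
      len <- min(len, n - filled)
      lab[(filled + 1L):(filled + len)] <- cur
      filled <- filled + len
      cur <- if (cur == "A") "B" else "A"
    }
    labels[(bins$offsets[c] + 1L):(bins$offsets[c] + n)] <- lab
  }
  list(bins = bins, labels = labels)
}

#' Simulate multi-way reads with intra-compartment bias
#'
#' For each read an order k is drawn from the order distribution; with
#' probability beta all k bins are drawn (without replacement) from a single
#' compartment -- chosen with probability proportional to its size so that
#' per-bin coverage stays uniform -- otherwise uniformly from all bins.
#' Each chosen bin becomes a short fragment around the bin midpoint.
#'
#' @param bins a [genome_bins].
#' @param labels per-bin compartment labels.
#' @param spec a [synthetic_spec].
#' @param path if non-NULL, the reads are also written as a cluster file.
#' @return a `cluster_frags` data.frame (invisibly written to `path` when
#'   given), with attribute `tuples`: the true bin tuple of each read.
#' @export
simulate_multiway_reads <- function(bins, labels, spec, path = NULL) {
  if (length(labels) != bins$n_bins)
    stop("labels length must equal n_bins")
  set.seed(spec$seed + 1L)
  n <- spec$n_reads
  orders <- as.integer(names(spec$order_distribution))
  pool_a <- which(labels == "A"); pool_b <- which(labels == "B")
  q <- length(pool_a) / bins$n_bins
  if (n == 0L) {
    frags <- data.frame(read = integer(), read_id = character(),
                        chrom = character(), start = numeric(),
                        end = numeric())
    class(frags) <- c("cluster_frags", class(frags))
    attr(frags, "tuples") <- list()
    if (!is.null(path)) writeLines(character(0), path)
    return(frags)
  }
  k_all <- orders[sample.int(length(orders), n, replace = TRUE,
                             prob = spec$order_distribution)]
  same <- stats::runif(n) < spec$intra_compartment_bias
  comp_a <- stats::runif(n) < q
  tuples <- vector("list", n)
  for (r in seq_len(n)) {
    pool <- if (!same[r]) seq_len(bins$n_bins)
            else if (comp_a[r]) pool_a else pool_b
    k <- min(k_all[r], length(pool))   # resample rule: clip to pool size
    tuples[[r]] <- sort(sample(pool, k))
  }
  iv <- bin_interval(bins, unlist(tuples, use.names = FALSE))
  mid <- floor((iv$start + iv$end) / 2)
  half <- 100L   # 200 bp fragments centred on the bin midpoint
  frags <- data.frame(read = rep.int(seq_len(n), lengths(tuples)),
                      read_id = rep.int(sprintf("read%06d", seq_len(n)),
                                        lengths(tuples)),
                      chrom = iv$chrom,
                      start = pmax(mid - half, iv$start),
                      end = pmin(mid + half, iv$end),
                      stringsAsFactors = FALSE)
  class(frags) <- c("cluster_frags", class(frags))
  attr(frags, "tuples") <- tuples
  if (!is.null(path)) write_cluster_file(frags, path)
  frags
}

#' Simulate epigenomic peak tracks
#'
#' Per track and per bin a peak count is drawn from a Poisson whose mean is
#' `mu_baseline + signal_effect` in the enriched compartment and
#' `mu_baseline` in the other; the first half of the tracks is A-enriched
#' ("active" marks), the second half B-enriched.  Peaks are written as
#' 200 bp BED intervals placed uniformly inside their bin.
#'
#' @param bins a [genome_bins].
#' @param labels per-bin compartment labels.
#' @param spec a [synthetic_spec].
#' @param dir if non-NULL, one BED file per track is written there.
#' @return list with `counts` (N x n_tracks integer matrix), `track_names`,
#'   and `paths` (NULL unless `dir` given).
#' @export
simulate_peaks <- function(bins, labels, spec, dir = NULL) {
  set.seed(spec$seed + 2L)
  n <- bins$n_bins
  is_a <- labels == "A"
  counts <- matrix(0L, n, spec$n_tracks)
  track_names <- sprintf("track%02d", seq_len(spec$n_tracks))
  a_enriched <- seq_len(spec$n_tracks) <= spec$n_tracks / 2
  for (t in seq_len(spec$n_tracks)) {
    mu_a <- spec$mu_baseline + if (a_enriched[t]) spec$signal_effect else 0
    mu_b <- spec$mu_baseline + if (a_enriched[t]) 0 else spec$signal_effect
    counts[, t] <- stats::rpois(n, ifelse(is_a, mu_a, mu_b))
  }
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    iv <- bin_interval(bins, seq_len(n))
    paths <- file.path(dir, paste0(track_names, ".bed"))
    for (t in seq_len(spec$n_tracks)) {
      reps <- counts[, t]
      b <- rep.int(seq_len(n), reps)
      width <- 200L
      room <- (iv$end - iv$start)[b] - width
      start <- iv$start[b] + floor(stats::runif(length(b)) * pmax(room, 1))
      utils::write.table(
        data.frame(iv$chrom[b], as.integer(start), as.integer(start + width),
                   sprintf("%s_peak%d", track_names[t], seq_along(b))),
        paths[t], sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    }
  }
  list(counts = counts, track_names = track_names, paths = paths)
}

#' Write a full synthetic dataset to a directory
#'
#' Produces `chrom.sizes`, `labels.tsv` (0-based bin id, compartment),
#' `clusters.txt` and a `tracks/` directory of BED files.
#'
#' @param spec a [synthetic_spec].
#' @param dir output directory (created if needed).
#' @return invisible list of the generated in-memory objects.
#' @export
simulate_dataset <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- simulate_genome(spec)
  write_chrom_sizes(g$bins, file.path(dir, "chrom.sizes"))
  utils::write.table(data.frame(bin = seq_len(g$bins$n_bins) - 1L,
                                label = g$labels),
                     file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  frags <- simulate_multiway_reads(g$bins, g$labels, spec,
                                   path = file.path(dir, "clusters.txt"))
  peaks <- simulate_peaks(g$bins, g$labels, spec,
                          dir = file.path(dir, "tracks"))
  invisible(list(bins = g$bins, labels = g$labels, frags = frags,
                 peaks = peaks))
}
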