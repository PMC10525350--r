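#' End-to-end pipeline on a planted synthetic world
#'
#' Runs the complete chain on data from [synthetic_spec()]: simulate genome,
#' compartments, multi-way reads and peak tracks; bin and decompose the
#' reads into candidate hyperedges; frequency-filter the positives; corrupt
#' them into 2:1 negatives; encode peak-count features with the stacked
#' autoencoder; split stratified folds; build the coupling hypergraph from
#' the training-fold positives only; train the scorer and evaluate it on
#' the held-out fold.
#'
#' Frequency thresholds default to 2 for every order: at desk scale the
#' recurrence filter plays the same balancing role as the
#' per-order thresholds used on deep real data, retaining tuples observed
#' in at least two reads.
#'
#' @param spec a [synthetic_spec].
#' @param thresholds named per-order frequency thresholds.
#' @param config a [train_config].
#' @param cfg an [mci_config]; defaults to the 64-d dual-channel scorer.
#' @param sae_epochs autoencoder pre-training epochs per layer.
#' @param sae_widths autoencoder layer widths; the last width must equal
#'   `cfg$d`.
#' @param test_fold which of the `config$folds` folds to hold out.
#' @param ratio negatives per positive.
#' @param window corruption window half-width in bins.
#' @return list with the intermediate artifacts (`bins`, `labels`, `edges`,
#'   `samples`, `features`, `sae`, `emb`, `folds`), the trained `model`,
#'   the held-out `report` and its overall `auc`.
#' @export
mci_pipeline <- function(spec = synthetic_spec(),
                         thresholds = c(`3` = 2, `4` = 2, `5` = 2, `6` = 2),
                         config = train_config(epochs = 20L,
                                               seed = spec$seed),
                         cfg = mci_config(),
                         sae_epochs = 50L, sae_widths = c(128L, cfg$d),
                         test_fold = 1L, ratio = 2L, window = 20L) {
  if (utils::tail(sae_widths, 1L) != cfg$d)
    stop("the last autoencoder width must equal the model dimension")
  g <- simulate_genome(spec)
  frags <- simulate_multiway_reads(g$bins, g$labels, spec)
  tuples <- bin_cluster(frags, g$bins)
  edges <- count_and_filter(tuples, thresholds)
  if (!nrow(edges))
    stop("no positive hyperedges survive the frequency thresholds")
  samples <- build_dataset(edges, g$bins, ratio = ratio, window = window,
                           seed = spec$seed)
  peaks <- simulate_peaks(g$bins, g$labels, spec)
  features <- feature_table_from_counts(peaks$counts, peaks$track_names)
  sae <- train_sae(features, widths = sae_widths, epochs = sae_epochs,
                   seed = spec$seed)
  emb <- sae_encode(sae, features)
  folds <- kfold_split(samples, k = config$folds, seed = config$seed)
  tr <- samples[folds[[test_fold]]$train, , drop = FALSE]
  te <- samples[folds[[test_fold]]$test, , drop = FALSE]
  graph <- if (cfg$use_che) build_hypergraph(.positives_of(tr),
                                             g$bins$n_bins) else NULL
  model <- train_mci(tr, emb, graph, config, cfg)
  report <- evaluate_mci(model, te)
  list(bins = g$bins, labels = g$labels, frags = frags, edges = edges,
       samples = samples, features = features, sae = sae, emb = emb,
       folds = folds, train = tr, test = te, model = model,
       report = report, auc = report$auc[report$slice == "all"])
}

#' Noise-injection denoising experiment
#'
#' Simulates a clean compartment-biased read set, adds a fraction of
#' uniformly random noise reads, and compares the pairwise contact matrix
#' before and after likelihood denoising against the noise-free ground
#' truth (Pearson correlation on off-diagonal upper-triangle entries).
#'
#' @param pipe result of [mci_pipeline()] (supplies the trained model and
#'   the clean reads).
#' @param spec the [synthetic_spec] the pipeline used.
#' @param noise_fraction noise reads as a fraction of clean reads.
#' @return list with `cor_noisy`, `cor_denoised`, `likelihood`, and the
#'   three contact matrices.
#' @export
denoise_experiment <- function(pipe, spec, noise_fraction = 0.3) {
  clean_cm <- reads_to_contacts(pipe$frags, pipe$bins)
  noise_spec <- spec
  noise_spec$n_reads <- as.integer(round(spec$n_reads * noise_fraction))
  noise_spec$intra_compartment_bias <- 0   # uniformly random ligation noise
  noise_spec$seed <- spec$seed + 1000L
  noise <- simulate_multiway_reads(pipe$bins, pipe$labels, noise_spec)
  noise$read <- noise$read + max(pipe$frags$read)
  all_frags <- rbind(pipe$frags, noise)
  class(all_frags) <- class(pipe$frags)
  noisy_cm <- reads_to_contacts(all_frags, pipe$bins)
  lik <- pairwise_likelihood(pipe$model, pipe$bins)
  den_cm <- denoise_contacts(lik, noisy_cm)
  ut <- upper.tri(matrix(0, pipe$bins$n_bins, pipe$bins$n_bins))
  ref <- as.matrix(clean_cm$values)[ut]
  nv <- as.matrix(noisy_cm$values)[ut]
  dv <- as.matrix(den_cm$values)[ut]
  list(cor_noisy = stats::cor(nv, ref),
       cor_denoised = stats::cor(dv, ref),
       cor_noisy_spearman = stats::cor(nv, ref, method = "spearman"),
       cor_denoised_spearman = stats::cor(dv, ref, method = "spearman"),
       likelihood = lik, clean = clean_cm, noisy = noisy_cm,
       denoised = den_cm)
}

#' Save / load a model checkpoint
#'
#' Serialized with a format version and a configuration echo so stale
#' checkpoints fail loudly.
#'
#' @param model an `mci_model`.
#' @param path checkpoint path (RDS).
#' @export
save_mci <- function(model, path) {
  saveRDS(list(format = "hypermci-ckpt-1", cfg = model$cfg, model = model),
          path)
  invisible(path)
}

#' @rdname save_mci
#' @export
load_mci <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "hypermci-ckpt-1"))
    stop("not a recognized model checkpoint: ", path)
  x$model
}
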