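#' Stratified k-fold split
#'
#' Partitions sample indices into k folds, stratified jointly by label and
#' tuple order so every fold preserves the 2:1 class balance and the
#' per-order composition.  Fold sizes differ by at most one.
#'
#' @param samples a `labeled_samples` data.frame.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return list of k lists, each with integer vectors `train` and `test`.
#' @export
kfold_split <- function(samples, k = 5L, seed = 1L) {
  n <- nrow(samples)
  if (n < k) stop("fewer samples than folds")
  set.seed(seed)
  fold <- integer(n)
  strata <- split(seq_len(n), paste0(samples$label, ":", samples$order))
  ptr <- 0L  # global rotating pointer keeps overall fold sizes within 1
  for (g in strata) {
    g <- g[sample.int(length(g))]
    fold[g] <- (ptr + seq_along(g) - 1L) %% k + 1L
    ptr <- (ptr + length(g)) %% k
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

#' Area under the ROC curve
#'
#' Rank-based (equivalent to the Wilcoxon statistic): concordant pairs
#' count 1, ties 1/2.  Returns NA when the labels are single-class.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return AUC in `[0, 1]`, or NA.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  n1 <- as.numeric(n1); n0 <- as.numeric(n0)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision: sum over score-descending positives of precision
#' times the recall increment, with tied scores grouped.
#'
#' @inheritParams auc_score
#' @return AUPR in `(0, 1]`, or NA for single-class labels.
#' @export
aupr_score <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0L || n1 == length(labels)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  grp <- cumsum(!duplicated(sc))
  tp_g <- tapply(lab, grp, sum)
  n_g <- tapply(rep(1, length(lab)), grp, sum)
  tp <- cumsum(tp_g); np <- cumsum(n_g)
  prec <- tp / np
  rec <- tp / n1
  sum(prec * diff(c(0, rec)))
}

#' Classification metrics report
#'
#' Computes AUC, AUPR, accuracy, precision, recall and F1 at threshold
#' `t = 0.5`, overall and per tuple order.
#'
#' @param scores predicted probabilities.
#' @param labels binary labels.
#' @param orders optional tuple orders for the per-order slices.
#' @param t binarization threshold.
#' @return data.frame with one row per slice (`"all"` plus each order).
#' @export
metrics_report <- function(scores, labels, orders = NULL, t = 0.5) {
  one <- function(sc, y, name) {
    pred <- classify(sc, t)
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    fn <- sum(pred == 0 & y == 1)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec)
          else NA_real_
    data.frame(slice = name, n = length(y),
               auc = auc_score(sc, y), aupr = aupr_score(sc, y),
               accuracy = mean(pred == y), precision = prec, recall = rec,
               f1 = f1, stringsAsFactors = FALSE)
  }
  out <- one(scores, labels, "all")
  if (!is.null(orders))
    for (k in sort(unique(orders))) {
      i <- orders == k
      out <- rbind(out, one(scores[i], labels[i], as.character(k)))
    }
  rownames(out) <- NULL
  out
}

#' Training configuration
#'
#' Defaults follow the tuned values for deep multi-way contact data:
#' batch size 96, dropout 0.4, Adam learning rate 1e-3, 200 epochs.
#'
#' @param batch_size minibatch size s.
#' @param dropout dropout rate d.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param lambda_kl KL alignment weight.
#' @param seed RNG seed for initialization, batching and dropout.
#' @param folds CV fold count.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 96L, dropout = 0.4, lr = 1e-3,
                         epochs = 200L, lambda_kl = 1.0, seed = 1L,
                         folds = 5L) {
  stopifnot(batch_size >= 1, dropout >= 0, dropout < 1, lr > 0, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), dropout = dropout,
                 lr = lr, epochs = as.integer(epochs),
                 lambda_kl = lambda_kl, seed = as.integer(seed),
                 folds = as.integer(folds)), class = "train_config")
}

#' Train the hyperedge scorer
#'
#' Minibatch Adam on binary cross-entropy plus the KL alignment loss.  The
#' structural channel's incidence matrix should be built from training-fold
#' positives only (the caller controls `graph`) to avoid label leakage.
#' When a validation set is supplied the parameters of the best epoch by
#' validation loss are returned; otherwise the final epoch's.
#'
#' @param samples training `labeled_samples`.
#' @param emb N x d vertex embedding matrix from [sae_encode()].
#' @param graph a `hypergraph` over the training positives (used by the
#'   coupling channel; may be NULL when `cfg$use_che` is FALSE).
#' @param config a [train_config].
#' @param cfg an [mci_config]; its `dropout`/`lambda_kl` are overridden by
#'   `config` for consistency.
#' @param val_samples optional validation `labeled_samples`.
#' @return an `mci_model`: list with `params`, `cfg`, `emb`, `graph_op`,
#'   `loss_curve` (per-epoch training loss), `val_curve`, `best_epoch`.
#' @export
train_mci <- function(samples, emb, graph, config = train_config(),
                      cfg = mci_config(d = ncol(emb)), val_samples = NULL) {
  if (max(unlist(samples$bins)) > nrow(emb))
    stop("embeddings do not cover all vertex ids")
  cfg$dropout <- config$dropout
  cfg$lambda_kl <- config$lambda_kl
  op <- if (cfg$use_che) {
    if (is.null(graph)) stop("coupling channel requires a hypergraph")
    hconv_operator(graph)
  } else NULL
  params <- mci_init(cfg, seed = config$seed)
  st <- .adam_init(params)
  set.seed(config$seed + 1L)
  n <- nrow(samples)
  loss_curve <- numeric(config$epochs)
  val_curve <- rep(NA_real_, config$epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    ordr <- sample.int(n)
    tot <- 0
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ordr[s:min(s + config$batch_size - 1L, n)]
      batch <- build_batch(samples[idx, , drop = FALSE], emb, cfg$max_order)
      dm <- .draw_dropout(batch, cfg)
      res <- .mci_loss_grads(params, cfg, batch, op, emb, dm)
      if (!is.finite(res$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      tot <- tot + res$loss * length(idx)
      upd <- .adam_step(params, res$grads, st, config$lr)
      params <- upd$params; st <- upd$state
    }
    loss_curve[ep] <- tot / n
    if (!is.null(val_samples)) {
      model_ep <- structure(list(params = params, cfg = cfg, emb = emb,
                                 graph_op = op), class = "mci_model")
      pv <- predict_mci(model_ep, val_samples)
      val_curve[ep] <- as.numeric(total_loss(pv, val_samples$label, 0, 0))
      if (val_curve[ep] < best$loss)
        best <- list(loss = val_curve[ep], params = params, epoch = ep)
    }
  }
  final <- if (!is.null(val_samples) && best$epoch > 0L) best$params
           else params
  structure(list(params = final, cfg = cfg, emb = emb, graph_op = op,
                 loss_curve = loss_curve, val_curve = val_curve,
                 best_epoch = if (!is.null(val_samples)) best$epoch
                              else config$epochs),
            class = "mci_model")
}

#' @export
print.mci_model <- function(x, ...) {
  cat(sprintf(paste0("<mci_model> d = %d, heads = %d, channels:%s%s, ",
                     "trained %d epoch(s)\n"),
              x$cfg$d, x$cfg$n_heads,
              if (x$cfg$use_she) " separating" else "",
              if (x$cfg$use_che) " coupling" else "",
              length(x$loss_curve)))
  invisible(x)
}

#' Evaluate a trained model on labeled samples
#'
#' @param model an `mci_model`.
#' @param samples test `labeled_samples`.
#' @return a [metrics_report()] data.frame (AUC is NA, not 0, on a
#'   single-class test set).
#' @export
evaluate_mci <- function(model, samples) {
  p <- predict_mci(model, samples)
  metrics_report(p, samples$label, samples$order)
}

#' Cross-validated training
#'
#' Runs `config$folds`-fold CV: per fold, the coupling-channel hypergraph is
#' rebuilt from the training-fold positives only, the model trained on the
#' training fold and evaluated on the held-out fold.
#'
#' @param samples full `labeled_samples`.
#' @param emb vertex embeddings.
#' @param bins a [genome_bins] (for the per-fold hypergraph dimensions).
#' @param config a [train_config].
#' @param cfg an [mci_config].
#' @return list with `fold_metrics` (list of reports), `mean_auc`,
#'   `mean_aupr`, and `models`.
#' @export
cv_mci <- function(samples, emb, bins, config = train_config(),
                   cfg = mci_config(d = ncol(emb))) {
  folds <- kfold_split(samples, k = config$folds, seed = config$seed)
  reports <- vector("list", length(folds))
  models <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- samples[folds[[f]]$train, , drop = FALSE]
    te <- samples[folds[[f]]$test, , drop = FALSE]
    graph <- if (cfg$use_che)
      build_hypergraph(.positives_of(tr), bins$n_bins) else NULL
    m <- train_mci(tr, emb, graph, config, cfg)
    models[[f]] <- m
    reports[[f]] <- evaluate_mci(m, te)
  }
  aucs <- vapply(reports, function(r) r$auc[r$slice == "all"], 0)
  auprs <- vapply(reports, function(r) r$aupr[r$slice == "all"], 0)
  list(fold_metrics = reports, mean_auc = mean(aucs),
       mean_aupr = mean(auprs), models = models)
}

.positives_of <- function(samples) {
  pos <- samples[samples$label == 1L, , drop = FALSE]
  d <- data.frame(key = pos$key, order = pos$order,
                  frequency = rep(1L, nrow(pos)), stringsAsFactors = FALSE)
  d$bins <- pos$bins
  structure(d, class = c("hyperedge_set", "data.frame"))
}

#' Hyperparameter grid search
#'
#' Evaluates the full Cartesian product of batch-size, dropout and
#' learning-rate grids by k-fold CV and reports mean AUC per configuration.
#' The conventional grids are `s in {64, 96, 128}`,
#' `d in {0.1, 0.2, 0.3, 0.4, 0.5}`, `lr in {1e-4, 5e-4, 1e-3, 5e-3, 1e-2}`.
#'
#' @param samples full `labeled_samples`.
#' @param emb vertex embeddings.
#' @param bins a [genome_bins].
#' @param batch_sizes,dropouts,lrs grid values.
#' @param epochs,folds,seed shared training settings.
#' @param dry_run if TRUE, return the enumerated configuration table
#'   without training (for inspecting the grid).
#' @param cfg an [mci_config].
#' @return data.frame of all configurations with `mean_auc`/`mean_aupr`,
#'   sorted by mean AUC; attribute `best` holds the argmax row.
#' @export
grid_search <- function(samples, emb, bins,
                        batch_sizes = c(64L, 96L, 128L),
                        dropouts = c(0.1, 0.2, 0.3, 0.4, 0.5),
                        lrs = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2),
                        epochs = 200L, folds = 5L, seed = 1L,
                        cfg = mci_config(d = ncol(emb)), dry_run = FALSE) {
  stopifnot(length(batch_sizes) > 0, length(dropouts) > 0, length(lrs) > 0)
  grid <- expand.grid(batch_size = batch_sizes, dropout = dropouts,
                      lr = lrs, KEEP.OUT.ATTRS = FALSE)
  grid$mean_auc <- grid$mean_aupr <- NA_real_
  if (dry_run) return(grid)
  for (i in seq_len(nrow(grid))) {
    config <- train_config(grid$batch_size[i], grid$dropout[i], grid$lr[i],
                           epochs = epochs, seed = seed, folds = folds)
    res <- cv_mci(samples, emb, bins, config, cfg)
    grid$mean_auc[i] <- res$mean_auc
    grid$mean_aupr[i] <- res$mean_aupr
  }
  o <- order(-grid$mean_auc)
  out <- grid[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "best") <- out[1L, , drop = FALSE]
  out
}
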