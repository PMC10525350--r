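test_that("stratified folds partition the samples evenly", {
  set.seed(2)
  samp <- sample_set(lapply(1:10, function(i) sort(sample.int(50L, 3L))),
                     rep(c(1, 0), 5))
  folds <- kfold_split(samp, k = 5L, seed = 1L)
  tests <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(tests) == 2L))
  expect_setequal(unlist(tests), 1:10)          # each sample in one test fold
  for (f in folds)
    expect_setequal(c(f$train, f$test), 1:10)

  expect_error(kfold_split(samp[1:3, ], k = 5L), "fewer samples")

  # stratification at n = 1500 with a 1:2 label ratio
  set.seed(3)
  big <- sample_set(lapply(1:1500, function(i)
    sort(sample.int(300L, sample(3:6, 1L)))),
    rep(c(1, 0, 0), 500))
  bf <- kfold_split(big, k = 5L, seed = 2L)
  for (f in bf) {
    frac <- mean(big$label[f$test] == 1)
    expect_lt(abs(frac - 1 / 3), 0.05)
  }
  expect_lte(diff(range(lengths(lapply(bf, `[[`, "test")))), 1L)
})

test_that("AUC equals the brute-force concordant-pair count", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 100L
    y <- rbinom(n, 1, 0.4)
    sc <- round(runif(n), 2)             # rounding forces ties
    pos <- which(y == 1); neg <- which(y == 0)
    conc <- 0
    for (i in pos) for (j in neg)
      conc <- conc + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
    expect_equal(auc_score(sc, y), conc / (length(pos) * length(neg)))
  }
  expect_true(is.na(auc_score(runif(5), rep(1, 5))))
})

test_that("threshold-free and thresholded metrics behave analytically", {
  y <- c(rep(1, 30), rep(0, 70))
  perfect <- c(runif(30, 0.6, 1), runif(70, 0, 0.4))
  rep1 <- metrics_report(perfect, y)
  expect_equal(rep1$auc[1], 1)
  expect_equal(rep1$aupr[1], 1)

  set.seed(6)
  y2 <- rbinom(1e4, 1, 0.5)
  null_auc <- auc_score(runif(1e4), y2)
  expect_lt(abs(null_auc - 0.5), 0.02)

  # all predicted positive: recall 1, precision = base rate
  allpos <- metrics_report(rep(0.9, 100), y)
  expect_equal(allpos$recall[1], 1)
  expect_equal(allpos$precision[1], 0.3)
})

test_that("training reduces the loss and is seed-deterministic", {
  set.seed(20)
  N <- 40L; d <- 8L
  emb <- matrix(rnorm(N * d), N, d)
  # planted rule: tuples inside 1..20 are positive, straddling ones negative
  pos <- lapply(1:60, function(i) sort(sample(1:20, 3)))
  neg <- lapply(1:60, function(i) sort(c(sample(1:20, 1), sample(21:40, 2))))
  samp <- sample_set(c(pos, neg), rep(c(1, 0), each = 60))
  graph <- build_hypergraph(edge_set(pos), N)
  cfg <- mci_config(d = d, n_heads = 2L)
  config <- train_config(batch_size = 32L, epochs = 15L, lr = 3e-3,
                         dropout = 0.1, seed = 7L)
  m <- train_mci(samp, emb, graph, config, cfg)
  expect_lt(tail(m$loss_curve, 1), m$loss_curve[1])

  m2 <- train_mci(samp, emb, graph, config, cfg)
  expect_identical(m$params, m2$params)
  p <- predict_mci(m, samp)
  expect_identical(p, predict_mci(m2, samp))
  expect_gt(auc_score(p, samp$label), 0.9)      # the rule is learnable

  # validation-based best-epoch selection records the curve
  m3 <- train_mci(samp[1:80, ], emb, graph,
                  train_config(batch_size = 32L, epochs = 5L, seed = 7L),
                  cfg, val_samples = samp[81:120, ])
  expect_true(all(is.finite(m3$val_curve)))
  expect_gte(m3$best_epoch, 1L)
})

test_that("single-class evaluation reports NA, not zero", {
  s <- planted_mini()
  one_class <- s$test[s$test$label == 1, ][1:5, ]
  rep <- evaluate_mci(s$model, one_class)
  expect_true(is.na(rep$auc[1]))
  expect_true(is.na(rep$aupr[1]))
})

test_that("grid search enumerates the Cartesian product and ranks by AUC", {
  # the conventional grids: 3 x 5 x 5 = 75 configurations
  grid <- grid_search(NULL, NULL, NULL, dry_run = TRUE)
  expect_equal(nrow(grid), 75L)
  expect_equal(nrow(unique(grid[, 1:3])), 75L)

  # a real (tiny) search: singleton x two learning rates
  set.seed(30)
  N <- 30L; d <- 6L
  emb <- matrix(rnorm(N * d), N, d)
  pos <- lapply(1:40, function(i) sort(sample(1:15, 3)))
  neg <- lapply(1:40, function(i) sort(sample(16:30, 3)))
  samp <- sample_set(c(pos, neg), rep(c(1, 0), each = 40))
  bins <- genome_bins("chr1", N * 1e6, 1e6)
  out <- grid_search(samp, emb, bins, batch_sizes = 32L, dropouts = 0.1,
                     lrs = c(1e-3, 5e-3), epochs = 3L, folds = 2L,
                     seed = 1L, cfg = mci_config(d = d, n_heads = 2L))
  expect_equal(nrow(out), 2L)
  expect_equal(out$mean_auc[1], max(out$mean_auc))
  expect_equal(attr(out, "best")$lr, out$lr[1])

  singleton <- grid_search(samp, emb, bins, batch_sizes = 32L,
                           dropouts = 0.1, lrs = 1e-3, epochs = 2L,
                           folds = 2L, seed = 1L,
                           cfg = mci_config(d = d, n_heads = 2L))
  expect_equal(nrow(singleton), 1L)
})
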