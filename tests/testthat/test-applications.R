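test_that("pairwise likelihood is symmetric, bounded, unit-diagonal", {
  small_bins <- genome_bins("chr1", 5e6, 1e6)
  set.seed(44)
  cfg <- mci_config(d = 8L, n_heads = 2L)
  mini <- structure(list(
    params = mci_init(cfg, 44L), cfg = cfg,
    emb = matrix(rnorm(40), 5, 8),
    graph_op = hconv_operator(
      build_hypergraph(edge_set(list(c(1L, 2L, 3L), c(2L, 4L, 5L))), 5L))),
    class = "mci_model")
  lik <- pairwise_likelihood(mini, small_bins)
  expect_equal(attr(lik, "n_evaluations"), choose(5, 2))
  expect_equal(lik$values, t(lik$values))
  expect_true(all(lik$values >= 0 & lik$values <= 1))
  expect_equal(diag(lik$values), rep(1, 5))
})

test_that("denoising is the entrywise product and never increases", {
  b <- genome_bins("chr1", 20e6, 1e6)
  set.seed(14)
  raw <- matrix(rpois(400, 2), 20, 20)
  cm <- contact_matrix(raw + t(raw), b)

  ones <- structure(list(values = matrix(1, 20, 20), bins = b),
                    class = "likelihood_matrix")
  expect_equal(as.matrix(denoise_contacts(ones, cm)$values),
               as.matrix(cm$values), ignore_attr = TRUE)

  diag_only <- structure(list(values = diag(20), bins = b),
                         class = "likelihood_matrix")
  d <- as.matrix(denoise_contacts(diag_only, cm)$values)
  expect_true(all(d[upper.tri(d)] == 0))

  lv <- matrix(runif(400), 20, 20); lv <- (lv + t(lv)) / 2; diag(lv) <- 1
  lik <- structure(list(values = lv, bins = b), class = "likelihood_matrix")
  got <- as.matrix(denoise_contacts(lik, cm)$values)
  want <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)                 # brute-force loop oracle
    want[i, j] <- lv[i, j] * as.matrix(cm$values)[i, j]
  expect_equal(got, want, ignore_attr = TRUE)
  expect_true(all(got <= as.matrix(cm$values) + 1e-12))

  wrong <- contact_matrix(matrix(0, 5, 5), genome_bins("chr1", 5e6, 1e6))
  expect_error(denoise_contacts(lik, wrong), "dimension")
})

test_that("embedding extraction has the contracted shapes", {
  s <- planted_mini()
  d <- s$model$cfg$d
  N <- s$bins$n_bins
  fused <- extract_embeddings(s$model)
  expect_equal(dim(fused), c(N, d))
  expect_true(all(is.finite(fused)))
  expect_identical(fused, extract_embeddings(s$model))

  pre <- extract_embeddings(s$model, stage = "concat")
  expect_equal(dim(pre), c(N, 2L * d))

  # an untrained model still produces finite embeddings of full shape
  cfg <- mci_config(d = 16L, n_heads = 2L)
  raw <- structure(list(params = mci_init(cfg, 5L), cfg = cfg,
                        emb = matrix(rnorm(10 * 16), 10, 16),
                        graph_op = hconv_operator(
                          build_hypergraph(edge_set(list(c(1L, 2L, 3L))),
                                           10L))),
                   class = "mci_model")
  expect_true(all(is.finite(extract_embeddings(raw))))
})

test_that("PCA separates planted clouds and respects its contracts", {
  set.seed(15)
  cloud <- rbind(matrix(rnorm(200 * 4, mean = 0), 200, 4),
                 matrix(rnorm(200 * 4, mean = 3), 200, 4))
  lab <- rep(c("A", "B"), each = 200)
  pc <- pca_compartments(cloud, labels = lab)
  expect_gt(pc$separation_auc, 0.95)

  # 2-d mean-centered input with orthogonal axes: projection is a rotation
  set.seed(16)
  xy <- scale(matrix(rnorm(100 * 2), 100, 2), scale = FALSE)
  rot <- pca_compartments(xy, n_components = 2L)$projection
  expect_equal(as.matrix(dist(rot)), as.matrix(dist(xy)), tolerance = 1e-8)

  no_labels <- pca_compartments(cloud)
  expect_null(no_labels$separation_auc)

  expect_error(pca_compartments(matrix(1, 50, 3)), "constant")

  # sub-compartment labels collapse to their A/B prefix
  pc2 <- pca_compartments(cloud, labels = rep(c("A1", "B3"), each = 200))
  expect_equal(pc2$separation_auc, pc$separation_auc)
})

test_that("model checkpoints round-trip through disk", {
  s <- planted_mini()
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_mci(s$model, f)
  back <- load_mci(f)
  expect_identical(back$params, s$model$params)
  p1 <- predict_mci(s$model, s$test[1:10, ])
  expect_identical(predict_mci(back, s$test[1:10, ]), p1)

  bad <- withr::local_tempfile()
  saveRDS(list(format = "other"), bad)
  expect_error(load_mci(bad), "checkpoint")
})
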