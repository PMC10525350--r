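# shared tiny fixtures for the scorer tests
tiny_setup <- function(seed = 1, d = 8L, n_heads = 2L, N = 12L, ...) {
  set.seed(seed)
  cfg <- mci_config(d = d, n_heads = n_heads, dropout = 0, ...)
  params <- mci_init(cfg, seed = seed)
  emb <- matrix(rnorm(N * d), N, d)
  hg <- rand_hypergraph(N, 5L, seed)
  op <- hconv_operator(build_hypergraph(hg$edges, N))
  list(cfg = cfg, params = params, emb = emb, op = op, N = N)
}

test_that("attention rows are a softmax over the other real vertices", {
  s <- tiny_setup()
  samp <- sample_set(list(c(1L, 2L, 3L), c(2L, 5L, 7L, 9L),
                          c(1L, 4L, 6L, 8L, 10L, 11L)), c(1, 0, 1))
  batch <- build_batch(samp, s$emb)
  att <- attention_embed(batch, s$params, s$cfg)
  for (h in seq_len(s$cfg$n_heads))
    for (i in 1:6) {
      a <- att$alpha[[h]][[i]]
      expect_true(all(a >= 0))
      expect_equal(a[, i], rep(0, 3))            # no self-attention
      rs <- rowSums(a)
      expect_equal(rs[batch$mask[, i] == 1], rep(1, sum(batch$mask[, i])))
      expect_equal(rs[batch$mask[, i] == 0], rep(0, sum(batch$mask[, i] == 0)))
      # padded columns receive no weight
      expect_true(all(a[, batch$mask[1, ] == 0][1, ] == 0))
    }
  for (i in 1:6)
    expect_true(all(abs(att$Ed[[i]]) < 1))       # tanh range
})

test_that("attention matches a pencil-and-paper evaluation in 2-d", {
  cfg <- mci_config(d = 2L, n_heads = 1L, dropout = 0)
  x <- matrix(c(0.5, -1, 1, 2, -0.3, 0.7), 3, 2, byrow = TRUE)
  Wq <- matrix(c(1, 0.5, -0.5, 1), 2, 2)
  Wk <- matrix(c(0.3, -1, 1, 0.2), 2, 2)
  Wv <- matrix(c(1, 0, 0, -1), 2, 2)
  params <- list(Wq = Wq, Wk = Wk, Wv = Wv, Wo = diag(2))
  samp <- sample_set(list(c(1L, 2L, 3L)), 1)
  batch <- build_batch(samp, x)
  got <- attention_embed(batch, params, cfg)

  # hand evaluation with explicit loops
  q <- x %*% Wq; k <- x %*% Wk; v <- x %*% Wv
  for (i in 1:3) {
    e <- sapply(1:3, function(j) sum(q[i, ] * k[j, ]))
    js <- setdiff(1:3, i)
    a <- exp(e[js]) / sum(exp(e[js]))
    ed <- tanh(colSums(a * v[js, ]))
    expect_equal(as.vector(got$Ed[[i]]), ed, tolerance = 1e-12)
    expect_equal(as.vector(got$alpha[[1]][[i]][, js]), a, tolerance = 1e-12)
  }
})

test_that("the MLP view is per-vertex and matches hand evaluation", {
  cfg <- mci_config(d = 2L, n_heads = 1L, dropout = 0)
  x1 <- c(0.3, -0.8)
  W1 <- matrix(c(1, -0.5, 0.2, 1), 2, 2); b1 <- c(0.1, -0.2)
  W2 <- matrix(c(0.7, 0.1, -1, 0.4), 2, 2); b2 <- c(0, 0.3)
  W3 <- matrix(c(1, 1, -1, 0.5), 2, 2); b3 <- c(-0.1, 0.2)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
  emb <- rbind(x1, c(2, 3), c(-1, 1))
  batch <- build_batch(sample_set(list(c(1L, 2L, 3L)), 1), emb)
  got <- mlp_embed(batch, params, cfg)
  relu <- function(z) pmax(z, 0)
  # row-vector convention: x W1 + b1 with W1 read as (in x out)
  hand_row <- relu(relu(x1 %*% W1 + b1) %*% W2 + b2) %*% W3 + b3
  expect_equal(as.vector(got$EI[[1]][1, ]), as.vector(hand_row))

  # zero parameters give zero output
  zero <- lapply(params, function(p) p * 0)
  got0 <- mlp_embed(batch, zero, cfg)
  expect_true(all(got0$EI[[1]] == 0))

  # independence: vertex 1's view never changes with its tuple partners
  batch2 <- build_batch(sample_set(list(c(1L, 3L, 2L)), 1), emb)
  got2 <- mlp_embed(batch2, params, cfg)
  expect_equal(got2$EI[[1]][1, ], got$EI[[1]][1, ])
})

test_that("KL alignment is zero at equality, positive otherwise, exact", {
  mask <- matrix(c(1, 1, 1, 0, 0, 0), 1, 6)
  E <- lapply(1:6, function(i) matrix(rnorm(4), 1, 4))
  expect_equal(kl_align(E, E, mask), 0)

  set.seed(4)
  E2 <- lapply(1:6, function(i) matrix(rnorm(4), 1, 4))
  expect_gte(kl_align(E, E2, mask), 0)

  # direct evaluation of the base-2 divergence on fixed 4-d vectors
  a <- c(0.2, -1, 0.5, 2); b <- c(1, 0.3, -0.4, 0)
  Ea <- c(list(matrix(a, 1)), rep(list(matrix(0, 1, 4)), 5))
  Eb <- c(list(matrix(b, 1)), rep(list(matrix(0, 1, 4)), 5))
  m1 <- matrix(c(1, rep(0, 5)), 1, 6)
  P <- exp(a) / sum(exp(a)); Q <- exp(b) / sum(exp(b))
  expect_equal(kl_align(Ea, Eb, m1), sum(P * log2(P / Q)))
})

test_that("hypergraph convolution equals the dense brute-force oracle", {
  # hand example: two vertices joined by one edge, identity weights,
  # no activation: X = (1, 0)' propagates to (0.5, 0.5)'
  e2 <- edge_set(list(c(1L, 2L)))
  g2 <- build_hypergraph(e2, 2L)
  out <- hconv(matrix(c(1, 0), 2, 1), g2, activation = "identity",
               layers = 1L)
  expect_equal(as.vector(out), c(0.5, 0.5))

  # zero input stays zero
  s <- tiny_setup()
  expect_true(all(hconv(matrix(0, s$N, 4), s$op, layers = 3L) == 0))

  set.seed(77)
  for (rep in 1:25) {
    N <- sample(4:10, 1)
    M <- sample(1:6, 1)
    hg <- rand_hypergraph(N, M, seed = rep + 100L)
    X <- matrix(rnorm(N * 3), N, 3)
    W <- lapply(1:2, function(t) matrix(rnorm(9), 3, 3))
    graph <- build_hypergraph(hg$edges, N)
    got <- hconv(X, graph, weights = W, layers = 2L, activation = "lrelu")
    want <- dense_hconv_oracle(X, hg$edges, N, weights = W, layers = 2L,
                               activation = "lrelu")
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("fusion scores are masked sigmoid means in (0, 1)", {
  s <- tiny_setup(seed = 6)
  samp <- sample_set(list(c(1L, 2L, 3L), c(4L, 6L, 8L, 9L, 10L, 12L)),
                     c(1, 0))
  batch <- build_batch(samp, s$emb)
  hc <- hconv(s$emb, s$op, weights = s$params[paste0("Wt", 1:3)],
              layers = 3L, cache = TRUE)
  att <- attention_embed(batch, s$params, s$cfg)
  mlp <- mlp_embed(batch, s$params, s$cfg)
  fs <- fuse_and_score(att$Ed, mlp$EI, hc$out, batch, s$params, s$cfg)
  expect_true(all(fs$p > 0 & fs$p < 1))
  expect_equal(fs$p, rowSums(fs$p_slot * batch$mask) / batch$l)

  # zero scoring head: every per-vertex logit is 0, so p = sigmoid(0) = 0.5
  p0 <- s$params; p0$ws <- p0$ws * 0; p0$bs <- 0
  fs0 <- fuse_and_score(att$Ed, mlp$EI, hc$out, batch, p0, s$cfg)
  expect_equal(fs0$p, c(0.5, 0.5))
})

test_that("total loss reduces to its analytic values", {
  expect_equal(as.numeric(total_loss(1 - 1e-7, 1, 0, 1)), 1e-7,
               tolerance = 1e-3)
  expect_equal(as.numeric(total_loss(0.5, 1, 0, 1)), log(2))
  expect_equal(as.numeric(total_loss(0.3, 1, 0.7, 0)), -log(0.3))
  expect_equal(attr(total_loss(0.3, 1, 0.7, 2), "bce"), -log(0.3))
  expect_equal(as.numeric(total_loss(0.3, 1, 0.7, 2)), -log(0.3) + 1.4)
})

test_that("classification threshold is inclusive at t", {
  expect_equal(classify(c(0.5, 0.4999, 0.9, 0)), c(1L, 0L, 1L, 0L))
  expect_true(all(classify(runif(10), t = 0) == 1L))
})

test_that("padding and vertex order never change the score", {
  s <- tiny_setup(seed = 8)
  hc <- hconv(s$emb, s$op, weights = s$params[paste0("Wt", 1:3)],
              layers = 3L, cache = TRUE)
  fw <- function(tuples) {
    batch <- build_batch(sample_set(tuples, rep(1, length(tuples))), s$emb)
    hypermci:::.mci_forward(s$params, s$cfg, batch, hc)$p
  }
  p_alone <- fw(list(c(2L, 5L, 9L, 11L)))
  p_perm <- fw(list(c(9L, 2L, 11L, 5L)))
  p_batched <- fw(list(c(2L, 5L, 9L, 11L), c(1L, 3L, 4L, 6L, 7L, 8L)))
  # attention and averaging are order-agnostic; summation order and BLAS
  # kernel choice may differ, so equality holds to float accumulation noise
  expect_equal(p_alone, p_perm, tolerance = 1e-12)
  expect_equal(p_alone, p_batched[1], tolerance = 1e-12)
})

test_that("backpropagation matches finite differences to 1e-4", {
  s <- tiny_setup(seed = 42, d = 6L, n_heads = 2L, N = 10L)
  samp <- sample_set(list(c(1L, 2L, 3L), c(2L, 5L, 7L, 9L),
                          c(1L, 4L, 6L, 8L, 9L, 10L)), c(1, 0, 1))
  batch <- build_batch(samp, s$emb)
  res <- hypermci:::.mci_loss_grads(s$params, s$cfg, batch, s$op, s$emb)
  loss_at <- function(params)
    hypermci:::.mci_loss_grads(params, s$cfg, batch, s$op, s$emb)$loss
  h <- 1e-5
  set.seed(1)
  for (nm in names(s$params)) {
    idx <- seq_along(s$params[[nm]])
    if (length(idx) > 6) idx <- sample(idx, 6)
    for (i in idx) {
      pp <- s$params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- s$params; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      an <- res$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-4)
    }
  }
})

test_that("ablated channels leave no dead code paths", {
  # noSHE never computes attention/MLP/KL: its loss ignores lambda_kl
  s1 <- tiny_setup(seed = 3, use_she = FALSE)
  samp <- sample_set(list(c(1L, 2L, 3L), c(4L, 5L, 6L, 7L)), c(1, 0))
  batch <- build_batch(samp, s1$emb)
  r_a <- hypermci:::.mci_loss_grads(s1$params, s1$cfg, batch, s1$op, s1$emb)
  cfg0 <- s1$cfg; cfg0$lambda_kl <- 0
  r_b <- hypermci:::.mci_loss_grads(s1$params, cfg0, batch, s1$op, s1$emb)
  expect_identical(r_a$loss, r_b$loss)
  expect_identical(r_a$grads, r_b$grads)
  expect_equal(r_a$kl, 0)

  # noCHE has no hconv parameters at all
  s2 <- tiny_setup(seed = 3, use_che = FALSE)
  expect_false(any(grepl("^Wt", names(s2$params))))
})
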