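test_that("reads bin by fragment midpoint, deduplicated and sorted", {
  b <- tiny_bins()
  r <- structure(list(read_id = "r1", fragments = data.frame(
    chrom = c("chr1", "chr1"),
    start = c(1500000, 1700000), end = c(1500500, 1700300))),
    class = "multiway_read")
  expect_equal(bin_read(r, b), 2L)      # both midpoints in the second bin

  r2 <- structure(list(read_id = "r2", fragments = data.frame(
    chrom = rep("chr2", 4),
    start = c(2.1e6, 0.2e6, 2.4e6, 1.1e6),
    end   = c(2.2e6, 0.3e6, 2.5e6, 1.2e6))), class = "multiway_read")
  # chr2 occupies global bins 6..8; locals 3,1,3,2 -> (6,7,8)
  expect_equal(bin_read(r2, b), c(6L, 7L, 8L))

  rX <- structure(list(read_id = "rX", fragments = data.frame(
    chrom = "chrX", start = 0, end = 100)), class = "multiway_read")
  expect_error(bin_read(rX, b), "unknown chromosome")
})

test_that("decomposition enumerates the order-3..6 subset window", {
  expect_length(decompose_tuple(1:5), 16L)            # 10 + 5 + 1
  expect_length(decompose_tuple(1:8), 210L)           # 56+70+56+28
  expect_equal(decompose_tuple(1:2), list())

  # property: count equals sum_j C(n, j) for all n <= 12, and the tuples
  # are exactly the distinct sorted subsets (brute-force enumeration)
  set.seed(1)
  for (n in 3:12) {
    tp <- sort(sample.int(500, n))
    got <- decompose_tuple(tp)
    want_n <- sum(choose(n, 3:min(6, n)))
    expect_length(got, want_n)
    keys <- vapply(got, paste, "", collapse = ",")
    expect_false(anyDuplicated(keys) > 0)
    expect_true(all(vapply(got, function(s) all(s %in% tp), TRUE)))
  }
})

test_that("frequency filtering applies the >= per-order thresholds", {
  # e1 seen 12x, e2 11x, threshold 12 at order 3 -> only e1 survives
  tuples <- c(rep(list(c(1L, 2L, 3L)), 12), rep(list(c(4L, 5L, 6L)), 11))
  got <- count_and_filter(tuples, c(`3` = 12, `4` = 1, `5` = 1, `6` = 1))
  expect_equal(got$key, "1,2,3")
  expect_equal(got$frequency, 12L)

  all_kept <- count_and_filter(tuples, c(`3` = 1, `4` = 1, `5` = 1, `6` = 1))
  expect_equal(nrow(all_kept), 2L)

  expect_error(count_and_filter(tuples, c(`3` = 1)), "every order")
})

test_that("counting matches a brute-force dictionary filter", {
  set.seed(42)
  tuples <- lapply(1:1000, function(i) sort(sample.int(40, sample(3:8, 1))))
  thr <- c(`3` = 3, `4` = 2, `5` = 2, `6` = 1)
  got <- count_and_filter(tuples, thr)

  # oracle: enumerate subsets per read with nested loops and a named list
  dict <- list()
  for (tp in tuples)
    for (k in 3:min(6, length(tp))) {
      cmb <- combn(tp, k)
      for (c in seq_len(ncol(cmb))) {
        key <- paste(cmb[, c], collapse = ",")
        dict[[key]] <- (dict[[key]] %||% 0L) + 1L
      }
    }
  keep <- names(dict)[mapply(function(k, f) {
    ord <- length(strsplit(k, ",")[[1]])
    f >= thr[as.character(ord)]
  }, names(dict), unlist(dict))]
  expect_setequal(got$key, keep)
  expect_equal(got$frequency,
               unname(unlist(dict)[got$key]))
  # deterministic ordering: ascending order then lexicographic bins
  expect_false(is.unsorted(got$order))
})

test_that("incidence and degree matrices follow the degree definitions", {
  h1 <- build_hypergraph(edge_set(list(c(1L, 2L, 3L))), 3L)
  expect_equal(as.matrix(h1$H), matrix(1, 3, 1), ignore_attr = TRUE)
  expect_equal(h1$dv, c(1, 1, 1))
  expect_equal(h1$de, 3)

  h2 <- build_hypergraph(edge_set(list(c(1L, 2L, 3L), c(1L, 4L, 5L))), 5L)
  expect_equal(h2$dv, c(2, 1, 1, 1, 1))
  expect_equal(unname(h2$de), c(3, 3))

  h0 <- build_hypergraph(edge_set(list()), 4L)
  expect_equal(h0$n_edges, 0L)
  expect_equal(h0$dv, rep(0, 4))

  expect_error(build_hypergraph(edge_set(list(c(1L, 9L, 10L))), 5L),
               "exceeds")
})

test_that("degree double-counting identity holds on random hypergraphs", {
  for (seed in 1:10) {
    hg <- rand_hypergraph(N = 12L, M = 8L, seed = seed)
    g <- build_hypergraph(hg$edges, hg$N)
    # brute force Dv and De from the incidence matrix
    H <- as.matrix(g$H)
    expect_equal(g$dv, as.vector(H %*% g$w))
    expect_equal(unname(g$de), unname(colSums(H)))
    expect_equal(sum(g$dv), sum(g$w * g$de))
  }
})

test_that("hyperedge TSV round-trip reproduces H, Dv, De exactly", {
  hg <- rand_hypergraph(N = 20L, M = 12L, seed = 99L)
  f <- withr::local_tempfile()
  write_hyperedges(hg$edges, f)
  back <- read_hyperedges(f)
  g1 <- build_hypergraph(hg$edges, hg$N)
  g2 <- build_hypergraph(back, hg$N)
  expect_identical(as.matrix(g1$H), as.matrix(g2$H))
  expect_identical(g1$dv, g2$dv)
  expect_identical(g1$de, g2$de)
})

test_that("frequency weighting fills W when requested", {
  es <- edge_set(list(c(1L, 2L, 3L), c(2L, 3L, 4L)), frequency = c(3L, 1L))
  g <- build_hypergraph(es, 4L, weight_by_frequency = TRUE)
  expect_equal(mean(g$w), 1)            # normalized to mean 1
  expect_equal(g$w[1] / g$w[2], 3)
  expect_equal(g$dv[2], sum(g$w))       # vertex 2 is in both edges
})
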