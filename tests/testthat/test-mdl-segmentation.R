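test_that("universal integer code matches its closed form and is monotone", {
  expect_equal(universal_integer_code(1), log2(2.865064), tolerance = 1e-12)
  expect_equal(universal_integer_code(2), log2(2.865064) + 1, tolerance = 1e-12)
  expect_equal(universal_integer_code(16),
               log2(2.865064) + 4 + 2 + 1, tolerance = 1e-12)
  k <- 1:200
  expect_true(all(diff(universal_integer_code(k)) >= 0))
  expect_error(universal_integer_code(0), "k >= 1")
})

test_that("model cost reproduces each closed-form term", {
  cfg <- seg_config(beta = 1)
  # single segment: no positional freedom, zero-range parameter term
  expect_equal(model_cost(1, 100, 2, 1, 0, cfg),
               universal_integer_code(1), tolerance = 1e-12)
  # positional term log2 C(9, 2) = log2 36 (36 enumerable boundary placements)
  expect_equal(model_cost(3, 10, 1, 1, 0, cfg) - universal_integer_code(3),
               log2(36), tolerance = 1e-12)
  # all-singleton segmentation has a single boundary placement
  n <- 17
  expect_equal(model_cost(n, n, 2, 1, 0, cfg) - universal_integer_code(n),
               0, tolerance = 1e-12)
  # parameter term scales with range and classes
  expect_equal(model_cost(4, 50, 3, 8, 0, cfg) -
                 model_cost(4, 50, 3, 1, 0, cfg),
               4 * 3 * log2(8), tolerance = 1e-12)
})

test_that("segment class cost equals the Gaussian code length", {
  cfg <- seg_config(beta = 1)
  # variance 1 block: (n/2)(1/ln2 + log2 2*pi)
  expect_equal(segment_class_cost(matrix(c(0, 2), 1, 2), c(1, 2), 1, cfg),
               1 / log(2) + log2(2 * pi), tolerance = 1e-12)
  # constant block is floored, never -Inf
  v <- matrix(3, 2, 4)
  got <- segment_class_cost(v, c(1, 4), 1:2, cfg)
  expect_true(is.finite(got))
  expect_equal(got, 8 / 2 * (1 / log(2) + log2(2 * pi * cfg$variance_floor)),
               tolerance = 1e-12)
  # halving tau shifts cost by |s||C_k| * log2(tau2/tau1) in the tau term
  set.seed(1)
  v <- matrix(rnorm(12, 5), 3, 4)
  c1 <- segment_class_cost(v, c(2, 4), 1:3, seg_config(tau = 1, beta = 1))
  c05 <- segment_class_cost(v, c(2, 4), 1:3, seg_config(tau = 0.5, beta = 1))
  expect_equal(c05 - c1, 9 * log2(0.5), tolerance = 1e-9)
})

test_that("data cost agrees with an independently coded evaluator", {
  set.seed(7)
  for (rep in 1:10) {
    m <- 3; n <- 12
    vals <- matrix(abs(rnorm(m * n, 2, 2)), m, n)
    labels <- c(0, 1, sample(0:1, m - 2, replace = TRUE))
    cfg <- seg_config(beta = 1)
    for (segs in list(cbind(1, n), rbind(c(1, 5), c(6, n)),
                      cbind(1:n, 1:n))) {
      expect_equal(data_cost(vals, segs, labels, cfg),
                   oracle_data_cost(vals, segs, labels, cfg$tau,
                                    cfg$variance_floor),
                   tolerance = 1e-10)
    }
  }
})

test_that("splitting at identical per-class statistics leaves data cost unchanged", {
  # duplicated half-matrices: both halves share mean and ML variance exactly
  set.seed(2)
  half <- matrix(abs(rnorm(4 * 6, 3)), 4, 6)
  vals <- cbind(half, half)
  labels <- c(0, 0, 1, 1)
  cfg <- seg_config(beta = 1)
  d1 <- data_cost(vals, cbind(1, 12), labels, cfg)
  d2 <- data_cost(vals, rbind(c(1, 6), c(7, 12)), labels, cfg)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("dynamic program equals exhaustive enumeration bit for bit", {
  set.seed(11)
  for (i in 1:25) {
    m <- sample(2:5, 1); n <- sample(5:10, 1)
    K <- min(sample(1:3, 1), m)
    vals <- matrix(abs(rnorm(m * n, 2, 2)), m, n)
    labels <- c(0:(K - 1), sample(0:(K - 1), m - K, replace = TRUE))
    cfg <- seg_config(beta = 1)
    opt <- optimal_segmentation(vals, labels, cfg)
    expect_identical(opt$total_bits, brute_force_best(vals, labels, cfg))
    segs <- opt$segments
    expect_equal(segs$start_col[1], 1L)
    expect_equal(segs$end_col[nrow(segs)], n)
    expect_true(all(segs$start_col[-1] == segs$end_col[-nrow(segs)] + 1))
  }
})

test_that("a constant matrix yields a single segment", {
  vals <- matrix(2, 4, 30)
  seg <- optimal_segmentation(vals, c(0, 0, 1, 1), seg_config(beta = 1))
  expect_equal(nrow(seg$segments), 1L)
})

test_that("the minimum segment size is honoured", {
  set.seed(3)
  vals <- matrix(abs(rnorm(4 * 60, 2, 3)), 4, 60)
  seg <- optimal_segmentation(vals, c(0, 1, 0, 1), seg_config(beta = 10))
  expect_true(all(seg$segments$end_col - seg$segments$start_col + 1 >= 10))
})

test_that("tau enters model and data cost with the printed scaling", {
  # model parameter term grows by |S||C| bits per halving of tau; the data
  # term shrinks by n|C| bits (the 1/|C_k| weight cancels the class size)
  set.seed(4)
  vals <- matrix(abs(rnorm(3 * 20, 2, 5)), 3, 20)
  labels <- c(0, 1, 1)
  segs <- rbind(c(1, 8), c(9, 20))
  tot <- function(tau) {
    cfg <- seg_config(tau = tau, beta = 1)
    data_cost(vals, segs, labels, cfg) +
      model_cost(2, 20, 2, max(vals), min(vals), cfg)
  }
  # variance floors never bind at this signal scale, so the shift is exact
  expect_equal(tot(0.5) - tot(1), 2 * 2 * 1 + 20 * 2 * log2(0.5),
               tolerance = 1e-9)
})

test_that("total bits are invariant under class relabelling", {
  set.seed(5)
  vals <- matrix(abs(rnorm(6 * 30, 2, 2)), 6, 30)
  labels <- c(0, 0, 1, 1, 2, 2)
  cfg <- seg_config(beta = 5)
  a <- optimal_segmentation(vals, labels, cfg)
  relabel <- c(2, 0, 1)  # bijection on {0,1,2}
  b <- optimal_segmentation(vals, relabel[labels + 1], cfg)
  expect_equal(a$total_bits, b$total_bits, tolerance = 1e-12)
  expect_equal(a$segments, b$segments)
})

test_that("chunked segmentation covers all columns and matches the DP when l = 1", {
  set.seed(6)
  vals <- matrix(abs(rnorm(4 * 120, 1, 2)), 4, 120)
  labels <- c(0, 1, 0, 1)
  cfg1 <- seg_config(beta = 10, chunk_size = 200)
  expect_equal(chunked_segmentation(vals, labels, cfg1)$segments,
               optimal_segmentation(vals, labels, cfg1)$segments)
  cfg3 <- seg_config(beta = 10, chunk_size = 50)
  seg <- chunked_segmentation(vals, labels, cfg3)
  s <- seg$segments
  expect_equal(s$start_col[1], 1L)
  expect_equal(s$end_col[nrow(s)], 120L)
  expect_true(all(s$start_col[-1] == s$end_col[-nrow(s)] + 1))
  # segments never span the 50/100 chunk boundaries
  expect_true(all(!(s$start_col <= 50 & s$end_col > 50)))
  expect_true(all(!(s$start_col <= 100 & s$end_col > 100)))
})

test_that("short inputs fall back to a single segment with a warning", {
  vals <- matrix(1:12 + 0, 2, 6)
  expect_warning(seg <- optimal_segmentation(vals, c(0, 1), seg_config(beta = 10)),
                 "single segment")
  expect_equal(nrow(seg$segments), 1L)
})
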