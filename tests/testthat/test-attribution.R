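test_that("attribution is exactly zero when the input equals the baseline", {
  tm <- tiny_model()$model
  # baseline = the actual inputs of row 3 in frame 1
  run <- hiclstm:::.run_frame(tm, 1, 3L)
  Xin <- do.call(rbind, lapply(run$X, function(m) m[1, ]))
  A <- integrated_gradients(tm, 1, 3L, baseline = Xin, steps = 8)
  expect_true(all(A == 0))
})

test_that("path attribution recovers the closed form of a linear target", {
  # for f(X) = sum_t w_t . x_t the attribution is w_t * (x_t - b_t),
  # independent of the number of path steps
  set.seed(5)
  Tn <- 4; D <- 6
  W <- matrix(rnorm(Tn * D), Tn, D)
  Xin <- matrix(rnorm(Tn * D), Tn, D)
  Bl <- matrix(rnorm(Tn * D), Tn, D)
  grad_fn <- function(X) {
    lapply(seq_len(Tn), function(t)
      matrix(W[t, ], nrow(X[[1]]), D, byrow = TRUE))
  }
  for (steps in c(2, 5, 50)) {
    A <- hiclstm:::.ig_path_attr(grad_fn, Xin, Bl, steps)
    expect_equal(A, W * (Xin - Bl), tolerance = 1e-12)
  }
})

test_that("attributions satisfy completeness as steps grow", {
  tm <- tiny_model()$model
  A <- integrated_gradients(tm, 1, 5L, steps = 200, check_completeness = NA)
  gap <- attr(A, "completeness_gap")
  expect_lt(gap, 0.01)
  A8 <- integrated_gradients(tm, 1, 5L, steps = 8, check_completeness = NA)
  expect_lte(gap, attr(A8, "completeness_gap") + 1e-12)
})

test_that("importance aggregation averages over a bin's occurrences", {
  tm <- tiny_model()$model
  track <- aggregate_importance(tm, steps = 8)
  expect_identical(nrow(track), tm$n_bins)
  expect_true(all(track$coverage > 0))
  # oracle: recompute bin 10's score from the raw attribution matrices
  M <- tm$rep_size
  occ <- c()
  for (k in 1:2) {
    fr <- tm$frame_spec$frames[k, ]
    rows <- seq(fr$start, min(fr$end, tm$n_bins) - 1L)
    for (r in rows) {
      A <- integrated_gradients(tm, k, r, steps = 8, check_completeness = NA)
      cols <- attr(A, "cols")
      if (r == 10) occ <- c(occ, sum(A[, 1:M]))
      hit <- which(!is.na(cols) & cols == 10)
      for (t in hit) occ <- c(occ, sum(A[t, M + 1:M]))
    }
  }
  expect_equal(track$raw[11], mean(occ), tolerance = 1e-10)
})

test_that("aggregation with an empty row set fails", {
  tm <- tiny_model()$model
  expect_error(aggregate_importance(tm, rows = integer(0)), "empty row set")
})

test_that("min-max normalization treats signs separately", {
  expect_equal(normalize_importance(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_importance(c(-2, -6)), c(0, -1))
  expect_equal(normalize_importance(c(5)), 1)
  expect_equal(normalize_importance(c(-3)), -1)
  got <- normalize_importance(c(2, 0, -4, 4, -8))
  expect_equal(got, c(0, 0, 0, 1, -1))
  expect_error(normalize_importance(c(0, 0)), "nonzero")
  # output ranges: positives in [0,1], negatives in [-1,0], zeros preserved
  set.seed(12)
  v <- c(rnorm(20), 0)
  nv <- normalize_importance(v)
  expect_true(all(nv[v > 0] >= 0 & nv[v > 0] <= 1))
  expect_true(all(nv[v < 0] >= -1 & nv[v < 0] <= 0))
  expect_identical(nv[v == 0], 0)
})

test_that("interval profiles average interior spans and flanks", {
  track <- seq(0, 99)             # track value = bin index
  iv <- data.frame(start = 0, end = 200000)    # bins 0..19 at 10 kb
  pr <- aggregate_profile(track, iv, 10000, n_interior = 10, flank = 50000)
  expect_identical(pr$flank_bins, 5L)
  expect_identical(length(pr$profile), 20L)
  interior <- pr$profile[6:15]
  expect_equal(interior, seq(0.5, 18.5, by = 2))
  # a constant track gives a flat profile (interval away from the ends so
  # the flanks are fully covered)
  iv_mid <- data.frame(start = 400000, end = 600000)
  pr2 <- aggregate_profile(rep(3, 100), iv_mid, 10000)
  expect_true(all(pr2$profile == 3))
  # too-short intervals are skipped with a warning
  expect_warning(
    expect_error(aggregate_profile(track, data.frame(start = 0, end = 50000),
                                   10000, n_interior = 10), "no interval"),
    "skipped")
})

test_that("trained importance singles out TAD boundaries as insulators", {
  # the attribution target is the sum of a row's predicted contacts, so
  # bins that suppress contacts across themselves (TAD boundaries) receive
  # systematically negative attributions relative to the rest of the genome
  model <- fixture_model()
  truth <- fixture_sim()$sim$truth
  track <- normalize_importance(aggregate_importance(model, steps = 8))
  b <- truth$boundary_bins + 1L
  pv <- stats::wilcox.test(track$normalized[b], track$normalized[-b],
                           alternative = "less")$p.value
  expect_lt(pv, 0.05)
})
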