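toy_rep <- function(n = 4, M = 3) {
  # rows 1..n are bins 0..n-1; last row is the padding representation
  matrix(as.numeric(seq_len((n + 1) * M)), n + 1, M)
}

test_that("shift knockout deletes rows and back-fills with padding", {
  R <- toy_rep()
  out <- knockout(R, 1, method = "shift")
  expect_equal(out[1, ], R[1, ])
  expect_equal(out[2, ], R[3, ])
  expect_equal(out[3, ], R[4, ])
  expect_equal(out[4, ], R[5, ])            # padding fills the tail
  expect_equal(out[5, ], R[5, ])            # padding row itself untouched
  expect_equal(attr(out, "coord_map"), c(0, 2, 3, NA))
  expect_error(knockout(R, 0:3, method = "shift"), "every bin")
})

test_that("zero, padding and average knockouts touch only their targets", {
  R <- toy_rep()
  z <- knockout(R, 1, method = "zero")
  expect_true(all(z[2, ] == 0))
  expect_identical(z[-2, ], R[-2, ])
  p <- knockout(R, 1, method = "padding")
  expect_equal(p[2, ], R[5, ])
  a <- knockout(R, 1, method = "average", window = 1)
  expect_equal(a[2, ], (R[1, ] + R[3, ]) / 2)
  expect_identical(a[-2, ], R[-2, ])
  expect_error(knockout(R, integer(0)), "empty")
  expect_error(knockout(R, 7), "out of range")
})

test_that("orientation replacement swaps the orientation means", {
  set.seed(2)
  R <- matrix(rnorm(8 * 4), 8, 4)
  u <- c(1, 2, 3, 4)
  R[c(1, 3), ] <- rep(u, each = 2)          # forward sites, identical rows
  out <- replace_orientation(R, forward_bins = c(0, 2),
                             reverse_bins = c(4, 5))
  rev_mean <- colMeans(R[c(5, 6), ])
  expect_equal(out[1, ], rev_mean)
  expect_equal(out[3, ], rev_mean)
  expect_equal(out[5, ], u)                 # reverse sites get the forward mean
  expect_equal(out[6, ], u)
  expect_identical(out[c(2, 4, 7, 8), ], R[c(2, 4, 7, 8), ])
  expect_error(replace_orientation(R, integer(0), 4), "empty")
})

test_that("orientation means exclude the padding row", {
  R <- toy_rep()
  R[5, ] <- 1e6                             # a padding row that would dominate
  out <- replace_orientation(R, forward_bins = 0, reverse_bins = c(1, 2))
  expect_equal(out[1, ], colMeans(R[2:3, , drop = FALSE]))
  expect_equal(out[2, ], R[1, ])
  expect_equal(out[3, ], R[1, ])
})

test_that("tandem duplication doubles the block and maps provenance", {
  R <- toy_rep()
  dup <- duplicate_block(R, c(1, 2))
  expect_identical(dim(dup), c(7L, 3L))     # 6 bins + padding
  expect_equal(unclass(dup)[1:6, ], R[c(1, 2, 3, 2, 3, 4), ])
  expect_equal(attr(dup, "coord_map"), c(0, 1, 2, 1, 2, 3))
  expect_equal(attr(dup, "copy"), c(NA, 1L, 1L, 2L, 2L, NA))
  expect_error(duplicate_block(R, c(2, 5)), "out of range")
})

test_that("the 2.1 Mb duplication block spans 214 bins", {
  rb <- region_bins(67950000, 70080000, 10000)
  R <- matrix(rnorm(7100 * 2), 7100, 2)
  dup <- duplicate_block(R, c(rb$first, rb$last))
  expect_identical(nrow(dup), 7100L + 214L)
})

test_that("duplicating then shift-deleting the second copy is the identity", {
  R <- toy_rep(n = 9, M = 4)
  dup <- duplicate_block(R, c(2, 4))
  copy2 <- which(attr(dup, "copy") == 2L) - 1L
  back <- knockout(dup, copy2, method = "shift")
  expect_identical(unclass(back)[1:10, ], R)
})

test_that("combine_copies sums read counts over carriers", {
  p <- transform_params()
  # reference bins 0,1,2; bin 1 duplicated -> post bins 0,1,1',2
  map <- c(0L, 1L, 1L, 2L)
  x <- 0.3
  v <- matrix(0.1, 4, 4)
  v[1, 2] <- v[1, 3] <- x; v[2, 1] <- v[3, 1] <- x
  pp <- contact_matrix(v, 10000, "probability")
  out <- combine_copies(pp, map, p)
  expect_identical(out$n_bins, 3L)
  # pair (0,1) has two carriers with equal probability x
  expect_equal(out$values[1, 2],
               to_probability(2 * from_probability(x, p), p))
  # pair (0,2) has a single carrier: pass-through up to the round trip
  expect_equal(out$values[1, 3], 0.1, tolerance = 1e-6)
  expect_error(combine_copies(contact_matrix(matrix(1, 2, 2), 1e4, "probability"),
                              c(0L, 1L), p), "probability of 1")
})

test_that("combine_copies conserves total read count", {
  p <- transform_params()
  set.seed(9)
  v <- matrix(runif(16, 0.05, 0.9), 4, 4)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  pp <- contact_matrix(v, 10000, "probability")
  out <- combine_copies(pp, c(0L, 1L, 1L, 2L), p)
  cs_in <- sum(from_probability(pp$values, p))
  cs_out <- sum(from_probability(out$values, p))
  expect_equal(cs_out, cs_in, tolerance = 1e-6)
})

test_that("duplication baseline keeps observed values outside the block", {
  fx <- fixture_sim()
  obs <- fx$sim$contacts
  block <- c(40, 59)
  base <- duplication_baseline(obs, block)
  idx <- setdiff(seq_len(300), 41:60)
  expect_identical(base$values[idx, idx], obs$values[idx, idx])
  expect_identical(base$values[idx, 41:60], obs$values[idx, 41:60])
  # within-block entry = mean over window placements at the same offset
  ri <- 3; rj <- 11
  starts <- seq_len(300 - 20 + 1)
  want <- mean(obs$values[cbind(starts + ri - 1, starts + rj - 1)])
  expect_equal(base$values[40 + ri, 40 + rj], want)
  expect_equal(base$values[40 + rj, 40 + ri], want)
})

test_that("duplication baseline of a constant matrix is that constant", {
  obs <- contact_matrix(matrix(4, 30, 30), 1e4, "raw_counts")
  base <- duplication_baseline(obs, c(5, 10))
  expect_true(all(base$values == 4))
  expect_error(duplication_baseline(obs, c(0, 20)), "half the chromosome")
})

test_that("effect curves localize a single changed entry", {
  v <- matrix(0.4, 5, 5)
  wt <- contact_matrix(v, 10000, "probability")
  expect_true(all(effect_by_distance(wt, wt, sites = 2, window = 4e4)$delta == 0,
                  na.rm = TRUE))
  v2 <- v; v2[2, 5] <- 0.1; v2[5, 2] <- 0.1   # pair (1,4): separation 3
  ko <- contact_matrix(v2, 10000, "probability")
  eff <- effect_by_distance(wt, ko, sites = 2, window = 4e4)
  expect_identical(nrow(eff), 4L)
  # straddling pairs at separation 3 are (0,3) and (1,4); only (1,4) changed
  expect_equal(eff$delta[3], (0 + (0.1 - 0.4)) / 2)
  expect_true(all(eff$delta[c(1, 2, 4)] == 0, na.rm = TRUE))
  # mse variant squares the change
  effm <- effect_by_distance(wt, ko, sites = 2, window = 4e4, stat = "mse")
  expect_equal(effm$delta[3], (0 + 0.3^2) / 2)
  expect_error(effect_by_distance(wt, ko, sites = integer(0)), "empty")
})

test_that("shift knockouts are compared through the coordinate map", {
  tm <- tiny_model()$model
  wt <- predict_matrix(tm)
  kr <- knockout(tm, c(10, 11), method = "shift")
  ko <- predict_matrix(tm, rep = kr)
  ref <- map_to_reference(ko, attr(kr, "coord_map"), tm$n_bins)
  expect_identical(ref$n_bins, tm$n_bins)
  # deleted bins have no counterpart
  expect_true(all(is.na(ref$values[11, ])))
  expect_true(all(is.na(ref$values[, 12])))
  # bins upstream of the knockout keep their predictions
  expect_equal(ref$values[1:10, 1:10], wt$values[1:10, 1:10])
})
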