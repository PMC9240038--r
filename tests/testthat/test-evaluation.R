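sym <- function(v, n) {
  m <- matrix(v, n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("r2_by_distance matches hand-computed sums", {
  # obs = 1,2,3 and pred = 1,2,4 at separation 1 -> R2 = 1 - 1/2
  o <- matrix(0, 4, 4); p <- matrix(0, 4, 4)
  o[cbind(1:3, 2:4)] <- c(1, 2, 3); o[cbind(2:4, 1:3)] <- c(1, 2, 3)
  p[cbind(1:3, 2:4)] <- c(1, 2, 4); p[cbind(2:4, 1:3)] <- c(1, 2, 4)
  obs <- contact_matrix(o, 1e4, "raw_counts")
  pred <- contact_matrix(p, 1e4, "raw_counts")
  r2 <- r2_by_distance(obs, pred, max_distance = 1e4)
  expect_equal(r2$by_distance$r2[1], 0.5)
})

test_that("r2 is 1 for perfect predictions and 0 for the distance mean", {
  fx <- fixture_sim()
  obs <- fx$cp
  r2 <- r2_by_distance(obs, obs, max_distance = 3e5)
  expect_true(all(abs(r2$by_distance$r2 - 1) < 1e-12))
  base <- distance_mean_baseline(obs)
  r2b <- r2_by_distance(obs, base, max_distance = 3e5)
  expect_true(all(abs(r2b$by_distance$r2) < 1e-10))
})

test_that("r2 is invariant to adding a constant to both matrices", {
  fx <- fixture_sim()
  obs <- fx$sim$contacts
  pred <- distance_mean_baseline(obs)
  pred$values <- pred$values * 0.9 + 1      # imperfect predictor
  r2a <- r2_by_distance(obs, pred, max_distance = 2e5)
  obs2 <- contact_matrix(obs$values + 5, obs$resolution, "raw_counts")
  pred2 <- contact_matrix(pred$values + 5, obs$resolution, "raw_counts")
  r2b <- r2_by_distance(obs2, pred2, max_distance = 2e5)
  expect_equal(r2a$by_distance$r2, r2b$by_distance$r2, tolerance = 1e-9)
})

test_that("zero-variance separations are reported missing", {
  obs <- contact_matrix(matrix(1, 5, 5), 1e4, "raw_counts")
  r2 <- r2_by_distance(obs, obs, max_distance = 2e4)
  expect_true(all(is.na(r2$by_distance$r2)))
})

test_that("distance-mean baseline averages each stratum and is idempotent", {
  m <- sym(0, 3)
  m[1, 2] <- m[2, 1] <- 2; m[2, 3] <- m[3, 2] <- 4; m[1, 3] <- m[3, 1] <- 7
  obs <- contact_matrix(m, 1e4, "raw_counts")
  base <- distance_mean_baseline(obs)
  expect_equal(base$values[1, 2], 3)
  expect_equal(base$values[2, 3], 3)
  expect_equal(base$values[1, 3], 7)
  expect_equal(distance_mean_baseline(base)$values, base$values)
  cm <- contact_matrix(matrix(2, 4, 4), 1e4, "raw_counts")
  expect_true(all(distance_mean_baseline(cm)$values == 2))
})

test_that("binarize_signal applies a strict threshold", {
  expect_identical(binarize_signal(c(0.4, 0.5, 0.6)), c(0L, 0L, 1L))
  expect_identical(binarize_signal(c(-1, 0.2)), c(0L, 0L))
  expect_identical(binarize_signal(c(-1, 0.2), threshold = -Inf), c(1L, 1L))
  expect_error(binarize_signal(c(1, NA)), "finite")
})

test_that("negative sampling balances classes reproducibly", {
  pos <- c(3, 7, 20, 21)
  ls <- sample_negatives(pos, 0:99, seed = 5)
  expect_identical(sum(ls$label == 0), 4L)
  expect_true(!any(ls$bin[ls$label == 0] %in% pos))
  ls2 <- sample_negatives(pos, 0:99, seed = 5)
  expect_identical(ls, ls2)
  # a universe with exactly 11 spare bins: sample covers 10 of the 11
  pos10 <- 0:9
  ls3 <- sample_negatives(pos10, 0:20, seed = 1)
  expect_identical(sum(ls3$label == 0), 10L)
  expect_true(all(ls3$bin[ls3$label == 0] %in% 10:20))
  expect_error(sample_negatives(0:9, 0:15, seed = 1), "not enough")
})

test_that("classification metrics match their closed forms", {
  # unit confusion table: one of each -> accuracy 1/2
  m <- classification_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(1L, 1L, 1L, 1L))
  expect_equal(m$accuracy, 0.5)
  # P = R => F = P (here P = R = 1/2)
  expect_equal(m$f1, 0.5)
  # three-item example: AP = (1 + 2/3) / 2
  m3 <- classification_metrics(c(1, 0, 1), c(0.9, 0.8, 0.7))
  expect_equal(m3$ap, (1 + 2 / 3) / 2)
  # all-tied scores: AuROC 0.5 by convention
  mt <- classification_metrics(c(1, 0, 1, 0), rep(0.3, 4))
  expect_equal(mt$auroc, 0.5)
  expect_error(classification_metrics(c(1, 1), c(0.1, 0.2)), "at least one")
})

test_that("AP and AuROC are invariant under monotone score transforms", {
  set.seed(31)
  labels <- rbinom(60, 1, 0.4)
  labels[1] <- 1; labels[2] <- 0
  scores <- rnorm(60)
  a <- classification_metrics(labels, scores)
  b <- classification_metrics(labels, exp(3 * scores) + 2)
  expect_equal(a$ap, b$ap)
  expect_equal(a$auroc, b$auroc)
})

test_that("rank-based AuROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  labels <- rbinom(80, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- runif(80)
  got <- classification_metrics(labels, scores)$auroc
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("classifiers separate a linearly separable toy exactly", {
  set.seed(3)
  n <- 60
  X <- cbind(c(rep(1, n / 2), rep(-1, n / 2)), rnorm(n))
  labels <- data.frame(bin = 0:(n - 1), label = rep(c(1L, 0L), each = n / 2))
  for (kind in c("boosted_tree", "linear_multilabel")) {
    rep_ <- train_classifier(X, labels, kind = kind, nrounds = 50)
    expect_equal(rep_$map, 1)
    expect_equal(rep_$auroc, 1)
  }
})

test_that("labels independent of features give chance-level AuROC", {
  set.seed(17)
  n <- 500
  X <- matrix(rnorm(n * 4), n, 4)
  labels <- data.frame(bin = 0:(n - 1), label = rep(c(0L, 1L), n / 2))
  rep_ <- train_classifier(X, labels, kind = "linear_multilabel")
  expect_lt(abs(rep_$auroc - 0.5), 0.1)
})

test_that("cross-validation folds are reproducible by seed", {
  set.seed(23)
  X <- matrix(rnorm(200), 100, 2)
  labels <- data.frame(bin = 0:99, label = rep(c(0L, 1L), 50))
  a <- train_classifier(X, labels, kind = "linear_multilabel", seed = 4)
  b <- train_classifier(X, labels, kind = "linear_multilabel", seed = 4)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(train_classifier(X, data.frame(bin = 0:9, label = rep(1L, 10))),
               "both classes")
})
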