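#' Reconstruction accuracy by genomic distance
#'
#' For every separation `d` up to `max_distance`, computes
#' `R^2 = 1 - SS_res / SS_tot` between observed and predicted values over
#' all ordered pairs at that separation (entries missing in either matrix
#' are excluded pairwise), plus the unweighted average over separations.
#' A separation with zero observed variance has an undefined `R^2` and is
#' reported `NA`.
#'
#' @param obs,pred [contact_matrix()]s of the same shape.
#' @param max_distance Maximum separation in bp (default 5e6).
#' @return List with `by_distance` (data.frame `distance`, `r2`, `n_pairs`)
#'   and `average`.
#' @export
r2_by_distance <- function(obs, pred, max_distance = 5e6) {
  stopifnot(inherits(obs, "contact_matrix"), inherits(pred, "contact_matrix"))
  if (obs$n_bins != pred$n_bins) stop("matrices differ in size")
  n <- obs$n_bins
  dmax <- min(as.integer(max_distance / obs$resolution), n - 1L)
  res <- data.frame(distance = seq_len(dmax) * obs$resolution,
                    r2 = NA_real_, n_pairs = 0L)
  for (d in seq_len(dmax)) {
    i <- seq_len(n - d)
    o <- c(obs$values[cbind(i, i + d)], obs$values[cbind(i + d, i)])
    p <- c(pred$values[cbind(i, i + d)], pred$values[cbind(i + d, i)])
    ok <- !is.na(o) & !is.na(p)
    o <- o[ok]; p <- p[ok]
    res$n_pairs[d] <- length(o)
    if (length(o) < 2) next
    ss_tot <- sum((o - mean(o))^2)
    if (ss_tot == 0) next
    res$r2[d] <- 1 - sum((o - p)^2) / ss_tot
  }
  list(by_distance = res, average = mean(res$r2, na.rm = TRUE))
}

#' Distance-stratified mean baseline
#'
#' Predicts every pair by the mean observed value at its separation; by the
#' definition of `SS_tot` this baseline has `R^2 = 0` at every separation
#' with defined variance.
#'
#' @param obs A [contact_matrix()].
#' @return A [contact_matrix()] of the same kind.
#' @export
distance_mean_baseline <- function(obs) {
  stopifnot(inherits(obs, "contact_matrix"))
  n <- obs$n_bins
  out <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    v <- c(obs$values[cbind(i, i + d)], if (d > 0) obs$values[cbind(i + d, i)])
    mv <- mean(v, na.rm = TRUE)
    out[cbind(i, i + d)] <- mv
    out[cbind(i + d, i)] <- mv
  }
  out[is.nan(out)] <- NA_real_
  contact_matrix(out, obs$resolution, obs$kind)
}

#' Binarize a signal track
#'
#' Label 1 iff `value > threshold` (strict), e.g. active genes by log mean
#' expression > 0.5, FIREs by score > 0.5.
#'
#' @param values Numeric vector.
#' @param threshold Cutoff (default 0.5).
#' @return Integer 0/1 vector.
#' @export
binarize_signal <- function(values, threshold = 0.5) {
  if (any(!is.finite(values))) stop("values must be finite")
  as.integer(values > threshold)
}

#' Sample balanced negatives for a classification task
#'
#' Uniformly samples, without replacement, as many negative bins from the
#' non-positive universe as there are positives, reproducibly by seed.
#'
#' @param positive_bins 0-based positive bins.
#' @param universe 0-based candidate bins (e.g. `0:(n_bins-1)`).
#' @param seed Integer seed.
#' @param task Task name carried in the result.
#' @return A `label_set`: data.frame with `bin` and `label` (1/0), with
#'   attributes `task` and `seed`.
#' @export
sample_negatives <- function(positive_bins, universe, seed = 1L, task = "task") {
  positive_bins <- sort(unique(as.integer(positive_bins)))
  universe <- sort(unique(as.integer(universe)))
  if (!all(positive_bins %in% universe))
    stop("positives must lie in the universe")
  pool <- setdiff(universe, positive_bins)
  if (length(pool) < length(positive_bins))
    stop("not enough non-positive bins to balance the classes")
  neg <- with_seed(seed, sort(sample(pool, length(positive_bins))))
  structure(data.frame(bin = c(positive_bins, neg),
                       label = rep(c(1L, 0L), c(length(positive_bins), length(neg)))),
            class = c("label_set", "data.frame"), task = task, seed = seed)
}

#' Classification metrics used throughout the evaluation
#'
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)` and the F-score
#' `F = 2PR / (P + R)` are computed at a 0.5 score threshold. `auroc` is the
#' area under the TPR/FPR curve (rank statistic; ties get half credit, so
#' all-tied scores give 0.5). `ap` is the average of the maximum precision
#' achieved at or beyond each attained recall level; both `ap` and `auroc`
#' are invariant under strictly monotone score transforms.
#'
#' @param labels 0/1 vector (at least one of each class).
#' @param scores Numeric scores, higher = more positive.
#' @return List with `ap`, `auroc`, `accuracy`, `f1` and confusion counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0))
    stop("need at least one positive and one negative label")
  np <- sum(labels == 1); nn <- sum(labels == 0)

  # AuROC via mid-ranks (Mann-Whitney), ties get half credit
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)

  # AP: thresholds at distinct scores, descending
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  cum_tp <- cumsum(lab)
  # evaluate precision/recall after each distinct-score group
  grp_end <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  prec <- cum_tp[grp_end] / grp_end
  rec <- cum_tp[grp_end] / np
  rec_levels <- sort(unique(rec[rec > 0]))
  ap <- mean(vapply(rec_levels, function(rl) max(prec[rec >= rl]), numeric(1)))

  pred <- as.integer(scores > 0.5)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  accuracy <- (tp + tn) / (tp + fp + tn + fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  rr <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + rr > 0) 2 * p * rr / (p + rr) else 0
  list(ap = ap, auroc = auroc, accuracy = accuracy, f1 = f1,
       tp = tp, fp = fp, tn = tn, fn = fn)
}
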