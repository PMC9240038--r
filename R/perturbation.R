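# In-silico perturbations operate on the (n_bins + 1) x M representation
# table (padding row last) and record a coordinate map: for every perturbed
# bin, the 0-based reference bin it carries, or NA for novel/padding
# positions. Surgeries never touch rows they do not target.

.as_rep <- function(R) {
  if (inherits(R, "hiclstm_model")) R$rep else as.matrix(R)
}

.check_bins <- function(bins, n) {
  if (!length(bins)) stop("bin set is empty")
  bins <- sort(unique(as.integer(bins)))
  if (any(bins < 0 | bins >= n)) stop("bins out of range [0, ", n - 1, "]")
  bins
}

#' In-silico knockout of genomic bins
#'
#' Replaces the representations of `bins` by one of four methods:
#' `"shift"` deletes the rows and shifts all downstream representations
#' upward, filling the tail with the padding representation (the preferred
#' method: it emulates a genomic deletion); `"zero"` sets the rows to the
#' zero vector; `"average"` sets each row to the mean representation of its
#' `+/- window` neighbors (excluding knocked-out bins); `"padding"` sets the
#' rows to the padding representation.
#'
#' @param R Representation matrix `(n_bins + 1) x M` (padding row last) or
#'   a `hiclstm_model`.
#' @param bins 0-based bins to knock out.
#' @param method One of `"shift"`, `"zero"`, `"average"`, `"padding"`.
#' @param window Neighborhood half-width in bins for `method = "average"`
#'   (default 10, i.e. 100 kb at 10 kb resolution).
#' @return The perturbed representation matrix with attribute `coord_map`
#'   (integer vector over perturbed bins: reference bin or `NA`).
#' @export
knockout <- function(R, bins, method = c("shift", "zero", "average", "padding"),
                     window = 10L) {
  method <- match.arg(method)
  R <- .as_rep(R)
  n <- nrow(R) - 1L
  bins <- .check_bins(bins, n)
  pad <- R[n + 1L, ]
  out <- R
  map <- seq_len(n) - 1L
  if (method == "shift") {
    if (length(bins) == n) stop("cannot shift-knockout every bin")
    keep <- setdiff(seq_len(n) - 1L, bins)
    k <- length(keep)
    out[seq_len(k), ] <- R[keep + 1L, ]
    if (k < n) out[seq(k + 1L, n), ] <- matrix(pad, n - k, ncol(R), byrow = TRUE)
    map <- c(keep, rep(NA_integer_, n - k))
  } else if (method == "zero") {
    out[bins + 1L, ] <- 0
  } else if (method == "padding") {
    out[bins + 1L, ] <- matrix(pad, length(bins), ncol(R), byrow = TRUE)
  } else {
    if (window < 1) stop("window must be >= 1 for method = 'average'")
    for (b in bins) {
      nb <- setdiff(seq(b - window, b + window), bins)
      nb <- nb[nb >= 0 & nb < n]
      if (!length(nb)) stop("no neighbors available to average around bin ", b)
      out[b + 1L, ] <- colMeans(R[nb + 1L, , drop = FALSE])
    }
  }
  structure(out, coord_map = map, method = method, ko_bins = bins)
}

#' Swap CTCF motif orientations by mean-representation replacement
#'
#' Computes the genome-wide mean representation of the forward-oriented
#' motif bins and of the reverse-oriented motif bins (padding row excluded),
#' then replaces every target-site row by the opposite orientation's mean:
#' forward sites receive the reverse mean and reverse sites the forward
#' mean. `mode` records whether the targeted pairs were convergent or
#' divergent; the surgery is the same orientation swap in both cases.
#'
#' @param R Representation matrix or `hiclstm_model`.
#' @param forward_bins,reverse_bins 0-based bins of forward / reverse
#'   motifs (both nonempty).
#' @param mode `"convergent_to_divergent"` or `"divergent_to_convergent"`.
#' @return Perturbed representation matrix (identity `coord_map`).
#' @export
replace_orientation <- function(R, forward_bins, reverse_bins,
                                mode = c("convergent_to_divergent",
                                         "divergent_to_convergent")) {
  mode <- match.arg(mode)
  R <- .as_rep(R)
  n <- nrow(R) - 1L
  forward_bins <- .check_bins(forward_bins, n)
  reverse_bins <- .check_bins(reverse_bins, n)
  mean_fwd <- colMeans(R[forward_bins + 1L, , drop = FALSE])
  mean_rev <- colMeans(R[reverse_bins + 1L, , drop = FALSE])
  out <- R
  out[forward_bins + 1L, ] <- matrix(mean_rev, length(forward_bins), ncol(R),
                                     byrow = TRUE)
  out[reverse_bins + 1L, ] <- matrix(mean_fwd, length(reverse_bins), ncol(R),
                                     byrow = TRUE)
  structure(out, coord_map = seq_len(n) - 1L, mode = mode)
}

#' Tandem duplication of a representation block
#'
#' Builds the post-duplication representation table
#' `[prefix, block, block, suffix]`; the chromosome grows by the block
#' length. The coordinate map records, for every post-duplication bin, the
#' reference bin it carries, and the `copy` attribute marks first/second
#' copy provenance.
#'
#' @param R Representation matrix or `hiclstm_model`.
#' @param block Inclusive 0-based bin range `c(first, last)` (e.g. from
#'   [region_bins()]).
#' @return The enlarged representation matrix with attributes `coord_map`
#'   and `copy` (1, 2 or `NA` outside the duplicated block).
#' @export
duplicate_block <- function(R, block) {
  R <- .as_rep(R)
  n <- nrow(R) - 1L
  stopifnot(length(block) == 2)
  first <- as.integer(block[1]); last <- as.integer(block[2])
  if (first < 0 || last >= n || first > last)
    stop("block out of range")
  idx <- seq_len(n) - 1L
  pre <- idx[idx < first]
  blk <- seq(first, last)
  post <- idx[idx > last]
  order_ref <- c(pre, blk, blk, post)
  out <- rbind(R[order_ref + 1L, , drop = FALSE], R[n + 1L, , drop = FALSE])
  copy <- c(rep(NA_integer_, length(pre)), rep(1L, length(blk)),
            rep(2L, length(blk)), rep(NA_integer_, length(post)))
  structure(out, coord_map = order_ref, copy = copy,
            block = c(first, last))
}

#' Remap predictions on perturbed coordinates back to the reference
#'
#' For surgeries where every reference bin has at most one carrier (e.g.
#' shift knockout), builds the reference-coordinate predicted matrix;
#' reference bins without a carrier (the deleted bins) become `NA` rows and
#' columns. For duplications use [combine_copies()].
#'
#' @param pred Predicted [contact_matrix()] on perturbed coordinates.
#' @param map Coordinate map (from the surgery's `coord_map` attribute).
#' @param n_ref Number of reference bins.
#' @return A [contact_matrix()] on reference coordinates.
#' @export
map_to_reference <- function(pred, map, n_ref) {
  stopifnot(inherits(pred, "contact_matrix"), length(map) == pred$n_bins)
  if (any(duplicated(map[!is.na(map)])))
    stop("map is not one-to-one; use combine_copies() for duplications")
  out <- matrix(NA_real_, n_ref, n_ref)
  src <- which(!is.na(map))
  out[cbind(rep(map[src] + 1L, each = length(src)),
            rep(map[src] + 1L, times = length(src)))] <-
    pred$values[cbind(rep(src, each = length(src)), rep(src, times = length(src)))]
  contact_matrix(out, pred$resolution, pred$kind)
}

#' Sum duplicated copies back onto the reference genome
#'
#' Hi-C reads cannot be disambiguated between two duplicated copies, so the
#' post-duplication predictions are mapped to the reference by read-count
#' arithmetic: each predicted probability is inverted to a read count, the
#' counts of all perturbed-coordinate pairs carrying the same reference pair
#' are summed, and the sum is transformed back to a probability. Reference
#' pairs with a single carrier pass through unchanged (up to the round
#' trip); pairs whose carriers are all unmodeled (`NA`) stay `NA`.
#'
#' @param pred_post Predicted probability [contact_matrix()] on
#'   post-duplication coordinates (entries must be < 1).
#' @param map Coordinate map from [duplicate_block()].
#' @param params [transform_params()].
#' @return Probability [contact_matrix()] on reference coordinates.
#' @export
combine_copies <- function(pred_post, map, params = transform_params()) {
  stopifnot(inherits(pred_post, "contact_matrix"),
            pred_post$kind == "probability",
            length(map) == pred_post$n_bins, !any(is.na(map)))
  v <- pred_post$values
  if (any(v[!is.na(v)] >= 1))
    stop("predicted probability of 1 cannot be inverted to a read count")
  n_ref <- max(map) + 1L
  # aggregation matrix: reference bin x perturbed bin
  A <- matrix(0, n_ref, length(map))
  A[cbind(map + 1L, seq_along(map))] <- 1
  cs <- from_probability(ifelse(is.na(v), 0, v), params)
  cs_ref <- A %*% cs %*% t(A)
  cover <- A %*% (!is.na(v)) %*% t(A)
  out <- to_probability(cs_ref, params)
  out[cover == 0] <- NA_real_
  contact_matrix(out, pred_post$resolution, "probability")
}

#' Baseline prediction for a tandem duplication
#'
#' Predicts the observed pre-duplication values for all interactions among
#' the upstream, downstream and duplicated regions, and, for the duplicated
#' block with itself, the genomic average: each within-block entry at
#' relative offset `(ri, rj)` is the mean of the observed values at that
#' offset over all placements of a block-sized window along the chromosome.
#'
#' @param obs Observed [contact_matrix()].
#' @param block Inclusive 0-based bin range `c(first, last)`.
#' @return A [contact_matrix()] of the same kind as `obs`.
#' @export
duplication_baseline <- function(obs, block) {
  stopifnot(inherits(obs, "contact_matrix"), length(block) == 2)
  n <- obs$n_bins
  first <- as.integer(block[1]); last <- as.integer(block[2])
  if (first < 0 || last >= n || first > last) stop("block out of range")
  L <- last - first + 1L
  if (L > n / 2) stop("block longer than half the chromosome")
  out <- obs$values
  starts <- seq_len(n - L + 1L)            # window placements (1-based)
  # average over placements, one relative offset (ri, rj) at a time
  for (ri in seq_len(L)) {
    for (rj in ri:L) {
      vals <- obs$values[cbind(starts + ri - 1L, starts + rj - 1L)]
      mv <- mean(vals, na.rm = TRUE)
      out[first + ri, first + rj] <- mv
      out[first + rj, first + ri] <- mv
    }
  }
  contact_matrix(out, obs$resolution, obs$kind)
}

#' Mean contact change around perturbed sites, by separation
#'
#' For each separation `d` (bins) up to `window` bp, averages
#' `perturbed - wild-type` over all pairs `(i, j)` with `j - i = d` that
#' straddle a site (`i <= s <= j`) and lie within `window` of it. Both
#' matrices must be on the same (reference) coordinates; remap shifted
#' knockouts with [map_to_reference()] first. `stat = "mse"` averages the
#' squared difference instead (duplication evaluation).
#'
#' @param wt,perturbed Predicted [contact_matrix()]s on the same
#'   coordinates.
#' @param sites 0-based perturbed-site bins.
#' @param window Window in bp (default 2e6, i.e. the 2 Mb neighborhood).
#' @param stat `"mean_diff"` (default) or `"mse"`.
#' @return data.frame with `distance` (bp), `delta` and `n_pairs`;
#'   separations with no modeled pair have `NA` delta.
#' @export
effect_by_distance <- function(wt, perturbed, sites, window = 2e6,
                               stat = c("mean_diff", "mse")) {
  stat <- match.arg(stat)
  stopifnot(inherits(wt, "contact_matrix"), inherits(perturbed, "contact_matrix"))
  if (wt$n_bins != perturbed$n_bins)
    stop("matrices have different dimensions; remap to reference coordinates first")
  n <- wt$n_bins
  sites <- .check_bins(sites, n)
  dmax <- as.integer(window / wt$resolution)
  diffm <- perturbed$values - wt$values
  if (stat == "mse") diffm <- diffm^2
  res <- data.frame(distance = seq_len(dmax) * wt$resolution,
                    delta = NA_real_, n_pairs = 0L)
  for (d in seq_len(dmax)) {
    vals <- c()
    for (s in sites) {
      i <- seq(max(0L, s - d), s)
      j <- i + d
      ok <- j < n & (j - s) <= dmax & (s - i) <= dmax
      v <- diffm[cbind(i[ok] + 1L, j[ok] + 1L)]
      vals <- c(vals, v[!is.na(v)])
    }
    if (length(vals)) {
      res$delta[d] <- mean(vals)
      res$n_pairs[d] <- length(vals)
    }
  }
  res
}
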