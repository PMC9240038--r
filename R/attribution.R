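#' Integrated-gradients attribution for one row of a frame
#'
#' Attributes the decoder's output for row `row` of frame `frame` (the
#' scalar target is the sum of the row's predicted contact probabilities
#' over the frame's real columns) to the per-step input vectors
#' `(R_row, R_j)`. The path integral of gradients from `baseline` to the
#' actual input is approximated by a midpoint Riemann sum with `steps`
#' points, so the completeness identity
#' `sum(attributions) = target(input) - target(baseline)` holds up to a
#' discretization gap that shrinks with `steps`.
#'
#' @param model A trained [hiclstm()] model.
#' @param frame 1-based frame index.
#' @param row 0-based bin index inside the frame.
#' @param baseline Baseline input: a single `2M` vector recycled to every
#'   step, or a `frame_length x 2M` matrix. Default: all zeros (the "absent
#'   locus" reference).
#' @param steps Number of path points (`>= 2`). Default 50.
#' @param check_completeness If the relative completeness gap exceeds this
#'   fraction, the number of steps is doubled (once) and the attribution
#'   recomputed. Set `NA` to skip. Default 0.05.
#' @return A `frame_length x 2M` matrix of attributions (columns 1..M:
#'   the row-representation half; M+1..2M: the column half) with attributes
#'   `target`, `target_baseline`, `completeness_gap` (relative), `cols`
#'   (0-based column bins, `NA` = padding) and `steps`.
#' @export
integrated_gradients <- function(model, frame, row, baseline = NULL,
                                 steps = 50L, check_completeness = 0.05) {
  stopifnot(inherits(model, "hiclstm_model"), steps >= 2)
  fs <- model$frame_spec
  stopifnot(frame >= 1, frame <= fs$n_frames)
  cm <- .frame_colmat(fs, frame, row, model$scan %||% "diagonal")
  cols <- cm$colmat[1, ]
  cols[!cm$valid[1, ]] <- NA_integer_
  Tlen <- fs$frame_length
  M2 <- 2L * model$rep_size

  # actual input for this row
  Xfull <- .run_frame(model, frame, row, cache = FALSE)$X
  Xin <- do.call(rbind, lapply(Xfull, function(m) m[1, ]))   # T x 2M
  if (is.null(baseline)) baseline <- numeric(M2)
  Bl <- if (is.null(dim(baseline))) {
    stopifnot(length(baseline) == M2)
    matrix(baseline, Tlen, M2, byrow = TRUE)
  } else {
    stopifnot(all(dim(baseline) == c(Tlen, M2)))
    baseline
  }
  if (any(!is.finite(Xin)) || any(!is.finite(Bl)))
    stop("non-finite input or baseline")
  mask <- as.numeric(!is.na(cols))          # real columns enter the target

  target_at <- function(Xmat) {
    X <- lapply(seq_len(Tlen), function(t) matrix(Xmat[t, ], 1))
    sum(.lstm_forward(model$params, X, cache = FALSE)$Y[1, ] * mask)
  }

  grad_fn <- function(X) {
    fwd <- .lstm_forward(model$params, X, cache = TRUE)
    if (any(!is.finite(fwd$Y))) stop("non-finite prediction along the path")
    dY <- matrix(mask, nrow(fwd$Y), Tlen, byrow = TRUE)
    .lstm_backward(model$params, X, fwd, dY)$dX
  }

  t_in <- target_at(Xin)
  t_bl <- target_at(Bl)
  A <- .ig_path_attr(grad_fn, Xin, Bl, steps)
  gap <- abs(sum(A) - (t_in - t_bl)) / max(abs(t_in - t_bl), 1e-12)
  if (!is.na(check_completeness) && gap > check_completeness) {
    steps <- 2L * steps
    A <- .ig_path_attr(grad_fn, Xin, Bl, steps)
    gap <- abs(sum(A) - (t_in - t_bl)) / max(abs(t_in - t_bl), 1e-12)
  }
  structure(A, target = t_in, target_baseline = t_bl,
            completeness_gap = gap, cols = cols, steps = steps, row = row)
}

# Midpoint-Riemann path integral of gradients from baseline Bl to input Xin
# (both T x D). `grad_fn` maps a list over T of (batch x D) path-point
# matrices to the list of per-point gradients of the scalar target.
.ig_path_attr <- function(grad_fn, Xin, Bl, steps) {
  Tlen <- nrow(Xin); D <- ncol(Xin)
  alphas <- (seq_len(steps) - 0.5) / steps
  diff <- Xin - Bl
  X <- lapply(seq_len(Tlen), function(t) {
    outer(alphas, diff[t, ]) + matrix(Bl[t, ], steps, D, byrow = TRUE)
  })
  dX <- grad_fn(X)
  do.call(rbind, lapply(seq_len(Tlen), function(t) {
    colMeans(dX[[t]]) * diff[t, ]
  }))
}

#' Aggregate attributions into a per-bin importance track
#'
#' Computes integrated gradients for every (frame, row) pair and condenses
#' them to a single raw score per genomic bin: each attribution matrix is
#' summed over representation dimensions, the row half (summed over steps)
#' counts as one occurrence for the row's bin, each column-step sum counts
#' as one occurrence for that column's bin, and a bin's score is the mean
#' over its occurrences so that coverage differences at chromosome ends do
#' not bias scores.
#'
#' @param model A trained [hiclstm()] model.
#' @param steps IG path points per row (default 50).
#' @param rows Optional 0-based subset of bins to attribute (default: all).
#' @return An `importance_track`: data.frame with `bin` (0-based), `raw`,
#'   `coverage` and `normalized` (filled by [normalize_importance()],
#'   `NA` here).
#' @export
aggregate_importance <- function(model, steps = 50L, rows = NULL) {
  stopifnot(inherits(model, "hiclstm_model"))
  fs <- model$frame_spec
  n <- model$n_bins
  M <- model$rep_size
  sums <- numeric(n); cnt <- integer(n)
  any_attr <- FALSE
  for (k in seq_len(fs$n_frames)) {
    fr <- fs$frames[k, ]
    frame_rows <- seq(fr$start, min(fr$end, n) - 1L)
    if (!is.null(rows)) frame_rows <- intersect(frame_rows, rows)
    if (!length(frame_rows)) next
    for (r in frame_rows) {
      A <- integrated_gradients(model, k, r, steps = steps,
                                check_completeness = NA)
      any_attr <- TRUE
      cols <- attr(A, "cols")
      real <- which(!is.na(cols))
      row_occ <- sum(A[, seq_len(M)])
      sums[r + 1L] <- sums[r + 1L] + row_occ
      cnt[r + 1L] <- cnt[r + 1L] + 1L
      col_occ <- rowSums(A[real, M + seq_len(M), drop = FALSE])
      jj <- cols[real] + 1L
      for (t in seq_along(jj)) {         # a column bin can repeat across rows
        sums[jj[t]] <- sums[jj[t]] + col_occ[t]
        cnt[jj[t]] <- cnt[jj[t]] + 1L
      }
    }
  }
  if (!any_attr) stop("no attributions computed (empty row set)")
  raw <- ifelse(cnt > 0, sums / pmax(cnt, 1L), NA_real_)
  structure(data.frame(bin = seq_len(n) - 1L, raw = raw, coverage = cnt,
                       normalized = NA_real_),
            class = c("importance_track", "data.frame"),
            resolution = model$resolution)
}

#' Min-max normalize an importance track
#'
#' Positive raw scores are mapped to `[0, 1]` by
#' `(IG - IG_min) / (IG_max - IG_min)` computed over the positive subset;
#' negative scores are mapped by the same formula on their absolute values
#' and then negated, giving `[-1, 0]`. Zeros stay zero. A degenerate subset
#' (all equal) maps to 1 (or -1).
#'
#' @param track An `importance_track` from [aggregate_importance()], or a
#'   bare numeric vector of raw scores.
#' @return The track with the `normalized` column filled (or a numeric
#'   vector).
#' @export
normalize_importance <- function(track) {
  raw <- if (is.data.frame(track)) track$raw else track
  ok <- !is.na(raw)
  if (!any(ok & raw != 0)) stop("importance track has no nonzero score")
  out <- rep(NA_real_, length(raw))
  out[ok & raw == 0] <- 0
  minmax <- function(v) {
    if (max(v) == min(v)) rep(1, length(v))
    else (v - min(v)) / (max(v) - min(v))
  }
  pos <- ok & raw > 0
  if (any(pos)) out[pos] <- minmax(raw[pos])
  neg <- ok & raw < 0
  if (any(neg)) out[neg] <- -minmax(abs(raw[neg]))
  if (is.data.frame(track)) { track$normalized <- out; track } else out
}

#' Average a per-bin track over scaled interval profiles
#'
#' For each interval the interior is partitioned into `n_interior`
#' equi-spaced sub-spans whose track values are averaged, and `flank` bp of
#' per-bin values are appended up- and downstream; profiles are then
#' averaged across intervals. Intervals shorter than `n_interior` bins are
#' skipped with a warning.
#'
#' @param track Numeric per-bin vector (e.g. normalized importance).
#' @param intervals data.frame with `start`/`end` in bp (0-based,
#'   half-open), e.g. from [read_bed()].
#' @param resolution Bin size in bp.
#' @param n_interior Number of interior sub-spans (default 10).
#' @param flank Flank length in bp (default 50000, i.e. 5 bins at 10 kb).
#' @return List with `profile` (length `n_interior + 2 * flank_bins`),
#'   `position` labels, and `n_used` intervals.
#' @export
aggregate_profile <- function(track, intervals, resolution, n_interior = 10L,
                              flank = 50000) {
  stopifnot(n_interior >= 1, nrow(intervals) >= 1)
  n <- length(track)
  fb <- as.integer(flank / resolution)
  profs <- list()
  for (r in seq_len(nrow(intervals))) {
    b0 <- bin_of(intervals$start[r], resolution)
    b1 <- bin_of(intervals$end[r] - 1, resolution)
    len <- b1 - b0 + 1
    if (len < n_interior) {
      warning(sprintf("interval %d spans %d bins < n_interior = %d; skipped",
                      r, len, n_interior))
      next
    }
    bins <- seq(b0, b1)
    span <- pmin(floor((bins - b0) * n_interior / len), n_interior - 1L)
    interior <- vapply(seq_len(n_interior) - 1L, function(s) {
      mean(track[bins[span == s] + 1], na.rm = TRUE)
    }, numeric(1))
    up <- track[.clamp_idx(seq(b0 - fb, b0 - 1), n) + 1]
    down <- track[.clamp_idx(seq(b1 + 1, b1 + fb), n) + 1]
    profs[[length(profs) + 1]] <- c(up, interior, down)
  }
  if (!length(profs)) stop("no interval long enough for the profile")
  profile <- colMeans(do.call(rbind, profs), na.rm = TRUE)
  list(profile = profile,
       position = c(if (fb) paste0("up", rev(seq_len(fb))),
                    paste0("interior", seq_len(n_interior)),
                    if (fb) paste0("down", seq_len(fb))),
       n_used = length(profs), flank_bins = fb)
}

# indices outside [0, n) become NA so flanks at chromosome ends are ignored
.clamp_idx <- function(idx, n) {
  idx[idx < 0 | idx >= n] <- NA_integer_
  idx
}

#' Export an importance track as bedGraph
#'
#' @param track An `importance_track`.
#' @param path Output path.
#' @param which `"normalized"` (default) or `"raw"`.
#' @param chrom Chromosome name.
#' @export
write_importance <- function(track, path, which = c("normalized", "raw"),
                             chrom = "chrS") {
  which <- match.arg(which)
  write_bedgraph(track[[which]], attr(track, "resolution"), path, chrom = chrom)
}
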