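#' Construct an untrained Hi-C representation model
#'
#' The model couples a learnable representation table (one M-vector per
#' genomic bin plus one padding row at index `n_bins`) with a layer-norm
#' LSTM decoder. The decoder scans each diagonal frame column by column,
#' fed at step `j` with the concatenation `(R_i, R_j)` of the row and column
#' representations, and emits the predicted contact probability through a
#' linear head with a sigmoid. Hidden state is reinitialized at every frame
#' boundary and at the start of every row.
#'
#' @param n_bins Number of genomic bins on the chromosome.
#' @param resolution Bin size in bp.
#' @param rep_size Representation size M (default 16).
#' @param hidden_size LSTM hidden size H (default 16).
#' @param frame_length Frame length in bins (default 150).
#' @param activation Candidate/cell activation (default `"softsign"`).
#' @param layer_norm Layer-normalize gate pre-activations (default TRUE).
#' @param scan Column-scan regime. `"diagonal"` (default): each row's
#'   sequence starts at its own diagonal, so the step index coincides with
#'   genomic distance and each unordered in-frame pair is visited once;
#'   predictions are mirrored. `"full"`: every row scans the whole frame
#'   from its left boundary (both triangles).
#' @param transform [transform_params()] used when converting counts.
#' @param seed Integer seed for parameter initialization; recorded in the
#'   model and in every saved archive.
#' @return An object of class `hiclstm_model`.
#' @export
hiclstm <- function(n_bins, resolution, rep_size = 16L, hidden_size = 16L,
                    frame_length = 150L, scan = c("diagonal", "full"),
                    activation = c("softsign", "tanh", "sigmoid"),
                    layer_norm = TRUE, transform = transform_params(),
                    seed = 1L) {
  activation <- match.arg(activation)
  scan <- match.arg(scan)
  stopifnot(n_bins >= 1, resolution >= 1)
  n_bins <- as.integer(n_bins)
  model <- with_seed(seed, {
    rep <- matrix(stats::rnorm((n_bins + 1L) * rep_size, sd = 0.1),
                  n_bins + 1L, rep_size)
    params <- lstm_params(rep_size, hidden_size, activation, layer_norm)
    list(rep = rep, params = params)
  })
  structure(
    list(rep = model$rep, params = model$params,
         n_bins = n_bins, resolution = as.numeric(resolution),
         rep_size = as.integer(rep_size), hidden_size = as.integer(hidden_size),
         frame_spec = make_frames(n_bins, frame_length), scan = scan,
         transform = transform, config = NULL,
         loss_log = numeric(0), seed = as.integer(seed)),
    class = "hiclstm_model"
  )
}

#' @export
print.hiclstm_model <- function(x, ...) {
  cat(sprintf(paste0(
    "hiclstm_model: %d bins at %g bp, M = %d, H = %d, %d frame(s) of %d\n",
    "  activation %s, layer norm %s, %s\n"),
    x$n_bins, x$resolution, x$rep_size, x$hidden_size,
    x$frame_spec$n_frames, x$frame_spec$frame_length,
    x$params$activation, x$params$layer_norm,
    if (length(x$loss_log)) sprintf("trained %d epoch(s), last loss %.3g",
                                    length(x$loss_log), utils::tail(x$loss_log, 1))
    else "untrained"))
  invisible(x)
}

# padding row index (1-based) of a representation table with n real bins
.pad_row <- function(rep) nrow(rep)

# Per-row column bins of frame k as a B x T matrix plus validity mask.
# In the diagonal regime row r scans columns r, r+1, ... to the frame end;
# in the full regime every row scans the whole frame. Steps beyond the
# frame or chromosome are fed the padding representation and flagged
# invalid.
.frame_colmat <- function(frame_spec, k, rows, scan) {
  fr <- frame_spec$frames[k, ]
  Tlen <- frame_spec$frame_length
  colmat <- if (scan == "diagonal")
    outer(rows, seq_len(Tlen) - 1L, "+")
  else
    matrix(seq(fr$start, fr$end - 1L), length(rows), Tlen, byrow = TRUE)
  valid <- colmat < min(fr$end, frame_spec$n_bins)
  list(colmat = colmat, valid = valid)
}

# Build the step-input list for `rows` (0-based) scanning frame k and run the
# decoder. `rep` overrides the model's table; X_override bypasses the table
# entirely (used by integrated gradients).
.run_frame <- function(model, k, rows, rep = NULL, cache = FALSE,
                       X_override = NULL, frame_spec = NULL) {
  rep <- rep %||% model$rep
  frame_spec <- frame_spec %||% .frames_for(model, rep)
  cm <- .frame_colmat(frame_spec, k, rows, model$scan %||% "diagonal")
  if (is.null(X_override)) {
    B <- length(rows); M <- ncol(rep)
    pad <- .pad_row(rep)
    Rrows <- rep[rows + 1L, , drop = FALSE]
    X <- lapply(seq_len(ncol(cm$colmat)), function(t) {
      idx <- ifelse(cm$valid[, t], cm$colmat[, t] + 1L, pad)
      cbind(Rrows, rep[idx, , drop = FALSE])
    })
  } else {
    X <- X_override
  }
  fwd <- .lstm_forward(model$params, X, cache = cache)
  list(Y = fwd$Y, caches = fwd$caches, X = X,
       colmat = cm$colmat, valid = cm$valid, rows = rows)
}

# frame spec matching a (possibly overriding) representation table
.frames_for <- function(model, rep) {
  n <- nrow(rep) - 1L
  if (n == model$n_bins) model$frame_spec
  else make_frames(n, model$frame_spec$frame_length)
}

#' Predict one diagonal frame
#'
#' Runs the decoder over frame `frame` for the requested rows. Hidden and
#' cell state start at zero at each row's sequence start; columns are
#' scanned left to right (from the row's own diagonal in the default
#' regime, from the frame boundary with `scan = "full"`). Padded tail steps
#' are predicted but flagged invalid.
#'
#' @param model A [hiclstm()] model.
#' @param frame 1-based frame index.
#' @param rows 0-based bin indices; must lie inside the frame (the
#'   diagonal-frame regime). Default: every real bin of the frame.
#' @param rep Optional representation override, `(n_bins + 1) x M`.
#' @return List with `pred` (rows x frame_length matrix of probabilities),
#'   `rows` (0-based), `cols` (rows x frame_length matrix of 0-based column
#'   bins) and `valid` (logical mask of modeled steps).
#' @export
forward_frame <- function(model, frame, rows = NULL, rep = NULL) {
  stopifnot(inherits(model, "hiclstm_model"))
  rep <- rep %||% model$rep
  .check_override(model, rep)
  fs <- .frames_for(model, rep)
  stopifnot(frame >= 1, frame <= fs$n_frames)
  fr <- fs$frames[frame, ]
  real_end <- min(fr$end, fs$n_bins)
  if (is.null(rows)) rows <- seq(fr$start, real_end - 1L)
  if (any(rows < fr$start | rows >= real_end))
    stop("rows must lie inside the frame (diagonal-frame regime)")
  run <- .run_frame(model, frame, rows, rep = rep, frame_spec = fs)
  list(pred = run$Y, rows = rows, cols = run$colmat, valid = run$valid)
}

.check_override <- function(model, rep) {
  if (ncol(rep) != model$rep_size)
    stop("representation override has incompatible width (expected M = ",
         model$rep_size, ")")
  if (nrow(rep) < 2)
    stop("representation override must have at least one bin plus a padding row")
}

#' Predict the full contact matrix
#'
#' Assembles the dense predicted probability matrix from all diagonal
#' frames. Pairs whose bins fall in different frames are not modeled and are
#' reported as `NA`. With a representation override of a different length
#' (e.g. after a tandem duplication) the frame tiling is re-derived for the
#' new chromosome length while the decoder parameters stay fixed.
#'
#' @param model A [hiclstm()] model.
#' @param rep Optional `(n_bins' + 1) x M` representation override.
#' @return A [contact_matrix()] of kind `"probability"`.
#' @export
predict_matrix <- function(model, rep = NULL) {
  stopifnot(inherits(model, "hiclstm_model"))
  rep <- rep %||% model$rep
  .check_override(model, rep)
  fs <- .frames_for(model, rep)
  n <- fs$n_bins
  out <- matrix(NA_real_, n, n)
  diagonal <- (model$scan %||% "diagonal") == "diagonal"
  for (k in seq_len(fs$n_frames)) {
    fr <- fs$frames[k, ]
    rows <- seq(fr$start, min(fr$end, n) - 1L)
    run <- .run_frame(model, k, rows, rep = rep, frame_spec = fs)
    v <- which(run$valid, arr.ind = TRUE)
    ri <- rows[v[, 1]] + 1L
    ci <- run$colmat[v] + 1L
    out[cbind(ri, ci)] <- run$Y[v]
    if (diagonal) out[cbind(ci, ri)] <- run$Y[v]
  }
  contact_matrix(out, model$resolution, "probability")
}

#' Save / load a model archive
#'
#' The archive is a single versioned file holding all parameter tables and
#' metadata (seed, M, H, frame length, transform constants). A round trip
#' restores a bit-identical predictor.
#'
#' @param model A [hiclstm()] model.
#' @param path File path.
#' @return `save_hiclstm()` returns `path` invisibly; `load_hiclstm()`
#'   returns the model.
#' @export
save_hiclstm <- function(model, path) {
  stopifnot(inherits(model, "hiclstm_model"))
  saveRDS(list(format = "hiclstm-model", format_version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_hiclstm
#' @export
load_hiclstm <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model archive '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "hiclstm-model"))
    stop("'", path, "' is not a model archive")
  if (!identical(obj$format_version, 1L))
    stop("unsupported model archive version: ", obj$format_version)
  obj$model
}

#' Export the representation table as TSV
#'
#' Writes `bin <TAB> f1 .. fM` with one row per genomic bin (0-based) plus a
#' final row labeled `padding`.
#'
#' @param model A [hiclstm()] model (or a bare representation matrix).
#' @param path Output path.
#' @export
export_representations <- function(model, path) {
  rep <- if (inherits(model, "hiclstm_model")) model$rep else as.matrix(model)
  n <- nrow(rep) - 1L
  df <- data.frame(bin = c(as.character(seq_len(n) - 1L), "padding"),
                   rep, check.names = FALSE)
  colnames(df) <- c("bin", paste0("f", seq_len(ncol(rep))))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a per-bin representation TSV
#'
#' Accepts the format written by [export_representations()] (any numeric
#' feature columns after a `bin` column); rows labeled `padding` are dropped.
#' This is also the entry point for evaluating representations produced by
#' other tools.
#'
#' @param path TSV path.
#' @return Numeric matrix with one row per bin, ordered by bin.
#' @export
read_representations <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE)
  df <- df[df$bin != "padding", ]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m[order(as.integer(df$bin)), , drop = FALSE]
}
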