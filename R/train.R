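#' Training configuration
#'
#' Training recipe: mini-batches of row-sequences,
#' Adam with framework-default moments, global gradient-norm clipping, and a
#' two-stage learning-rate schedule (0.01 for 5 epochs, then 0.001 for 5).
#'
#' @param batch_size Row-sequences per optimization step. The default of 4
#'   suits chromosome-scale-or-smaller inputs trained for few epochs on one
#'   CPU; genome-scale training conventionally uses 2000 row-sequences per
#'   batch, which is appropriate when the input provides hundreds of
#'   thousands of sequences.
#' @param schedule Data frame with columns `lr` and `epochs`; rows are run
#'   in order.
#' @param clip_norm Global gradient-norm clip (default 1).
#' @param seed Integer seed controlling initialization-free randomness of
#'   the run (sequence shuffling); recorded in the trained model.
#' @param shuffle Shuffle row-sequence order each epoch (default TRUE).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment constants.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 4L,
                            schedule = data.frame(lr = c(0.01, 0.001),
                                                  epochs = c(5L, 5L)),
                            clip_norm = 1, seed = 1L, shuffle = TRUE,
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            adam_eps = 1e-8) {
  stopifnot(batch_size >= 1, clip_norm > 0,
            is.data.frame(schedule), all(c("lr", "epochs") %in% names(schedule)),
            all(schedule$lr > 0), all(schedule$epochs >= 0))
  structure(list(batch_size = as.integer(batch_size), schedule = schedule,
                 clip_norm = clip_norm, seed = as.integer(seed),
                 shuffle = isTRUE(shuffle),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps),
            class = "training_config")
}

# ---- flat parameter-vector plumbing for Adam + clipping --------------------

.collect <- function(model) {
  p <- model$params
  c(list(rep = model$rep),
    stats::setNames(p$W, paste0("W.", .GATES)),
    stats::setNames(p$U, paste0("U.", .GATES)),
    stats::setNames(p$b, paste0("b.", .GATES)),
    stats::setNames(p$gamma, paste0("gamma.", .GATES)),
    stats::setNames(p$beta, paste0("beta.", .GATES)),
    list(head_w = p$head_w, head_b = p$head_b))
}

.restore <- function(model, flat) {
  model$rep <- flat$rep
  for (g in .GATES) {
    model$params$W[[g]] <- flat[[paste0("W.", g)]]
    model$params$U[[g]] <- flat[[paste0("U.", g)]]
    model$params$b[[g]] <- flat[[paste0("b.", g)]]
    model$params$gamma[[g]] <- flat[[paste0("gamma.", g)]]
    model$params$beta[[g]] <- flat[[paste0("beta.", g)]]
  }
  model$params$head_w <- flat$head_w
  model$params$head_b <- flat$head_b
  model
}

.grads_as_flat <- function(gr, gRep) {
  c(list(rep = gRep),
    stats::setNames(gr$W, paste0("W.", .GATES)),
    stats::setNames(gr$U, paste0("U.", .GATES)),
    stats::setNames(gr$b, paste0("b.", .GATES)),
    stats::setNames(gr$gamma, paste0("gamma.", .GATES)),
    stats::setNames(gr$beta, paste0("beta.", .GATES)),
    list(head_w = gr$head_w, head_b = gr$head_b))
}

.adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(flat, grads, state, lr, cfg) {
  gn2 <- sum(vapply(grads, function(g) sum(g * g), numeric(1)))
  gn <- sqrt(gn2)
  if (gn > cfg$clip_norm)
    grads <- lapply(grads, function(g) g * (cfg$clip_norm / gn))
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + cfg$adam_eps)
  }
  list(flat = flat, state = state)
}

# ---- training --------------------------------------------------------------

#' Train the model on a contact-probability matrix
#'
#' Jointly optimizes the representation table and the LSTM decoder by
#' gradient descent on the mean squared error between predicted and observed
#' contact probabilities over all pairs within diagonal frames. Each
#' row-sequence (one row scanning one frame) is an independent training
#' sequence; padded steps and `NA` targets are masked out of the loss. The
#' run is exactly reproducible from the seed.
#'
#' @param model A [hiclstm()] model.
#' @param contacts A [contact_matrix()] of kind `"probability"` with
#'   `n_bins` matching the model.
#' @param config A [training_config()].
#' @param mask Optional `n_bins x n_bins` logical matrix; only `TRUE`
#'   entries enter the loss (used by [fine_tune()]).
#' @param init_head_bias On a freshly initialized model, start the output
#'   head's offset at the logit of the mean target probability (base-rate
#'   initialization; default TRUE). Ignored for already-trained models.
#' @return The trained model, with one training-loss value per epoch
#'   appended to `loss_log`.
#' @export
train_hiclstm <- function(model, contacts, config = training_config(),
                          mask = NULL, init_head_bias = TRUE) {
  stopifnot(inherits(model, "hiclstm_model"),
            inherits(contacts, "contact_matrix"),
            inherits(config, "training_config"))
  if (contacts$kind != "probability")
    stop("contacts must be of kind 'probability' (see to_probability())")
  if (contacts$n_bins != model$n_bins)
    stop("contacts have ", contacts$n_bins, " bins but model expects ",
         model$n_bins)
  target <- contacts$values
  keep <- !is.na(target)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(target)))
    keep <- keep & mask
  }
  if ((model$scan %||% "diagonal") == "diagonal")
    keep <- keep | t(keep)      # each unordered pair is visited once
  fs <- model$frame_spec
  # row-sequences: (frame, row) pairs that contribute at least one target
  seqs <- do.call(rbind, lapply(seq_len(fs$n_frames), function(k) {
    fr <- fs$frames[k, ]
    rows <- seq(fr$start, min(fr$end, fs$n_bins) - 1L)
    cm <- .frame_colmat(fs, k, rows, model$scan %||% "diagonal")
    has <- vapply(seq_along(rows), function(r) {
      jj <- cm$colmat[r, cm$valid[r, ]]
      any(keep[rows[r] + 1L, jj + 1L])
    }, logical(1))
    if (!any(has)) return(NULL)
    data.frame(frame = k, row = rows[has])
  }))
  if (is.null(seqs) || nrow(seqs) == 0)
    stop("no observed target entries fall inside any frame")

  if (init_head_bias && length(model$loss_log) == 0) {
    p0 <- min(max(mean(target[keep], na.rm = TRUE), 1e-6), 1 - 1e-6)
    model$params$head_b <- stats::qlogis(p0)
  }
  flat <- .collect(model)
  state <- .adam_init(flat)
  total_epochs <- sum(config$schedule$epochs)
  lr_per_epoch <- rep(config$schedule$lr, config$schedule$epochs)
  loss_log <- numeric(0)
  Tlen <- fs$frame_length

  with_seed(config$seed, {
    for (epoch in seq_len(total_epochs)) {
      ord <- if (config$shuffle) sample.int(nrow(seqs)) else seq_len(nrow(seqs))
      starts <- seq(1L, nrow(seqs), by = config$batch_size)
      epoch_sse <- 0; epoch_n <- 0
      for (s in starts) {
        batch <- seqs[ord[seq(s, min(s + config$batch_size - 1L, nrow(seqs)))], ]
        n_seq <- nrow(batch)
        gr_acc <- NULL
        gRep <- matrix(0, nrow(flat$rep), ncol(flat$rep))
        model_cur <- .restore(model, flat)
        for (k in unique(batch$frame)) {
          rows <- batch$row[batch$frame == k]
          run <- .run_frame(model_cur, k, rows, cache = TRUE)
          m_ok <- run$valid
          tgt <- matrix(0, length(rows), Tlen)
          v <- which(m_ok, arr.ind = TRUE)
          tgt[v] <- target[cbind(rows[v[, 1]] + 1L, run$colmat[v] + 1L)]
          m_ok[v] <- m_ok[v] & keep[cbind(rows[v[, 1]] + 1L, run$colmat[v] + 1L)]
          tgt[is.na(tgt)] <- 0
          err <- run$Y - tgt
          err[!m_ok] <- 0
          epoch_sse <- epoch_sse + sum(err^2)
          epoch_n <- epoch_n + sum(m_ok)
          # per-row mean squared error, rows weighted equally in the batch
          n_pair_row <- pmax(rowSums(m_ok), 1L)
          dY <- 2 * err / (n_pair_row * n_seq)
          bwd <- .lstm_backward(model_cur$params, run$X, run, dY)
          gr_acc <- if (is.null(gr_acc)) bwd$grads else
            .add_grads(gr_acc, bwd$grads)
          gRep <- .accumulate_rep_grad(gRep, bwd$dX, rows, run, model_cur)
        }
        step <- .adam_step(flat, .grads_as_flat(gr_acc, gRep), state,
                           lr_per_epoch[epoch], config)
        flat <- step$flat; state <- step$state
      }
      epoch_loss <- epoch_sse / epoch_n
      if (!is.finite(epoch_loss))
        stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate",
                     epoch))
      loss_log <- c(loss_log, epoch_loss)
    }
  })
  model <- .restore(model, flat)
  model$loss_log <- c(model$loss_log, loss_log)
  model$config <- config
  model
}

.add_grads <- function(a, b) {
  for (g in .GATES) {
    a$W[[g]] <- a$W[[g]] + b$W[[g]]
    a$U[[g]] <- a$U[[g]] + b$U[[g]]
    a$b[[g]] <- a$b[[g]] + b$b[[g]]
    a$gamma[[g]] <- a$gamma[[g]] + b$gamma[[g]]
    a$beta[[g]] <- a$beta[[g]] + b$beta[[g]]
  }
  a$head_w <- a$head_w + b$head_w
  a$head_b <- a$head_b + b$head_b
  a
}

# route dX (list over steps of B x 2M) back to representation rows:
# first half -> the batch rows (fed at every step), second half -> the
# column bin of the step (padding row for out-of-range steps).
.accumulate_rep_grad <- function(gRep, dX, rows, run, model) {
  M <- model$rep_size
  pad <- .pad_row(model$rep)
  row_idx <- rows + 1L
  d1 <- Reduce(`+`, lapply(dX, function(d) d[, seq_len(M), drop = FALSE]))
  gRep[row_idx, ] <- gRep[row_idx, ] + d1
  idxmat <- ifelse(run$valid, run$colmat + 1L, pad)           # B x T
  d2 <- do.call(rbind, lapply(dX, function(d) d[, M + seq_len(M), drop = FALSE]))
  agg <- rowsum(d2, group = as.vector(idxmat))
  tgt_rows <- as.integer(rownames(agg))
  gRep[tgt_rows, ] <- gRep[tgt_rows, , drop = FALSE] + agg
  gRep
}

#' Continue training on a sub-region (transfer / fine-tuning)
#'
#' Restricts the loss to the observed entries of `contacts` (non-`NA`, and
#' optionally only pairs with both bins in `bins`), then continues
#' optimization. Representations of bins that never appear in a frame
#' containing observed entries are untouched. With a schedule totaling zero
#' epochs the model is returned unchanged.
#'
#' @param model A trained [hiclstm()] model.
#' @param contacts [contact_matrix()] of kind `"probability"`; entries not
#'   to be trained on should be `NA`.
#' @param config A [training_config()] (typically fewer epochs, lower lr).
#' @param bins Optional 0-based bin subset defining the sub-region.
#' @return The fine-tuned model.
#' @export
fine_tune <- function(model, contacts, config = training_config(), bins = NULL) {
  mask <- NULL
  if (!is.null(bins)) {
    stopifnot(all(bins >= 0), all(bins < model$n_bins))
    inb <- logical(model$n_bins)
    inb[bins + 1L] <- TRUE
    mask <- outer(inb, inb, "&")
  }
  obs <- !is.na(contacts$values)
  if (!is.null(mask)) obs <- obs & mask
  if (!any(obs)) stop("no observed entries to fine-tune on")
  if (sum(config$schedule$epochs) == 0) return(model)
  train_hiclstm(model, contacts, config, mask = mask)
}
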