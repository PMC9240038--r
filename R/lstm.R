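# Numeric core: batched layer-norm LSTM with explicit forward/backward.
#
# Shapes: a "step" processes a batch of B independent sequences at one time
# point. X_t is B x 2M (concatenated row/column representations), hidden and
# cell states are B x H. Input weights W are 2M x H ("x %*% W" layout),
# recurrent weights U are H x H. Layer norm is applied to each gate
# pre-activation across the H units of each sample, with learnable gain and
# offset per gate.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.phi <- function(x, activation) {
  switch(activation,
         softsign = x / (1 + abs(x)),
         tanh = tanh(x),
         sigmoid = .sigmoid(x),
         stop("unknown activation: ", activation))
}

# derivative of phi expressed through its output (valid for all three)
.dphi_from_out <- function(out, activation) {
  switch(activation,
         softsign = (1 - abs(out))^2,
         tanh = 1 - out^2,
         sigmoid = out * (1 - out))
}

.GATES <- c("f", "i", "o", "g")

#' Initialize LSTM decoder parameters
#'
#' Gate weights are drawn uniformly from `[-1/sqrt(H), 1/sqrt(H)]`, biases
#' start at zero, layer-norm gains at one and offsets at zero except the
#' forget-gate offset which starts at one (the usual "remember by default"
#' initialization; without layer norm the forget bias itself starts at one).
#'
#' @param rep_size Representation size M; the input dimension is `2 * M`.
#' @param hidden_size Hidden size H.
#' @param activation Candidate/cell activation: `"softsign"` (default),
#'   `"tanh"` or `"sigmoid"`. Gates always use the logistic sigmoid.
#' @param layer_norm Apply layer normalization to gate pre-activations.
#' @return A list of parameter arrays of class `lstm_params`.
#' @export
lstm_params <- function(rep_size = 16L, hidden_size = 16L,
                        activation = c("softsign", "tanh", "sigmoid"),
                        layer_norm = TRUE) {
  activation <- match.arg(activation)
  M <- as.integer(rep_size); H <- as.integer(hidden_size)
  stopifnot(M >= 1, H >= 1)
  k <- 1 / sqrt(H)
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  p <- list(
    W = lapply(stats::setNames(.GATES, .GATES), function(.) rmat(2L * M, H)),
    U = lapply(stats::setNames(.GATES, .GATES), function(.) rmat(H, H)),
    b = lapply(stats::setNames(.GATES, .GATES), function(.) numeric(H)),
    gamma = lapply(stats::setNames(.GATES, .GATES), function(.) rep(1, H)),
    beta = lapply(stats::setNames(.GATES, .GATES), function(.) numeric(H)),
    head_w = stats::runif(H, -k, k),
    head_b = 0,
    M = M, H = H, activation = activation,
    layer_norm = layer_norm, ln_eps = 1e-5
  )
  if (layer_norm) p$beta$f <- rep(1, H) else p$b$f <- rep(1, H)
  class(p) <- "lstm_params"
  p
}

#' One LSTM cell step
#'
#' Computes gates `f, i, o = sigmoid(layer-normed pre-activations)`, the
#' candidate through the configured activation, `c' = f * c + i * phi(cand)`
#' and `h' = o * phi(c')` for a batch of inputs.
#'
#' @param x Input matrix `B x 2M` (a vector is treated as one sample).
#' @param h,c Previous hidden/cell state, `B x H` (or vectors).
#' @param params An [lstm_params()] object.
#' @return List with matrices `h` and `c` (`B x H`).
#' @export
lstm_cell <- function(x, h, c, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  if (is.null(dim(c))) c <- matrix(c, nrow = 1)
  if (any(!is.finite(x)) || any(!is.finite(h)) || any(!is.finite(c)))
    stop("non-finite input to lstm_cell")
  st <- .lstm_step(x, h, c, params, cache = FALSE)
  list(h = st$h, c = st$c)
}

# single step; with cache = TRUE returns everything the backward pass needs
.lstm_step <- function(X, h_prev, c_prev, params, cache = FALSE) {
  B <- nrow(X); H <- params$H
  A <- vector("list", 4); names(A) <- .GATES
  zhat <- inv <- A
  for (g in .GATES) {
    Z <- X %*% params$W[[g]] + h_prev %*% params$U[[g]] +
      matrix(params$b[[g]], B, H, byrow = TRUE)
    if (params$layer_norm) {
      mu <- rowMeans(Z)
      zc <- Z - mu
      va <- rowMeans(zc * zc)
      iv <- 1 / sqrt(va + params$ln_eps)
      zh <- zc * iv
      A[[g]] <- zh * matrix(params$gamma[[g]], B, H, byrow = TRUE) +
        matrix(params$beta[[g]], B, H, byrow = TRUE)
      if (cache) { zhat[[g]] <- zh; inv[[g]] <- iv }
    } else {
      A[[g]] <- Z
    }
  }
  f <- .sigmoid(A$f); i <- .sigmoid(A$i); o <- .sigmoid(A$o)
  gc <- .phi(A$g, params$activation)
  c_new <- f * c_prev + i * gc
  hc <- .phi(c_new, params$activation)
  h_new <- o * hc
  out <- list(h = h_new, c = c_new)
  if (cache)
    out <- c(out, list(f = f, i = i, o = o, gc = gc, hc = hc,
                       c_prev = c_prev, h_prev = h_prev,
                       zhat = zhat, inv = inv))
  out
}

# Forward over a sequence of T steps for B parallel sequences.
# X: list of T matrices (B x 2M). Returns Y (B x T, sigmoid head output)
# and, if cache, the per-step caches.
.lstm_forward <- function(params, X, cache = FALSE) {
  T_ <- length(X); B <- nrow(X[[1]]); H <- params$H
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  Y <- matrix(0, B, T_)
  caches <- if (cache) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    st <- .lstm_step(X[[t]], h, c, params, cache = cache)
    h <- st$h; c <- st$c
    Y[, t] <- .sigmoid(drop(h %*% params$head_w) + params$head_b)
    if (cache) { st$y <- Y[, t]; caches[[t]] <- st }
  }
  list(Y = Y, caches = caches)
}

.zero_grads <- function(params) {
  list(
    W = lapply(params$W, function(m) matrix(0, nrow(m), ncol(m))),
    U = lapply(params$U, function(m) matrix(0, nrow(m), ncol(m))),
    b = lapply(params$b, function(v) numeric(length(v))),
    gamma = lapply(params$gamma, function(v) numeric(length(v))),
    beta = lapply(params$beta, function(v) numeric(length(v))),
    head_w = numeric(length(params$head_w)),
    head_b = 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backward through the whole sequence. dY is B x T (dLoss/dy at each step).
# Returns parameter gradients and dX (list of T matrices B x 2M).
.lstm_backward <- function(params, X, fwd, dY) {
  T_ <- length(X); B <- nrow(X[[1]]); H <- params$H
  gr <- .zero_grads(params)
  dX <- vector("list", T_)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  act <- params$activation
  for (t in rev(seq_len(T_))) {
    cc <- fwd$caches[[t]]
    y <- cc$y
    dlogit <- dY[, t] * y * (1 - y)
    gr$head_w <- gr$head_w + drop(crossprod(cc$h, dlogit))
    gr$head_b <- gr$head_b + sum(dlogit)
    dh <- dh_next + tcrossprod(dlogit, params$head_w)
    do_ <- dh * cc$hc
    dc <- dc_next + dh * cc$o * .dphi_from_out(cc$hc, act)
    df <- dc * cc$c_prev
    di <- dc * cc$gc
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    dA <- list(f = df * cc$f * (1 - cc$f),
               i = di * cc$i * (1 - cc$i),
               o = do_ * cc$o * (1 - cc$o),
               g = dg * .dphi_from_out(cc$gc, act))
    dXt <- matrix(0, B, 2L * params$M)
    dh_prev <- matrix(0, B, H)
    for (g in .GATES) {
      if (params$layer_norm) {
        gr$gamma[[g]] <- gr$gamma[[g]] + colSums(dA[[g]] * cc$zhat[[g]])
        gr$beta[[g]] <- gr$beta[[g]] + colSums(dA[[g]])
        dzhat <- dA[[g]] * matrix(params$gamma[[g]], B, H, byrow = TRUE)
        m1 <- rowMeans(dzhat)
        m2 <- rowMeans(dzhat * cc$zhat[[g]])
        dZ <- cc$inv[[g]] * (dzhat - m1 - cc$zhat[[g]] * m2)
      } else {
        dZ <- dA[[g]]
      }
      gr$W[[g]] <- gr$W[[g]] + crossprod(X[[t]], dZ)
      gr$U[[g]] <- gr$U[[g]] + crossprod(cc$h_prev, dZ)
      gr$b[[g]] <- gr$b[[g]] + colSums(dZ)
      dXt <- dXt + tcrossprod(dZ, params$W[[g]])
      dh_prev <- dh_prev + tcrossprod(dZ, params$U[[g]])
    }
    dX[[t]] <- dXt
    dh_next <- dh_prev
  }
  list(grads = gr, dX = dX)
}
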