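random_params <- function(M = 3L, H = 4L, activation = "softsign",
                          layer_norm = TRUE) {
  p <- lstm_params(M, H, activation, layer_norm)
  for (g in c("f", "i", "o", "g")) {
    p$W[[g]] <- matrix(rnorm(2 * M * H, sd = 0.5), 2 * M, H)
    p$U[[g]] <- matrix(rnorm(H * H, sd = 0.5), H, H)
    p$b[[g]] <- rnorm(H, sd = 0.3)
    p$gamma[[g]] <- runif(H, 0.5, 1.5)
    p$beta[[g]] <- rnorm(H, sd = 0.3)
  }
  p$head_w <- rnorm(H, sd = 0.5)
  p$head_b <- rnorm(1)
  p
}

test_that("all-zero parameters give the fixed point (0, 0)", {
  p <- lstm_params(2, 3)
  for (g in c("f", "i", "o", "g")) {
    p$W[[g]][] <- 0; p$U[[g]][] <- 0; p$b[[g]][] <- 0
    p$gamma[[g]][] <- 0; p$beta[[g]][] <- 0
  }
  st <- lstm_cell(rnorm(4), numeric(3), numeric(3), p)
  # gates are sigmoid(0) = 0.5 and the candidate is phi(0) = 0
  expect_equal(st$c, matrix(0, 1, 3))
  expect_equal(st$h, matrix(0, 1, 3))
})

test_that("vectorized cell matches the scalar brute-force recurrence", {
  set.seed(101)
  for (case in 1:100) {
    layer_norm <- case %% 2 == 0
    act <- c("softsign", "tanh", "sigmoid")[case %% 3 + 1]
    p <- random_params(activation = act, layer_norm = layer_norm)
    x <- rnorm(6); h <- rnorm(4, sd = 0.5); c <- rnorm(4, sd = 0.5)
    got <- lstm_cell(x, h, c, p)
    want <- oracle_cell(x, h, c, p)
    expect_lt(max(abs(got$h - want$h)), 1e-10)
    expect_lt(max(abs(got$c - want$c)), 1e-10)
  }
})

test_that("layer norm off with tanh reduces to the textbook LSTM", {
  set.seed(7)
  p <- random_params(activation = "tanh", layer_norm = FALSE)
  x <- rnorm(6); h <- rnorm(4); c <- rnorm(4)
  got <- lstm_cell(x, h, c, p)
  # textbook recurrence written out directly
  sig <- function(z) 1 / (1 + exp(-z))
  zf <- drop(x %*% p$W$f + h %*% p$U$f) + p$b$f
  zi <- drop(x %*% p$W$i + h %*% p$U$i) + p$b$i
  zo <- drop(x %*% p$W$o + h %*% p$U$o) + p$b$o
  zg <- drop(x %*% p$W$g + h %*% p$U$g) + p$b$g
  cn <- sig(zf) * c + sig(zi) * tanh(zg)
  expect_equal(drop(got$c), cn, tolerance = 1e-12)
  expect_equal(drop(got$h), sig(zo) * tanh(cn), tolerance = 1e-12)
})

test_that("cell rejects non-finite input", {
  p <- lstm_params(2, 3)
  expect_error(lstm_cell(c(1, NaN, 0, 0), numeric(3), numeric(3), p),
               "non-finite")
})

test_that("sequence backward matches finite differences", {
  set.seed(42)
  p <- random_params()
  Tn <- 5; B <- 2
  X <- lapply(1:Tn, function(t) matrix(rnorm(B * 6), B))
  tgt <- matrix(runif(B * Tn), B, Tn)
  lossfun <- function(params, X) {
    sum((hiclstm:::.lstm_forward(params, X, cache = FALSE)$Y - tgt)^2)
  }
  fwd <- hiclstm:::.lstm_forward(p, X, cache = TRUE)
  bwd <- hiclstm:::.lstm_backward(p, X, fwd, 2 * (fwd$Y - tgt))
  eps <- 1e-6
  fd <- function(mutate) {
    (lossfun(mutate(p, eps), X) - lossfun(mutate(p, -eps), X)) / (2 * eps)
  }
  expect_equal(bwd$grads$W$f[1, 2],
               fd(function(p, e) { p$W$f[1, 2] <- p$W$f[1, 2] + e; p }),
               tolerance = 1e-5)
  expect_equal(bwd$grads$gamma$o[2],
               fd(function(p, e) { p$gamma$o[2] <- p$gamma$o[2] + e; p }),
               tolerance = 1e-5)
  expect_equal(bwd$grads$head_w[3],
               fd(function(p, e) { p$head_w[3] <- p$head_w[3] + e; p }),
               tolerance = 1e-5)
  # gradient w.r.t. an input coordinate
  X2 <- X; X2[[3]][1, 4] <- X[[3]][1, 4] + eps
  X3 <- X; X3[[3]][1, 4] <- X[[3]][1, 4] - eps
  expect_equal(bwd$dX[[3]][1, 4],
               (lossfun(p, X2) - lossfun(p, X3)) / (2 * eps),
               tolerance = 1e-5)
})
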