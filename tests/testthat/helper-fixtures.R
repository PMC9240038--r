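# Shared fixtures, built lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

# default synthetic chromosome (300 bins, seed 7) and its probability map
fixture_sim <- function() {
  if (is.null(.fx$sim)) {
    .fx$sim <- generate_chromosome()
    .fx$cp <- to_probability(.fx$sim$contacts)
  }
  list(sim = .fx$sim, cp = .fx$cp)
}

# the default-fixture model trained under the default 10-epoch recipe;
# trained once per test run (a couple of minutes on one CPU)
fixture_model <- function() {
  if (is.null(.fx$model)) {
    fx <- fixture_sim()
    m <- hiclstm(n_bins = 300, resolution = 10000, seed = 7)
    .fx$model <- train_hiclstm(m, fx$cp, training_config(seed = 7))
  }
  .fx$model
}

# a larger chromosome with 20 loops for knockout-direction checks
anchor_world <- function() {
  if (is.null(.fx$anchor)) {
    sim <- generate_chromosome(n_bins = 700, n_tads = 20, seed = 7)
    cp <- to_probability(sim$contacts)
    m <- hiclstm(n_bins = 700, resolution = 10000, seed = 7)
    .fx$anchor <- list(model = train_hiclstm(m, cp, training_config(seed = 7)),
                       truth = sim$truth, cp = cp)
  }
  .fx$anchor
}

# a tiny quickly-trained model for plumbing tests (2 epochs, 60 bins)
tiny_model <- function() {
  if (is.null(.fx$tiny)) {
    sim <- generate_chromosome(n_bins = 60, seed = 11)
    cp <- to_probability(sim$contacts)
    m <- hiclstm(n_bins = 60, resolution = 10000, frame_length = 30, seed = 11)
    cfg <- training_config(schedule = data.frame(lr = 0.01, epochs = 2), seed = 11)
    .fx$tiny <- train_hiclstm(m, cp, cfg)
    .fx$tiny_cp <- cp
    .fx$tiny_sim <- sim
  }
  list(model = .fx$tiny, cp = .fx$tiny_cp, sim = .fx$tiny_sim)
}

# independent scalar re-implementation of the layer-norm LSTM cell,
# written as plain loops over hidden units (the brute-force oracle)
oracle_cell <- function(x, h, c, p) {
  H <- p$H
  act <- function(a) switch(p$activation,
                            softsign = a / (1 + abs(a)),
                            tanh = tanh(a),
                            sigmoid = 1 / (1 + exp(-a)))
  sig <- function(a) 1 / (1 + exp(-a))
  pre <- function(W, U, b) {
    z <- numeric(H)
    for (u in seq_len(H)) {
      s <- b[u]
      for (d in seq_along(x)) s <- s + W[d, u] * x[d]
      for (d in seq_len(H)) s <- s + U[d, u] * h[d]
      z[u] <- s
    }
    z
  }
  ln <- function(z, gamma, beta) {
    if (!p$layer_norm) return(z)
    mu <- sum(z) / H
    va <- sum((z - mu)^2) / H
    gamma * (z - mu) / sqrt(va + p$ln_eps) + beta
  }
  af <- ln(pre(p$W$f, p$U$f, p$b$f), p$gamma$f, p$beta$f)
  ai <- ln(pre(p$W$i, p$U$i, p$b$i), p$gamma$i, p$beta$i)
  ao <- ln(pre(p$W$o, p$U$o, p$b$o), p$gamma$o, p$beta$o)
  ag <- ln(pre(p$W$g, p$U$g, p$b$g), p$gamma$g, p$beta$g)
  f <- sig(af); i <- sig(ai); o <- sig(ao); g <- act(ag)
  c_new <- f * c + i * g
  h_new <- o * act(c_new)
  list(h = h_new, c = c_new)
}
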