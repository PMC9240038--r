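# hiclstm

Chromatin folds into domains, loops and compartments, and chromosome
conformation capture (Hi-C) measures that folding as a symmetric matrix of
contact strengths between genomic bins. `hiclstm` learns a low-dimensional
representation for every bin of an intra-chromosomal Hi-C map *jointly*
with a recurrent decoder that reconstructs the map — so the representation
of a locus is, by construction, whatever the decoder needs to know about
that locus to rebuild its contacts. The package is aimed at computational
genomicists who want, from a single trained model:

* **per-bin embeddings** usable as features for identifying genomic
  elements (TADs, loop anchors, expression-associated bins, ...),
* **a contact-generation model** whose reconstruction accuracy can be
  benchmarked against a distance-stratified mean baseline,
* **feature attribution**: integrated gradients scoring how much each
  locus drives the predicted conformation, and
* **in-silico structural variants**: knockout of binding-site bins (four
  methods), CTCF motif orientation replacement, and tandem duplication
  with read remapping onto the reference genome.

## The model in brief

Each bin `i` carries a trainable vector `R_i` (M = 16 by default; one
extra padding vector handles chromosome ends). Contacts are transformed to
probabilities `CP = exp(-a / (v + δ))` (a = 8, δ = 1e-10). A single-layer
layer-norm LSTM scans 150-bin diagonal frames; at step `t` of row `i`'s
sequence it receives `(R_i, R_j)` and predicts `Ĥ_ij` through a linear
head with a sigmoid:

    f_t = σ(LN(W_f x_t + U_f h_{t-1} + b_f))      (input, forget, output gates)
    c_t = f_t ∘ c_{t-1} + i_t ∘ φ(LN(W_c x_t + U_c h_{t-1} + b_c))
    h_t = o_t ∘ φ(c_t),   φ = softsign
    Ĥ_ij = σ(w·h_t + b)

Representations and decoder are trained jointly by MSE on the contact
probabilities (Adam, gradient clipping, 0.01 × 5 epochs then 0.001 × 5).
Perturbation experiments edit only the representation table and re-run the
fixed decoder; duplications map two predicted copies back to the reference
by summing inverse-transformed read counts.

## Worked example

Everything runs on a synthetic chromosome with known TAD/loop structure —
no downloads needed:

```r
library(hiclstm)

sim <- generate_chromosome()              # 300 bins at 10 kb, 6 TADs, seed 7
cp  <- to_probability(sim$contacts)       # counts -> contact probabilities

model <- hiclstm(n_bins = 300, resolution = 10000, seed = 7)
model <- train_hiclstm(model, cp, training_config(seed = 7))
round(model$loss_log, 4)
#>  [1] 0.1059 0.0243 0.0158 0.0124 0.0130 0.0096 0.0086 0.0081 0.0078 0.0074

pred <- predict_matrix(model)
r2   <- r2_by_distance(cp, pred, max_distance = 5e5)
r2$average
#> [1] 0.3009341
r2_by_distance(cp, distance_mean_baseline(cp), max_distance = 5e5)$average
#> [1] 0
```

The training loss falls by an order of magnitude over the ten epochs, and
the mean per-distance R² within 500 kb is ~0.30–0.60 depending on the
seed — every point of which is above the distance-mean baseline, whose
stratified R² is exactly 0 by construction. A knockout experiment then
takes three lines:

```r
anchors <- sim$truth$anchors                       # convergent loop anchors
kr <- knockout(model, c(anchors$left[1], anchors$right[1]), method = "shift")
ko <- map_to_reference(predict_matrix(model, rep = kr),
                       attr(kr, "coord_map"), model$n_bins)
eff <- effect_by_distance(predict_matrix(model), ko,
                          c(anchors$left[1], anchors$right[1]), window = 2e5)
```

`eff$delta` is the mean change in predicted contact probability at each
separation around the deleted anchors (negative = contacts lost).

A command-line wrapper with `simulate`, `train`, `predict`, `evaluate`,
`classify`, `attribute`, `knockout`, `replace-orientation` and `duplicate`
subcommands lives at `inst/cli/hiclstm.R`:

```sh
Rscript inst/cli/hiclstm.R simulate --out sim --n-bins 300 --seed 7
Rscript inst/cli/hiclstm.R train --contacts sim/contacts.txt \
    --resolution 10000 --chrom-length 3000000 --seed 7 --out run
```

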