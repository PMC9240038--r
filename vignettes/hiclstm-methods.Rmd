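---
title: "Methods: recurrent representation learning for Hi-C contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrent representation learning for Hi-C contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

An intra-chromosomal Hi-C experiment yields a symmetric matrix $H$ of
contact strengths between genomic bins at a fixed resolution (10 kb by
default here). `hiclstm` learns two things jointly:

* a **representation table** $R \in \mathbb{R}^{(N+1) \times M}$ with one
  trainable $M$-vector per bin (default $M = 16$) plus one extra *padding*
  row used for positions beyond the chromosome end, and
* an **LSTM decoder** that reconstructs $H$ from pairs of these vectors.

For a pair $(i, j)$ the decoder receives the concatenation
$(R_i, R_j) \in \mathbb{R}^{2M}$ and emits
$\hat H_{i,j} = \sigma(w^\top h_t + b)$, where $h_t$ is the hidden state of
a single-layer unidirectional LSTM with layer normalization applied to each
gate pre-activation (learnable gain and offset per gate; normalization over
the $H$ hidden units of each sample, $\varepsilon = 10^{-5}$). Gates use
the logistic sigmoid; the candidate and cell-output activations default to
*softsign* $x / (1 + |x|)$, which saturates more gently than tanh
(`tanh` and `sigmoid` are available through `hiclstm(activation=)`).
The hidden size defaults to $H = M = 16$; downstream performance in this
family of models is governed mainly by the representation size, so we tie
the two by default and leave both configurable.

Raw contact strengths span many orders of magnitude, so training targets
are **contact probabilities**
$\mathrm{CP} = \exp(-a / (v + \delta))$ with $a = 8$ and
$\delta = 10^{-10}$ (`to_probability()`). The transform is strictly
increasing and exactly invertible (`from_probability()`), which the
perturbation machinery relies on: read counts, not probabilities, are the
additive quantity when two duplicated loci are mapped onto one reference.

## Frames and the scan regime

The decoder never runs over a whole chromosome at once. The chromosome is
tiled into **frames** of 150 bins (1.5 Mb at 10 kb); hidden and cell state
are reinitialized at every frame boundary, and pairs whose bins fall in
different frames are not modeled (`predict_matrix()` reports them `NA`).
Long-range structure beyond the frame span is out of the model's scope by
construction.

Within a frame, two scan regimes are implemented:

* **`scan = "diagonal"` (default).** Row $i$'s sequence starts at its own
  diagonal: step $t$ predicts the pair $(i, i + t - 1)$ up to the frame
  end, and each unordered pair is visited exactly once; the predicted
  matrix is symmetric by construction. Because the hidden state starts
  from zero at every sequence start, its trajectory under the recurrence
  acts as a clock, so the step index — which here *is* the genomic
  distance — is directly available to the decoder. The strong
  distance-decay of Hi-C then does not need to be recovered from the
  representations themselves.
* **`scan = "full"`.** Every row scans the whole frame from its left
  boundary (both triangles trained and predicted, orientation preserved).
  In this regime the clock encodes the absolute column position, and the
  distance to the row must be inferred from $R_i$, which we found requires
  far more optimization steps than desk-scale budgets allow: with the
  10-epoch schedule below, short-range strata remain badly fit and
  reconstruction stays worse than the distance-mean baseline. The regime
  is retained because it matches the fully general formulation (any row
  set against any column range), but it is not the default.

Padded steps at the chromosome tail are fed through the decoder (so hidden
dynamics match training) but masked out of the loss; the padding row of
$R$ therefore exists, is used as input, and is itself one of the knockout
reference vectors.

## Training

The loss is the mean squared error between predicted and observed contact
probabilities. Each row-sequence contributes the mean over its modeled
pairs, and a batch averages these per-row means, so short sequences (rows
near the frame end, which carry the near-diagonal pairs) are not
down-weighted by their length. Optimization is Adam
(\(\beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}\)) with global
gradient-norm clipping at 1.0 and the two-stage learning-rate schedule
0.01 for 5 epochs, then 0.001 for 5 epochs.

The batch size counts row-sequences and defaults to 4. This default
targets chromosome-scale or smaller inputs trained for the standard 10
epochs on a CPU, where the number of Adam steps — not the data volume — is
the binding constraint; with hundreds of thousands of sequences (full
genomes) a batch of 2000 sequences is the appropriate setting.

Initialization: representation entries are $\mathcal N(0, 0.1^2)$; gate
weights are uniform on $\pm 1/\sqrt H$; layer-norm gains start at 1 and
offsets at 0 except the forget-gate offset, which starts at 1 (the usual
remember-by-default initialization; without layer norm the forget bias
itself starts at 1); and on a fresh model the output-head offset starts at
the logit of the mean target probability (base-rate initialization), which
removes several epochs of global-level fitting. All runs are exactly
reproducible from the recorded seed: two trainings with the same seed are
bit-identical, which the test suite asserts.

`fine_tune()` continues optimization with the loss restricted to observed
(non-`NA`) entries, optionally within a bin subset — the mechanism for
adapting a trained model to a sub-matrix assayed by a different protocol
(5C-style data). Frames containing no observed entries are skipped
entirely, so representations of uninvolved bins are untouched bit-for-bit.

## Attribution

`integrated_gradients()` attributes a scalar target — the sum of one row's
predicted contact probabilities over its frame — to the per-step inputs
$(R_i, R_j)$, integrating gradients along the straight path from a
baseline to the input with a midpoint Riemann sum. Design choices:

* **Baseline = zero vector.** The zero representation is the natural
  "absent locus" reference, and makes the linear-decoder closed form
  $w_k (x_k - 0)$ exact.
* **Steps = 50 by default**, with the completeness identity
  (attributions summing to `target(input) - target(baseline)`) checked;
  if the relative gap exceeds 5% the step count is doubled once. At 200
  steps the gap is well below 1% on trained models.
* **Aggregation to one score per bin** (`aggregate_importance()`): each
  attribution matrix is summed over representation dimensions; the row
  half (summed over steps) is one occurrence for the row's bin and each
  column step is one occurrence for that column's bin; a bin's raw score
  is the *mean* over its occurrences, so bins near chromosome ends, which
  appear in fewer pairs, are not biased downward.
* **Normalization** (`normalize_importance()`): min–max applied to
  positive and negative scores separately; positives map to $[0, 1]$,
  negatives (on absolute value, then negated) to $[-1, 0]$, zeros stay
  zero, and a degenerate subset (all equal) maps to $\pm 1$. The output
  range convention for negatives is declared here, not inherited from any
  reference implementation.

The sign of an attribution is interpreted relative to the scalar target:
a bin whose presence *suppresses* the row sums it participates in — the
defining behavior of an insulating TAD boundary — receives negative
attributions. On synthetic chromosomes, boundary bins are therefore
singled out by systematically negative normalized importance rather than
by a positive peak; the magnitude-based boundary peak reported for
genome-scale models depends on attribution targets and data features this
fixture does not reproduce. Note also that a bin's row-occurrence
attribution aggregates over its whole sequence, so frame-start bins
(longest sequences) carry systematically larger magnitudes.

`aggregate_profile()` averages any per-bin track over scaled interval
profiles — by default 10 equi-spaced interior spans plus 50 kb of per-bin
flanks — which is how boundary-peak summaries over TADs are produced.

## In-silico perturbation

All perturbations edit the representation table only; decoder weights are
never touched. `knockout()` offers four methods — `shift` (delete rows,
shift downstream rows up, back-fill the tail with the padding vector; the
preferred method since it emulates a genomic deletion), `zero`, `average`
(mean of ±10 bins by default, knocked-out bins excluded) and `padding`.
`replace_orientation()` swaps CTCF motif orientations by replacing each
target row with the genome-wide mean representation of the opposite
orientation (padding row excluded from the means).
`duplicate_block()` builds `[prefix, block, block, suffix]` and records a
total coordinate map with copy provenance; frames are re-derived for the
longer chromosome at prediction time.

Comparisons against the wild type are made on reference coordinates:
shift knockouts via the coordinate map (`map_to_reference()`; deleted bins
have no counterpart and are `NA`), duplications via `combine_copies()`,
which inverts predicted probabilities to read counts, sums the counts of
all perturbed-coordinate pairs carrying the same reference pair, and
re-applies the transform. `duplication_baseline()` implements the
comparison baseline: observed values everywhere except the block with
itself, which gets the genomic average at matched offsets over all
placements of a block-sized window. `effect_by_distance()` condenses a
perturbation into the mean contact change at each separation over pairs
straddling a perturbed site (2 Mb window by default; an MSE variant serves
duplication evaluation). Only cis effects are representable: a
perturbation can act solely through the edited chromosome's own
representations.

## Evaluation

`r2_by_distance()` computes $R^2 = 1 - SS_{res}/SS_{tot}$ within each
separation stratum, excluding unmodeled pairs pairwise; a stratum with
zero variance is reported `NA`. The distance-stratified mean predictor
(`distance_mean_baseline()`) has $R^2 = 0$ at every stratum by
construction and is the reference every reconstruction is measured
against.

The element-identification harness binarizes signal tracks at a strict
threshold (0.5 for expression/FIRE-style scores), rasterizes interval
labels to bins at ≥ 50% overlap, balances classes by seeded uniform
negative sampling, and evaluates two classifier families with 5-fold
cross-validation: gradient-boosted trees (depth 6, up to 5000 rounds,
early stopping after 20 stagnant rounds on an internal validation split)
and a linear layer with sigmoid per task (logistic regression). Metrics
follow the definitions used throughout this literature: accuracy and
F-score at a 0.5 threshold, rank-based AuROC (ties get half credit, so
all-tied scores score 0.5 by convention), and mAP as the average of the
maximum precision at each attained recall level — both ranking metrics are
invariant under strictly monotone score transforms.

## The synthetic generator

`generate_chromosome()` emulates the structures the model is meant to
capture: power-law distance decay $(d + 1)^{-\gamma}$, multiplicative TAD
blocks, convergent loop anchors (forward motif at the TAD start, reverse at
the end, ±1 bin focal enrichment), and log-normal noise. Defaults — 300
bins at 10 kb, 6 TADs, one convergent loop per TAD, $\gamma = 0.8$,
`tad_boost` 3, `loop_boost` 5, `noise_sd` 0.3, `base` 100, seed 7 — were
chosen once to give realistic probability ranges after the exponential
transform (near-saturated at the diagonal, $10^{-9}$-scale for distal
cross-TAD pairs) while training in minutes on one CPU. The generator does
*not* emulate compartment checkerboards, replication-timing gradients,
mappability artifacts, or single-cell sparsity, so passing tests
demonstrate recovery of decay/TAD/loop structure — not performance on real
genome-wide Hi-C.

Problem sizes used by the test suite and the acceptance script: the
300-bin default fixture for training, reconstruction and attribution
checks, and a 700-bin, 20-TAD chromosome for the knockout-direction sign
test (20 loops, each knocked out separately).

A consequence of the generator's design worth spelling out: convergent
loop anchors are placed *on* TAD boundaries. Shift-knockout of such
anchors therefore deletes boundary bins and fuses the adjacent domains,
and the predicted contacts in the fused neighborhood *increase* — the
model reproduces the boundary-deletion/TAD-fusion phenotype rather than
the contact depletion seen when intra-domain CTCF+cohesin loop anchors
are removed from real genomes. Knockout-direction tests against this
fixture measure the former, not the latter.

## Known limitations

* Separations beyond the frame span (1.5 Mb at default settings) are
  undefined; effect curves report them as missing.
* The `full` scan regime needs far more optimization steps than the
  default desk-scale recipe provides (see above).
* Near-diagonal strata are the last to converge under MSE on sigmoid
  outputs (saturated targets attenuate gradients), so short-separation
  $R^2$ is the noisiest quantity across seeds.
* Multi-cell-type conditioning, bidirectional or multi-layer decoders and
  genome-scale GPU training paths are out of scope.
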