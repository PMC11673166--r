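---
title: "Generating patient tables from summary statistics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating patient tables from summary statistics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`statgan` generates patient-level tables conditioned on nothing but a vector
of per-column summary statistics. This vignette explains the model and its
assumptions, the parameters that matter, the numerical decisions baked into
the implementation, and what the package's tests do and do not establish.

## The problem and the modelling idea

Real medical tables are rarely shareable; their summary statistics usually
are. The package treats "statistics to table" as a conditional generation
problem, analogous to text-to-image synthesis: a generator network learns,
from many (statistics vector, table) pairs, to emit an entire table whose
extracted statistics match the conditioning vector. Because no real table is
available at training time either, the training pairs themselves are
manufactured: a constrained random sampler produces tables that realize
perturbed copies of the base statistics vector.

The schema is the contract throughout. Every column declares a kind
(`continuous`, `count`, `binary`), a range, an optional clinical risk
threshold with a direction, and whether it is the binary outcome. The
statistics menu is a pure function of the schema — min, max, mean per column;
risky fraction and odds ratio versus the outcome per thresholded feature;
outcome prevalence — so the flat vector has a deterministic order and width
(44 entries for the default 9-column schema). The menu is configuration, not
a fixed constant: schemas with other column sets get correspondingly wider or
narrower vectors.

## The corpus builder

`perturb_statistics()` multiplies every entry by `1 + u`, `u ~ U(-a, +a)`
with `a = 0.01` by default: the training corpus emulates "statistics that are
close to, but not exactly, the target". After perturbation the vector is
repaired so its invariants hold: fractions and prevalence are clipped to
`[0, 1]`, a binary column's min/max snap back to 0/1, and the mean is tied to
the prevalence for the outcome (a binary mean *is* its prevalence) and
clipped into `[min, max]` elsewhere.

`synthesize_table()` then realizes a perturbed vector. No sampling law is
implied by a statistics vector alone, so the package fixes a deliberately
simple, auditable one:

1. the outcome gets `round(prevalence * n)` cases, clamped so both classes
   keep at least one row;
2. the risky count per feature is `round(fraction * n)` (banker's rounding);
   the split of risky rows between cases and controls is chosen by exhaustive
   integer search over the feasible 2x2 layouts, scored by the distance of
   the (0.5-corrected) log odds ratio from the target;
3. cells are drawn uniformly inside the risky / non-risky sub-ranges, and an
   iterative shift-and-clip moves the column mean to the target while every
   cell stays inside its sub-range — so the risky count is never disturbed.
   Count columns are rounded and fine-tuned by unit steps afterwards; the
   mean tolerance (1% of the schema column range) is assessed after rounding.

The statistics CSV of the corpus is re-extracted from the tables actually
written, so row *i* of the CSV equals `extract_statistics(table_i)` at
serialization precision — the pairing the GAN trains on is exact by
construction, not by trust.

**What the fixture emulates, and what it does not.** The bundled
`make_reference_table()` stands in for a real cohort as evaluation ground
truth. Columns are drawn from class-conditional normals (cases shifted toward
the risky end of each range), clipped and rounded per kind. That yields
plausible marginals, both outcome classes, and positive feature–outcome
associations — enough to exercise every code path, including non-trivial odds
ratios and classifiers that beat chance. It does **not** reproduce the skewed
or zero-inflated marginals, measurement artefacts, or the inter-feature
correlation structure of real clinical data. A green test suite therefore
shows the machinery is correct and self-consistent, not that generated tables
would survive contact with any particular real cohort.

## The table-similarity loss

Cell-wise losses (MSE/MAE) are wrong for tables: permuting patient rows
leaves the data equivalent but changes every cell. The TS loss compares
tables through row sums and column sums only:

- vertical term `mu`: mean absolute difference of paired column sums;
- horizontal term `D = nu * P`, where each real row sum is matched to its
  nearest synthetic row sum (`delta_n = min_i |r_n - s_i|`), `nu` is the mean
  of these minima and `P` the fraction of minima whose value repeats;
- per-sample loss `L = D + mu`; batch loss `sqrt(mean(L))`.

Numerical decisions, all exposed as arguments:

- **Absolute column differences.** Signed differences would allow a negative
  `mu` and hence a negative `L`, breaking the square root of the batch loss.
  The default takes `|R_m - S_m|`; `signed = TRUE` retains the literal signed
  form for inspection.
- **Paired, not cross-product, column differences**, matching the `1/n_cols`
  normalizer of the vertical mean.
- **Repeat counting.** `N` counts minima whose value, rounded to
  `equality_decimals` (default 6), occurs at least twice. Exact float
  equality would make `P` vanish almost surely; the rounding tolerance makes
  the "repeated minima" notion usable. An alternative reading (multiplicity
  of the single most frequent minimum) coincides with the default in the
  identity case; the set-based count was chosen as the more stable statistic.
- **Square root on the batch mean** is the default (`apply_sqrt = FALSE`
  disables it); it is what keeps the loss on a gradient-friendly scale.
- **Gradients.** `P` is a piecewise-constant count: it contributes no
  gradient and is treated as a per-evaluation constant scaling the gradient
  of `nu`; the argmin defining each `delta_n` is held fixed (first index on
  ties). The analytic gradient is verified against central finite differences
  in the test suite, and is exactly zero at `synth == real`.

## The networks and training

Both networks are plain fully connected stacks with LeakyReLU (slope 0.2)
hidden activations and a sigmoid output, implemented in the package with
manual backpropagation and Adam. Dense layers fit the problem: the generator
emits the whole table (766 x 9 by default, flattened) in one pass, and a
convolutional first layer would need very large filters to couple noise with
the statistics vector. Defaults, all configurable:

| parameter | default | rationale |
|---|---|---|
| noise dimension | 128 | standard GAN noise width at this scale |
| generator widths | 128, 256, 512 | expanding stack toward the 6,894-unit output |
| statistics re-injection | after layer 2 | refocuses on the conditioning once table structure forms; after one layer the concatenation would force an oversized first layer |
| discriminator widths | 512, 256, 128 | mirror of the generator |
| discriminator injection | after layer 2 (mid-network) | the exact layer is a free choice; mid-network lets the table embedding form first |
| learning rates | generator 1e-4, discriminator 5e-5 | the 2:1 asymmetry counters mode collapse |
| batch size | 64, drop-last | 10,000 pairs give 156 iterations/epoch, 10,920 by epoch 70 |
| Adam betas | 0.5, 0.999 | common GAN-stabilizing choice |
| epochs | 70 | training always runs to `max_epochs`; the per-iteration history and per-epoch scatter snapshots of the monitored feature pair (columns 5 and 7 by default) support the analyst's own stopping judgement — no automated quality stop is claimed |

Tables are discriminated and compared in normalized `[0, 1]` column units
(min-max by the schema ranges); statistics are normalized likewise, with odds
ratios squashed by `x/(1+x)`. This keeps the loss surface independent of
column units and makes the range invariants of generated tables enforceable
by construction: `generate_table()` denormalizes, clips, rounds count
columns, thresholds the outcome at 0.5 and flips the single most borderline
row if one class is missing. Scores are clamped to `[1e-7, 1 - 1e-7]` before
logs. The discriminator sees the table as a flat vector; a 2-D arrangement
carries no extra meaning for dense layers.

The discriminator is always shown the corpus table paired with the *same*
statistics row that conditioned the generator, so real and fake samples are
judged against identical conditioning.

Determinism: every stochastic step (shuffling, noise, initialization) flows
from the training seed through a per-stage hash, so a fit is bit-reproducible
on the same platform with the same BLAS; `run_pipeline()` extends the same
scheme to one master seed per run.

## Evaluation machinery

**Fidelity.** Welch t-test per feature (pass: two-sided p > 0.05, with
Welch–Satterthwaite degrees of freedom — the unequal-variance denominator is
the natural reading when real and synthetic spreads differ); a chi-square
statistic `sum((S - R)^2 / R)` on the outcome counts with the real counts as
reference cells (this is *not* the proportional-expected goodness-of-fit
test: totals need not match); and the first Wasserstein distance between
empirical CDFs, min-max normalized by the real column's range, pass
threshold 0.1. The 0.1 threshold is a convention of the evaluation scheme —
it is configurable. Degenerate inputs are defined rather than left to chance:
identical constant samples give `t = 0, p = 1`; a zero real count is a
validation error naming the category; a degenerate real range cannot be
normalized and errors.

**Labels.** A metric is Excellent when more than half of its features pass,
Poor when none do, Good otherwise. Exactly 50% passing is unassigned by the
three-level scheme's usual statement; the package assigns the conservative
Good. The total label maps Excellent/Good/Poor to 3/2/1, weights each by
exactly `1/n` (n = number of metrics; 0.33 is a display rounding that
happens to produce identical totals for n = 3 — both are tested), sums, and
rounds half-up. Half-up matters only for n other than 3, where the weighted
sum can land on .5.

**Utility.** TRTR and TSTR share one stratified 80/20 real split (a fixed
protocol default — the split is not part of the published recipe) and one
real test side; TRTS is deliberately omitted since the use case for synthetic
data is training. The four classifier configurations are fixed verbatim;
their mapping onto the available backends is:

- random forest → `ranger` (88 trees, depth 11, Gini, seed 28). `ranger`
  additionally consumes R's global RNG stream, so the fit pins the RNG state
  to make the model a pure function of its inputs;
- cosine 4-NN → implemented in-package (no cosine-metric KNN exists in the
  installed stack); ties in the vote resolve to the nearest neighbour's
  class;
- decision tree → `rpart` at depth 7. The "max features = 2" and random-state
  fields of the spec have no `rpart` analogue: `rpart` searches all features
  deterministically, so the random state is inert; both fields are retained
  in the spec object for the record;
- MLP → the package's own dense-net machinery (the installed `nnet` is
  single-hidden-layer only, the spec needs (32,128,256)): ReLU, logistic
  output, Adam 1e-3, inputs min-max scaled by the training columns, and the
  stated early stop — terminate once the training loss fails to improve by
  more than 1e-4 for 10 consecutive epochs, within a 30-epoch cap.

Precision/recall/F1 are class-weighted, which makes weighted recall equal
accuracy — the pattern visible in published TSTR tables. The utility label is
Excellent only when every per-model, per-metric |TRTR − TSTR| gap is strictly
below 0.4; the Good (< 0.8) and Poor grades extend the published rule and are
flagged as a package convention.

## Problem sizes used in the tests

The test battery runs the full pipeline at reduced scale so the suite
completes in well under a minute per file on one CPU: shape checks generate a
handful of 766 x 9 tables rather than the 10,000-pair default; the round-trip
suite synthesizes 50 perturbed targets at 200 rows; the training-progress
check uses a 3-column, 50-row schema with 200 pairs, batch 20 and 30 epochs
(300 iterations), with learning rates scaled up (2e-3 / 1e-3, keeping the
2:1 ratio) because the run is some 36 times shorter than the full recipe —
at 1e-4 the parameter displacement after 300 Adam steps would be too small to
demonstrate learning either way. These sizes were fixed when the experiments
were designed; the assertions on them are directional (losses finite, TS
component falling, trained beats untrained at statistics recovery) rather
than threshold-tuned.

## Known limitations

- The constrained sampler matches univariate targets and a per-feature odds
  ratio; it makes no attempt at joint structure beyond that — capturing
  inter-feature correlation is exactly the GAN's job, not the sampler's.
- One fit is tied to one schema and statistics menu; a new menu means
  retraining.
- Wider tables make the single-shot generator harder to train (the output
  layer grows with `n_rows * n_cols`).
- Privacy is not evaluated: the method never sees real rows by design, but
  the package makes no differential-privacy or membership-inference claims.
- Training at the full default scale (10,000 pairs of 766 x 9 tables, 70
  epochs) is a multi-hour CPU job; the package keeps it configurable rather
  than assuming it.
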