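---
title: "ventwarn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ventwarn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the pipeline works, the assumptions behind it, and
the design decisions taken where more than one reasonable choice existed. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## The prediction problem

Every encounter is a PICU stay described by three long-format event tables
(encounters, timestamped clinical observations, timestamped medication
events). All timestamps are integer **minutes since admission** — the
package never touches calendar time, which avoids timezone and DST
ambiguity. The outcome is invasive mechanical ventilation (MV); MV cases
carry an onset time. The 30 minutes before onset are the **preparation
window**: intubation drugs (sedatives, paralytics) given there trivially
predict intubation, so every grid row in `[onset - 30 min, onset)` is
excluded from training and evaluation. The modeling target is a
**risk score** `r(t) = P(MV | data up to t)` on a 5-minute grid from
admission to the preparation boundary (MV cases) or discharge (no-MV
cases).

Alerting is threshold-based: the **early prediction point (EPP)** is the
first grid time with `r(t) >= tau`, an encounter with no crossing is a
negative prediction, and the **early warning time (EWT)** of a true
positive is `onset - EPP` in hours.

## Feature engineering

* **LOCF grid.** Observations arrive irregularly; each variable is
  resampled to 5-minute steps by carrying the last observation forward.
  Values before a variable's first observation stay missing. Duplicate
  records at one timestamp keep the last by record order.
* **Missingness indicators.** Each LOCF series is accompanied by a binary
  `miss_*` column. Charting intensity is informative (labs are ordered when
  patients look sick); the tree learner can exploit this and it is harmless
  otherwise.
* **Physiologic z-scores.** Pediatric vital signs are age-dependent, so raw
  values are standardized as `z = (x - mu)/sigma` against an age-banded
  normal-range table (bands `<1, 1-5, 5-12, 12-21` years). The bundled
  table (`default_normal_ranges()`) holds plausible synthetic reference
  values; a site deploying this on real data must substitute its own
  (e.g. handbook-derived) table. Gender-specific rows are supported but the
  default table uses `gender = "any"` throughout. Missing height maps to
  `z = 0` (an explicit convention; weight is required by the cohort
  filter, height is not).
* **Windows are half-open `(t - 6 h, t]`**, both for input/output rates and
  medication indicators, so an event is counted in exactly one boundary
  case and shifting all events by one grid step shifts indicator activation
  by exactly one grid step. Rates truncate the denominator at admission
  (volume so far divided by elapsed hours).
* **Medication indicators.** A medication earns an indicator column if, on
  the training split, it was given to at least 10% of MV patients or its
  one-dose-per-patient prevalence differs by more than 5 percentage points
  between outcome groups. Prevalence counts "given" events, with MV
  histories truncated at the preparation boundary.
* **Feature dictionary.** The dictionary (variable names, types, what gets
  z-scored, category sets) is data, not code: the default synthetic
  dictionary has 14 variables plus demographics; an institutional
  deployment would swap in its full assessment/lab dictionary.

## Medication-history features

The second medication representation treats the 6-hour medication history
as a sentence: events sorted by `(time, sequence_no)` and emitted as
`name action` token pairs, multi-word actions underscored, empty windows
mapped to the sentinel `<no_meds>`.

* **Embeddings.** GloVe vectors (dimension 10, context window 25 tokens)
  are fit on symmetric, 1/distance-weighted within-sentence co-occurrence
  counts of the training corpus by full-batch AdaGrad on the weighted
  least-squares GloVe objective (`f(x) = min((x/x_max)^0.75, 1)`,
  `x_max = 10`, 50 iterations, learning rate 0.05). The final vector is
  `w + w~`. The `<pad>` token and any token never observed in a
  co-occurrence get the zero vector, so padding cannot influence features.
* **Extractor.** A single 1-D convolutional layer (five filters per span
  for token spans 4, 5, 6; width equal to the embedding dimension),
  max-pooling over token positions with a leaky rectifier on the pooled
  maximum, a frozen per-feature standardization layer, dropout 0.5, and a
  zero-initialized softmax binary output, trained with momentum SGD
  (momentum 0.9, 40 epochs, batch 64, learning rate 3e-3, class-weighted
  cross-entropy, conv-gradient norm clipping) on one sentence per training
  encounter: the full history up to the preparation time for MV cases, the
  full stay for controls. The standardized max-pooled 15-vector is the
  `medhist1..15` feature block. Training is seeded and deterministic;
  extraction disables dropout. The network is implemented in package R code
  (vectorized convolution with analytic, finite-difference-verified
  backpropagation) — small enough that a deep-learning framework would add
  nothing but a dependency. Each of the non-obvious pieces earns its place
  on corpora of a few hundred to a few thousand sentences: a hard ReLU
  under max-pooling lets filters die irrecoverably, a randomly-initialized
  head lets early noise gradients destroy the conv filters (especially
  under scale-free optimizers like Adam, which is why momentum SGD is
  used), and without standardization the head would need unreachable
  weight magnitudes to exploit the tiny but consistent scale of pooled
  conv features.
* **Resolved inconsistency.** A printed filter shape of "4x20, 5x20, 6x20"
  is dimensionally incompatible with an embedding dimension of 10; for 1-D
  convolution over the token axis the filter width must equal the embedding
  dimension, so spans 4/5/6 at width 10 are used (width 20 is available by
  configuring `embedding dim = 20`). The exact count of `medhist` features
  is likewise not printed; 5 filters x 3 spans = 15 follows from the
  architecture.
* **An asymmetry worth noting:** the training corpus uses full histories,
  while feature extraction at grid time `t` uses the previous 6-hour
  window. Both behaviors are deliberate and mirror the described
  procedure.
* At grid time, features are recomputed only at sentence change points
  (an event entering or leaving the 6-hour window) and carried forward;
  identical sentences are deduplicated before the forward pass.

## Risk models and scoring

* **Instances.** Positives are all grid rows in the 12 hours before each
  training MV case's preparation time (144 rows per case); negatives are an
  equal number of rows drawn uniformly without replacement across all
  no-MV training encounters (row-level, no per-encounter quota). Balanced
  sampling counteracts the ~8.6% prevalence.
* **Learners.** Gradient-boosted trees (the default; depth 6, min child
  weight 1, subsample 0.8, column subsample 0.8, eta 0.1, 150 rounds,
  missing values consumed natively) and L1-regularized logistic regression
  (training-median imputation, penalty chosen by `cv.glmnet`). Defaults are
  conventional and config-exposed; optional stratified CV confirms the
  round count with early stopping. The deployed scorer is always refit on
  the full instance set.
* **Out-of-fold training scores.** Training-encounter score series are
  produced by 10 fold models, each fit without the fold's encounters, so a
  training course is always scored by a model that never saw it; the
  held-out test set is scored by the final refit model. This matters: with
  refit-model scores the training maxima are overfit, the max-F1 threshold
  saturates near 1 and every post-EPP trajectory of a training false
  positive disappears. Cross-validated course scoring restores a realistic
  threshold and an honest false-positive population for risk grouping.
* **Threshold.** `tau` maximizes F1 of `score >= tau` over the per-encounter
  maximum training scores, ties broken toward the higher threshold (higher
  specificity). Encounter-level AUROC/AUPRC use the per-encounter maximum
  score as the ranking statistic — consistent with the first-crossing
  classifier, which alerts exactly when the running maximum crosses `tau`.
* **Feature importance** reports the tree ensemble's split-gain and the
  mean |SHAP| over training instances (tree-path SHAP; for the linear
  comparator, exact linear attributions). Raw probabilities are used as
  risk scores; no recalibration is applied.

## Alerting variants

* **Dual threshold (B1).** A crossing of `tau` arms a clock; the encounter
  is positive only if `tau2 >= tau` is crossed within 6 hours, and the EPP
  is that second crossing (so dual-threshold alerts are a delayed-or-dropped
  subset of single-threshold alerts). If the window expires the scheme
  re-arms at the next crossing. `tau2` maximizes training precision subject
  to retaining at least 90% of the single-threshold sensitivity. Only the
  6-hour inter-threshold period is externally specified; the selection rule
  is this package's documented choice.
* **Waiting period (B2).** A crossing counts only if the score stays at or
  above `tau` for a sustained hour of consecutive grid points; the EPP is
  the first point of the run. Again the scheme is named but not defined
  externally; this is the most common reading and is config-exposed.

## Risk grouping

Positive predictions are stratified by spectral clustering of their
risk-score trajectories over `[EPP, EPP + 6 h]` — 73 points on the same
5-minute grid (reusing the modeling grid is the only self-consistent
sampling). Trajectories cut short by the preparation boundary or discharge
are excluded from clustering but still receive a transferred label via
their last-value-padded prefix, so every positive prediction is grouped.

* **Graph.** Symmetric KNN graph (edge if either point is in the other's
  K-neighborhood, Euclidean distance, default `K = 200` capped at `n - 1`),
  with locally-scaled Gaussian edge weights
  `w_ij = exp(-d_ij^2 / (sigma_i sigma_j))`, `sigma_i` the distance to the
  7th neighbor (the self-tuning kernel from the standard normalized
  spectral clustering literature). The plain 0/1 graph is available
  (`weighted = FALSE`) but is fragile exactly when `K` exceeds the natural
  cluster size — e.g. in 80% bootstrap subsamples of a 600-trajectory,
  3-bundle fixture, where binary adjacency degrades reclustering while the
  weighted graph keeps the bootstrap Jaccard stability near 1.
* **Model selection.** Eigenvalues of the symmetric normalized Laplacian,
  ascending; the cluster count maximizes the eigengap over `k = 2..8`.
  k-means (10 restarts) runs on the row-normalized embedding; if
  Hartigan-Wong aborts on duplicate rows, a kmeans++-seeded Lloyd fallback
  is used, and fewer distinct rows than centers degrade gracefully to exact
  row matching. Identical trajectories return a single cluster with a
  warning.
* **Stability.** 50 subsamples of 80% without replacement are reclustered
  (same `K`, cluster count fixed at the reference `k`); each reference
  cluster records the maximum Jaccard index against subsample clusters,
  restricted to shared points; reference clusters absent from a draw are
  excluded from that draw's mean.
* **Ordering and transfer.** Groups are ordered by their average risk
  score, ascending (low < medium < high for `k = 3`, generic ordered names
  otherwise). The ordering statistic is the mean over the full post-EPP
  window rather than the value at the EPP alone: at the EPP every
  trajectory sits just above the alert threshold by construction of the
  first crossing, so when the max-F1 threshold lands near the top of the
  score scale the at-EPP means of all clusters coincide and their order is
  noise. The two statistics give the same order whenever the at-EPP means
  genuinely separate (`order_risk_groups(stat = "epp")` selects the at-EPP
  rule). Test labels come from majority vote among the 15 nearest training
  trajectories, ties resolved toward the higher-risk group.
* **Reporting.** The Table-style report (positive predictions, PPV, EWT
  median [IQR]) is produced for the held-out test set and, because per-group
  rates over a few dozen test alerts are noisy at the default cohort size,
  also over all positive predictions (training positives with their
  reference labels, test positives with transferred labels).

## The synthetic cohort generator

The generator's job is to reproduce the statistical structure the pipeline
assumes — not pharmacology or physiology. It emulates:

* **Marginals:** MV prevalence 1176/13651 (~8.6%; an abstract elsewhere
  rounds this to 8.06%, the results section and the counts give 8.61% —
  the counts win); median length of stay 19.4 days (MV) vs 3.1 days
  (no-MV), lognormal; ages lognormal with medians 1.2 vs 4.8 years and dispersions
  solved from the printed interquartile ranges;
  non-invasive ventilation prevalence 28.4% vs 10.7%. (A length-of-stay
  table elsewhere is captioned in hours; days are used — an MV-onset
  filter at 12 h is incompatible with a 19.4-hour median stay.)
* **Event streams:** inhomogeneous Poisson charting (baseline ~1/h for
  vitals, sparser for labs, boosted 1.5x in the first 24 h and modestly
  in the pre-onset window), vitals drawn about the same age-banded normal
  ranges used for z-scoring, per-encounter random intercepts.
* **Outcome signal:** MV cases get (a) physiologic drift (rising
  respiratory/heart rate and FiO2, falling SpO2, rising lactate) ramping
  linearly over the 12 h before onset, plus a small persistent component
  (12% of the terminal magnitude) over the whole stay — severe cases look
  somewhat abnormal throughout, which is what makes post-EPP trajectories
  severity-structured; (b) escalating sequences of 6 predictive
  medications (actions biased to "rate changed") in the pre-onset window;
  (c) intubation sedatives inside the preparation window — a deliberate
  leak canary: any pipeline that sees them would show it.
* **Heterogeneity:** three severity archetypes (multipliers 0.35 / 0.875 /
  1.4) and per-case drift-channel expression (each numeric channel
  expressed with probability 0.7), so some MV cases are genuinely hard to
  detect; and **deteriorate-and-recover controls** (18% of no-MV stays): a
  transient triangular episode (half-width 2-5 h, severity 0.5-1.2) with
  the same drift signature and medication escalation, which resolves.
  These are the false-positive population that fills the low-risk group
  with decaying trajectories.
* **One signal knob.** Every outcome-linked contrast — including the
  demographic ones — interpolates between "absent" and "full study
  magnitude" via `signal_strength / signal_reference`. At
  `signal_strength = 0` the MV label is independent of every generated
  feature, so a leak-free pipeline must score at chance; held-out AUROC is
  also non-decreasing in `signal_strength` by construction. Magnitudes were
  chosen so that the default pipeline lands near the operating regime the
  method is known for (AUROC high-0.8s/low-0.9s, PPV near 0.5) rather than
  at ceiling; they were frozen before the acceptance checks and are
  configurable.
* **Filter fodder:** small fractions of encounters violate each inclusion
  rule (missing demographics, out-of-range ages, tracheostomy, cyanotic
  low-SpO2, data errors, early/short MV, post-procedure onset) so the
  flowchart always has work.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: real assessment/lab dictionaries (188+ features),
between-variable physiologic correlation beyond the shared severity factor,
medication dose values, care-pattern confounding (treatment given *because*
deterioration was recognized), coding drift over an 8-year extraction
window, or transcription noise in human-entered fields. Passing the suite
shows the pipeline recovers structure it is pointed at and nothing else; it
does not certify clinical performance.

## Problem sizes and numerical details

* The full-pipeline checks run one cohort of 2,000 encounters (about
  1,880 retained; roughly 4 million grid rows scored in streamed chunks of
  ~400k rows) for the planted-signal arm and one for the zero-signal arm;
  marginal-fidelity checks use 10,000 encounters with thinned event
  streams (outcome draws are unaffected by charting rates).
* Quantiles everywhere (EWT IQRs included) are type-7 (linear
  interpolation). Confusion-derived rates with empty denominators are NA.
  F1 at `sens = ppv = 0` is defined as 0.
* Eigengaps are computed on a symmetrized Laplacian (`(L + t(L))/2`) to
  guard against floating-point asymmetry; degrees are floored at 1e-12.
* All stage seeds derive deterministically from one global seed (distinct
  multipliers per stage, kept below 2^31); two runs of the same config are
  byte-identical.
* The cyanotic SpO2 rule is evaluated on the LOCF grid as the grid-time
  fraction below threshold (grid points before the first SpO2 observation
  do not count as low). The procedure-exclusion rule fires when MV onset is
  0-90 minutes *after* a documented procedure (the other direction is
  clinically implausible as an elective-intubation marker and is not
  implemented).
* Stratification bins for the train/test split: `<1, 1-4, 5-11, 12-21`
  years, crossed with outcome, gender, and NIV status; strata of size one
  go to training with a warning.

## Known limitations

* The GloVe and CNN stages are CPU-bound R; they are sized for cohorts of
  thousands, not millions, of encounters.
* The normal-range table and feature dictionary are synthetic stand-ins;
  results on real data depend on replacing both.
* The eigengap criterion on diffuse real-world trajectories can select
  cluster counts other than 3; reports use ordered generic group names
  whenever `k != 3`.
* PEWS comparators consume recorded PEWS values; the rubric itself is not
  recomputed from vitals.
* No calibration, no net-benefit analysis, and no survival modeling of EWT
  are included, by scope.
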