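---
title: "Methods: from raw screening plates to stable pharmacogenomic biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw screening plates to stable pharmacogenomic biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmscreen)
```

# Scope and model

`pharmscreen` implements the computational chain of a large-panel
cell-line viability screen: raw 384-well fluorescence plates are
normalized and quality-controlled, each cell line's dose-response curve
is reduced to IC50 / AUC / Emax, a multi-omic design matrix is
assembled, and repeated elastic-net regression scores each genomic
feature as a sensitivity or resistance biomarker. Connectivity and
term-enrichment statistics then ask whether a biomarker list is
biologically coherent. Because raw data of this kind are rarely
deposited, the package ships a first-class synthetic-data generator with
planted ground truth; every downstream stage is validated against what
was planted.

# The synthetic world

The generator emulates the structure of a pan-cancer screen:

* **Cohort** — default 624 cell lines over a 22-tissue panel
  (`default_tissues()`), tissue membership multinomial. Equal default
  proportions: the real panel's per-tissue counts are not published, and
  an uninformative split keeps every tissue estimable.
* **Dose series** — 7 concentrations by successive 2-fold dilution from
  10.64 µM: 10.64, 5.32, 2.66, 1.33, 0.665, 0.3325, 0.16625 µM. The
  printed endpoints of such screens (0.16–10.64 µM) are not an exact
  2-fold pair; halving from the top dose reproduces both at display
  precision. The number of doses is configurable.
* **Genomics** — expression and copy-number features are standard
  normal; mutations are Bernoulli with default rate 0.05 per gene, the
  sparsity typical of algorithmically filtered exome calls. A latent
  log10(IC50 µM) score per line is
  `baseline + Σ beta_j · z(feature_j) + N(0, residual_sd)` with planted
  effects declared via `planted_effect()` (beta in log10-IC50 units per
  feature SD; negative = sensitivity). Defaults: baseline log10(1.33)
  (the geometric centre of the dose range), residual sd 0.3.
* **Response dichotomy** — each line is a responder with probability
  `responder_fraction` (default 0.3; the mostly dichotomous
  responder/non-responder pattern is qualitative in the source material,
  so the prevalence is a package choice). Responders follow a true 4PL
  curve with IC50 `10^latent` (or drawn log-normal, default sd 0.5 on
  the log10 scale, when no latent scores are passed); non-responders are
  flat at viability 1 at every dose.
* **Plates** — raw signal is
  `blank + viability · (control − blank) + N(0, noise_sd · range)`,
  clamped at 0. Defaults: control level 50 000, blank 2 500 (20-fold
  signal over noise, comfortably above the 5-fold QC bound), noise_sd
  0.05, 16 control and 16 blank wells per 384-well plate, one treated
  well per (line, dose). No spatial plate artifacts, evaporation
  gradients or outlier wells are modelled, so a green parameter-recovery
  test establishes correctness of the estimators under well-behaved
  noise, not robustness to real-plate pathology.

# Plate QC

Viability is blank-subtracted and control-anchored:
`(raw − mean(blank)) / (mean(control) − mean(blank))`. The formula is a
package choice (standard for resazurin-type readouts); it maps the
control mean to exactly 1 and preserves negative values rather than
clamping them. Three filters follow, each a *strict* inequality
matching the usual wording of screening QC ("below 20%", "over
5-fold"):

1. control-well CV < 0.20 (sample SD over mean — small control counts
   argue for the n−1 estimator);
2. signal over noise = mean(control)/mean(blank) > 5;
3. directionality: mean viability at the two lowest doses over the mean
   at the two highest doses must be ≥ 1.2, otherwise the curve is
   rejected as responding in the wrong direction (or not at all).

A consequence worth stating: a genuinely flat (fully resistant) curve
has a ratio near 1 and fails filter 3, so flat lines never reach IC50
fitting. They are retained in all outputs with
`qc_status = "fail_directionality"` so rejection counts are auditable,
and resistant biology can still enter the response vector through
censored IC50s from curves that pass. With a noise-free generator every
plate passes filters 1–2 by construction; the test suite asserts this.

# Dose-response reduction

The 4PL model `v(d) = bottom + (top − bottom)/(1 + (d/e)^h)` is fitted
by bounded least squares (`stats::optim`, L-BFGS-B) with
`0 ≤ bottom ≤ top ≤ 1.2` and `h ∈ [0.1, 10]`. Three starts (`h` = 0.5,
1, 2; midpoint at the geometric median dose) guard against local
minima; ties resolve to the lowest residual sum of squares, then the
lowest Hill slope. The top ≤ 1.2 constraint is enforced by a quadratic
penalty on `bottom + span`, which is exact at the optimum for feasible
data.

* **IC50** is *absolute*: the dose where the fitted curve crosses
  viability 0.5, found by root-bracketing on
  `[d_min/10, 10·d_max]`. Curves that never reach 0.5 are censored at
  `10·d_max` (flag set); curves already below 0.5 at the lowest searched
  dose are censored at `d_min/10`. The absolute definition behaves
  sensibly for partial responders on a control-normalized scale.
* **AUC** is the trapezoidal mean of the *observed* viabilities over
  log2 dose, normalized by the log-dose span: a flat no-effect curve
  scores exactly 1, dose-unit relabelling cancels, and the metric
  survives fit failures.
* **Emax** is the minimum of the replicate-mean viabilities at the two
  highest doses — by definition a raw-point statistic, and the test
  suite checks it against a brute-force computation on every curve.

Parameter recovery on the synthetic surface: with zero noise the
pipeline returns each in-range responder IC50 within 1% relative error;
at 2% signal noise the median |log10(fitted/true)| over ~200 responders
stays below 0.05.

# Design matrix

Features are typed by prefix — `TIS_` (tissue one-hot, rows sum to 1),
`CN_`, `EXP_`, `MUT_` — and the response is `y = log10(IC50 µM)`. Two
choices deserve justification:

* **CN cap.** The copy-number block is truncated to the `cn_cap`
  (default 1700) genes with the largest absolute Pearson correlation
  between their copy number and their own expression, a concrete proxy
  for "copy-number alterations translated into expression"; ties break
  lexicographically, genes without an expression counterpart rank last.
* **Censoring.** Censored IC50s stay in `y` at their censoring bound
  with an exported mask (`exclude_censored` flips this). Dropping every
  resistant line would delete precisely the contrast a resistance
  biomarker needs. Whether the response should be IC50, log IC50 or AUC
  is not decidable from the source material; log10(IC50) is the default
  because the latent generator is linear on that scale.

Features are deliberately *not* standardized at assembly;
standardization happens inside each training split of the stability
selection so that no holdout information leaks into the scaling.

# Elastic-net stability selection

Each of `n_runs = 100` runs leaves out a uniformly sampled
`⌈0.10·n⌉` cell lines, standardizes columns on the training split
(zero-variance columns get coefficient 0), and fits an elastic net
(`glmnet`, mixing parameter 0.5) with the penalty chosen by internal
5-fold CV on the training split — minimum-CV-error lambda, no
one-standard-error rule, a determinate and simple choice. Holdouts are
not stratified by tissue. Per feature:

* **freq** — fraction of runs with a nonzero coefficient (by
  construction a multiple of 1/n_runs; the suite cross-checks it against
  the stored per-run coefficient matrix);
* **weight** — mean coefficient over the runs where the feature was
  selected (per-SD scale). Averaging over *all* runs instead is a
  one-flag change (`weight_all_runs`), since the reported semantics of
  a nonzero-run mean vs an all-run mean are not recoverable from
  screening literature conventions alone;
* **effect** — weight / sqrt(number of features of the same type), a
  declared approximation to "normalized for the number of features of
  each type"; the exact normalization is likewise config-exposed.

Reporting partitions features with freq strictly above 0.7 by weight
sign: negative = sensitivity, positive = resistance, ranked by
|effect|. Under a noise-only response the procedure is well behaved: in
repeated scaled-down experiments (3 × 30 runs in the suite; the full
1000-repetition property is too slow for a routine test run) no null
feature crosses the 0.7 threshold, while a single planted mutation at
β = −2 among 100 nulls is recovered at freq 1 with the correct sign.

# Connectivity and enrichment

`connectivity_test()` counts interaction edges with both endpoints in a
gene set and compares against uniformly resampled same-size node sets —
a deliberate match to "more connections than expected by chance"; a
degree-preserving null is out of scope, and p-values from databases
with degree-aware nulls will differ numerically on real data. The
add-one estimator `(1 + #{null ≥ obs})/(1 + n_perm)` avoids p = 0.
Edge lists are filtered at a confidence cutoff (default 0.4, a common
medium-confidence setting) at load time, deduplicated, and stripped of
self-loops. `term_enrichment()` is a plain hypergeometric upper tail
over a user-supplied universe with Benjamini–Hochberg adjustment across
the tested terms; memberships are restricted to the universe first, and
no ontology-graph propagation is performed.

# Numerical notes and limitations

* All generators and the stability selection are deterministic given
  their seed; byte-identical reruns are part of the test contract.
* The 4PL fitter can in principle report `converged = FALSE` (all
  starts failing); AUC and Emax are still emitted from raw points and
  the IC50 is censored.
* Synthetic per-SD effects on sparse binary features are large in raw
  units (β/SD(feature)); a planted mutation at β = −2 pushes carriers
  far below the dose range, which is exactly the "strongly responsive"
  extreme of a dichotomous screen, but means such lines are often
  directionality-rejected or low-censored in the full plate pipeline.
  Biomarker-recovery benchmarks therefore regress the latent
  log10(IC50) directly, as their definition prescribes; end-to-end
  demonstrations use milder expression effects.
* No modelling of probe-level expression processing, germline
  filtering, plate-position effects, or interaction-database
  idiosyncrasies; those are upstream or out of scope by design.
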