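---
title: "Methods: noise exposure, questionnaire scoring and the Bayesian network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noise exposure, questionnaire scoring and the Bayesian network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisecare)
```

`noisecare` models how hospital noise exposure, dispositional noise
sensitivity and perceived annoyance relate to the quality of patient care
delivered by nurses, using a discrete Bayesian network over seven ternary
variables. This vignette documents the methods, the tunable parameters,
the numerical choices, and — because the original cohort is not publicly
deposited — what the synthetic-data generator does and does not emulate.

## Noise exposure (ISO 9612 style)

Every measurement point contributes repeated one-minute equivalent
continuous sound pressure levels (Leq,1min). Point levels are combined by
the energetic (logarithmic) mean

$$L = 10\log_{10}\Big(\tfrac1n\sum_i 10^{L_i/10}\Big),$$

which is bounded by the minimum and maximum repeat and never falls below
the arithmetic mean. A nurse's workstation contributions $(L_i, t_i)$
yield $L_{Aeq,T_e}$ with $T_e=\sum_i t_i$, and the daily personal noise
exposure level $L_{EP,d} = L_{Aeq,T_e} + 10\log_{10}(T_e/T_0)$ with the
ISO reference day $T_0 = 8$ h (the study does not state shift length, so
$T_e$ always comes from the supplied durations). All decibel arithmetic
happens in the power domain; nothing is rounded before presentation.

Exposure categories: $L_{EP,d} < 50$ dBA low, $[50, 60]$ moderate,
$> 60$ high. The boundaries are closed on the moderate band because the
verbal rule "less than 50 … 50 to 60 … higher than 60" places 50 and 60
in the middle band.

## Questionnaire scoring

* **Weinstein noise sensitivity**: 21 six-point items coded 0–5, total
  0–105. The 0–5 coding is forced by the printed 0–105 range. Which items
  are reverse-keyed is instrument-dependent and not stated for the study
  translation, so `reverse_key` is configurable and defaults to none
  (a reversed item contributes $5 - \text{raw}$).
* **Annoyance**: a single 0–100 visual-analogue value; no item structure.
* **Quality patient care scale**: 65 four-point items (1–4), three
  subscales (psychosocial 28, communicational 13, physical 24 items).
  The instrument's item order is not printed, so the subscale map is
  configurable with a positional default (items 1–28, 29–41, 42–65); only
  the subscale sizes are fixed. Categories use the published fixed
  cut-offs. The study's wording alternates between "partly undesirable"
  and "partly desirable" for the middle band; the package uses the single
  label `partly_desirable` everywhere.

Sensitivity and annoyance are categorised at the sample's 25th/75th
percentiles, computed with linear interpolation between order statistics
(`quantile()` type 7). Scores strictly below the 25th percentile are low
and strictly above the 75th high; ties at a percentile fall inward to
moderate, the conservative reading of "less than / more than".

`cronbach_alpha()` implements
$\alpha = \frac{k}{k-1}\big(1 - \sum_j s_j^2 / s_T^2\big)$ with sample
variances. `impute_items()` replaces missing item responses by their
conditional means under a multivariate-normal working model fitted by EM
(pattern-grouped E-step; ridge-regularised covariance update, default
ridge $10^{-3}$, needed because 65 items on ~200 records leave the
covariance near-singular), then clips to the legal response range and
rounds. The normal model is an imputation device for bounded Likert
items, not a generative claim; with correlated items it is strictly
better than column-mean imputation, which the tests verify. Records
missing more than 20% of their items (configurable) are excluded from
the fit and flagged rather than imputed. Categorical missingness at the
network level is *not* imputed this way — it is handled natively by the
EM parameter learner.

## The network and its parameter learner

The expert-drawn structure (`build_study_network()`) has 15 arcs:
exposure → sensitivity; exposure and sensitivity → annoyance; all three
noise variables → each care aspect; the three aspects → overall quality.
The published conditional probability table for quality conditions
directly on exposure, sensitivity and annoyance — a different
parameterisation than the aspect-mediated structure — and the two views
are not reconciled in the published account. The package therefore supports both:
the 7-node structure above, and a packaged 4-node fixture
(`table3_network.json`) whose quality CPT is the published table with the
three parents as roots carrying the published category frequencies as
priors. One printed row of that table sums to 1.001 (display rounding)
and is renormalised in the fixture so that every CPT row is a probability
vector to $10^{-9}$.

Inference (`infer_posterior()`) is exact variable elimination with a
greedy smallest-intermediate-factor ordering; on every enumerable network
it must agree with brute-force summation of the factorised joint to
$10^{-9}$, and the test suite checks this on 200 random ternary networks.
Evidence whose probability is zero under the current parameters raises an
error ("impossible evidence") rather than returning a silent zero vector.

`em_learn()` fits CPTs from records with missing cells: the E-step
computes each record's exact posterior over its missing variables by
enumerating completions (records are grouped by observation pattern, so
complete data costs one pass), and the M-step normalises expected counts
per parent configuration. Parent configurations with zero expected count
receive the uniform row — the behaviour visible as 1/3-1/3-1/3 rows in
the published CPT. No smoothing is applied by default (the published
table contains exact 0.000 and 1.000 entries); Laplace smoothing is
available via `smooth`. Initialisation is uniform rows plus a seeded
Dirichlet jitter (concentration 50) to break symmetry; a single start by
default. The observed-data log-likelihood must be non-decreasing — a
decrease beyond $10^{-8}$ relative tolerance is raised as an error, since
it can only indicate an implementation bug — and iteration stops when the
improvement falls below `tol` ($10^{-6}$) or at `max_iter` (100). On
complete data the procedure converges immediately to the conditional
relative frequencies. MAP prediction breaks exact posterior ties by the
declared state order (low/moderate/high and
undesirable/partly_desirable/desirable).

## Delta-p sensitivity and influence values

`delta_p()` fixes the evidence nodes at their states with probability
100% and reports, per target node and state, prior, posterior and their
difference in percentage points. Joint evidence (e.g. exposure and
sensitivity simultaneously high) is expressed as multi-node evidence.
Deltas within a node sum to zero by construction. Machine output keeps
full precision; the print method rounds to whole points with an explicit
sign, the convention used for reporting such scenario analyses.
"Absolute percentage-point change of the posterior" is the definition
adopted here; a relative-change reading of the published percentages
cannot be excluded but is not the standard delta-p semantics.

The influence value of an arc parent → child summarises how much the
child's conditional distribution moves across the parent's states. The
source names the quantity (it is the "strength of influence" popularised
by graphical-model GUIs) but not its formula, so the package documents
and defaults to: the mean, over all co-parent configurations and all
unordered pairs of the parent's states, of the Euclidean distance between
the two child rows. The value is 0 exactly when the parent never changes
the child's distribution, and $\sqrt2$ for a maximal flip between two
degenerate rows. Hellinger distance (bounded by 1) is selectable via
`metric`; rankings are stable under the choice in all cases we examined,
but single values are not comparable across metrics.

## Cross-validated classification

`cross_validate()` performs k-fold (default 10) cross-validation of MAP
classification of a target node (quality of care in the study design):
per fold, CPTs are learned on the other folds and each held-out record is
predicted from **all** of its other observed variables as evidence — the
maximal-information default, since the study does not state its
prediction-time evidence set. Folds are a seeded shuffle into near-equal
parts, unstratified by default (matching "randomly divided"); a
stratified option exists because rare classes (19/209 in the study's
undesirable band) make empty-class folds plausible. A training split
lacking a target state triggers a warning and a Laplace pseudo-count of 1
on the target's expected counts; a held-out record whose evidence has
zero probability under the learned parameters falls back to the target's
prior (counted and reported). Sensitivity and specificity are macro
one-vs-rest averages — the published scalar values do not state their
3-class aggregation, so the package documents its own. ROC/AUC is
one-vs-rest per class from the held-out posteriors, with the mid-rank tie
convention (equivalent to the trapezoidal area), plus the unweighted
macro mean; because the published single ROC curve does not state its
class, the report always prints per-class and macro AUC.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
the original data; its defaults are the package's documented study
conditions, not the study's own (unprinted) parameters.

* **Ground-truth network.** Root priors equal the published category
  relative frequencies; every child row is the child's target marginal
  exponentially tilted along its state order by a signed, weighted mean
  of the parent configuration's positions, then rescaled (an iterative
  proportional-fitting step against the exact parent joint) so that the
  implied marginal of every node matches its target exactly. Tilt
  strengths and per-parent weights are fixed constants chosen once so the
  ground truth's influence ranking resembles the published one (exposure
  → annoyance strongest at ≈ 0.69, exposure → sensitivity weak at ≈ 0.28,
  aspects → quality ≈ 0.44–0.45, annoyance the dominant parent of the
  aspects). The published-CPT alternative (`quality_cpt = "table3"`)
  swaps in the 4-node fixture.
* **Cohort sampling** is ancestral (each node after its parents), fully
  determined by an explicit integer seed; no function in the package
  touches global random state without restoring it.
* **Item expansion.** For the fixed-cut-off quality scales, a total is
  drawn uniformly in the intersection of the overall band with the range
  implied by the three subscale bands, split across subscales by
  constrained uniform allocation and across items by sampling without
  replacement from per-item capacity slots (so item caps are respected
  exactly). Arithmetically infeasible subscale/total combinations — e.g.
  all three aspects desirable forces a total of at least 198, which
  exceeds the partly-desirable band — keep the subscales and relabel the
  total with a warning. For the percentile-based scales the published
  25/50/25 arithmetic fixes *who* must lie below the sample quartile, so
  exact reproduction of sampled categories whose proportions deviate from
  25/50/25 is impossible by definition; the generator draws scores from
  category-ordered, non-overlapping bands (centred near the published
  per-category means) and then sets the category columns to the realised
  percentile categories, relabelling boundary records (the count is
  returned as an attribute). After this harmonisation the round trip
  expand → re-score is the identity on every category column, which the
  tests assert at cohort size 500.
* **Noise environment.** Six departments with base levels between 44.5
  and 64 dBA; points spaced 5 m on a synthetic floor plan with
  department-level spread 1.2 dB and within-point repeat spread 0.8 dB
  (10 repeats per point, 1510 points at study scale). Each nurse gets a
  7 h main and 1 h secondary workstation drawn from points whose mapped
  level lies in the dB band of the nurse's exposure category, with a
  0.5 dB safety margin off the 50/60 boundaries; since the energetic mean
  of in-band levels stays in band and $T_e = T_0$, recomputing LEP,d from
  the grid reproduces every assigned category exactly.
* **Missingness** is MCAR only (per-cell Bernoulli, default rate 0.05 at
  the category level), because the study does not characterise its
  missingness mechanism.

What the generator does **not** emulate: spatial autocorrelation of noise
beyond department means, item-level response styles (acquiescence,
halo effects), non-MCAR missingness, and any pandemic-era shift in care
quality. Passing tests therefore demonstrate the correctness and
stability of the pipeline under the assumed dependency structure — not
that real cohorts satisfy that structure.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 200 random networks of 3–8
ternary nodes for the inference-vs-enumeration property; n = 5000
complete records for EM parameter recovery, asserting both exact equality
of learned rows with conditional frequencies (the noise-free content) and
total variation ≤ 0.05 against the truth for parent configurations with
at least 400 records — at smaller counts the bound is dominated by
binomial sampling noise rather than estimation quality; n = 50000 for the
exposure-marginal calibration check (±0.02); cohorts of 209–500 for the
round-trip identities; and the full study-scale end-to-end run (n = 209,
1510 grid points, 10 folds), which completes in well under two minutes on
one CPU. Stochastic unit checks assert within three binomial standard
errors of the realised subgroup size. CPT rows are validated to sum to 1
within $10^{-9}$ after construction and after every M-step; probability
vectors returned by inference are normalised exactly once, at the end of
elimination.

## Known limitations

Only the noise *level* is modelled: frequency content and psychoacoustic
indices are out of scope, as are floor-plan graphics, structure learning
(the study's structure is expert-drawn), continuous or hybrid nodes, and
approximate inference. The published cohort-dependent numbers (per-group
means, the scenario percentages, the influence values, the confusion
matrix and AUC) are not reproducible without the undeposited records and
unprinted CPTs; the package instead verifies every reproducible quantity
and all structural properties of the method.
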