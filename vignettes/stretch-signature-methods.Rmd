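---
title: "Methods: pooled discovery and validation of stretch transcriptomic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled discovery and validation of stretch transcriptomic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Mechanical ventilation can injure the lung by cyclic overdistention
(ventilator-induced lung injury, VILI). Individual expression studies of
cells or animals exposed to cyclic stretch are small and measured on
heterogeneous platforms, so no single study supports a reliable molecular
read-out of stretch. `stretchsig` implements a meta-analytic workflow that
pools such studies, identifies stretch-responsive features while
controlling for co-occurring injury stimuli ("second hits" such as LPS),
condenses them into a per-sample transcriptomic score, refines the feature
set for discrimination, and stress-tests the result with resampling-based
robustness analyses.

The package ships a synthetic multi-study generator so that every step of
the workflow can be exercised, and its statistical behavior verified,
without access to the original repositories.

# Control-anchored co-normalization

Studies are pooled on the exact intersection of their feature sets
(features absent from any study are dropped) and batch-corrected with a
location/scale model fitted **on control samples only** — samples with
neither stretch nor a second hit. For feature $g$ in study $i$, controls
are assumed to follow

$$ y_{ijg} = \alpha_g + \gamma_{ig} + \delta_{ig}\,\varepsilon_{ijg}, $$

with $\alpha_g$ the grand control mean, $\gamma_{ig}$ and $\delta_{ig}$ the
per-study location and scale distortions, and unit-variance noise
$\varepsilon$. The fit standardizes by $\alpha_g$ and the pooled control
scale $\sigma_g$, estimates $\gamma_{ig}$, $\delta_{ig}$ per batch, and —
with `eb = TRUE` — shrinks them by parametric empirical Bayes (normal prior
on locations, inverse-gamma prior on squared scales, moment-matched
hyperparameters, fixed-point iteration of the conditional posterior means).
The corrections estimated on controls are then applied to **all** samples
of each study. Because cases and controls of a study receive the same
correction, case–control contrasts pass through unchanged while study
means and scales align; this is what makes pooling admissible without
erasing the disease signal.

Numerical choices:

* The pooled scale uses the $(n_i - 1)$-weighted pooled variance of
  control residuals, so a single study standardizes to exactly unit batch
  parameters and pooling one study is an identity (this is asserted to
  1e-8 in the tests).
* The EB fixed point iterates to a relative tolerance of `1e-6`, at most
  200 iterations; convergence deltas and iteration counts are kept in the
  fitted object for audit.
* Features with (near-)zero control variance are floored at
  `scale_floor = 1e-8` and flagged rather than dropped, avoiding division
  by zero without silently losing data.
* Batches whose hyperparameter moments are degenerate (e.g. a
  near-constant batch) keep their direct estimates; the `shrunk` flag in
  the fitted object records this.
* A non-EB mode (`eb = FALSE`) uses the unshrunken per-batch estimates; in
  noise-free constructions it aligns control means exactly, which the unit
  tests exploit as a closed-form oracle.

A deliberate property of EB shrinkage is that when batch effects are
homogeneous across features, per-feature batch estimates are pulled toward
the common batch mean and a fraction of the per-feature sampling noise
survives the correction. Cross-study control-mean alignment after EB
therefore improves with the number of controls per study; the acceptance
checks use 3 studies with 80 controls per group and residual SD 0.5, where
mean absolute cross-study control-mean differences fall below 0.05 while
planted effects are recovered within ±10%.

# Differential expression

Each feature of the pooled matrix is fitted by ordinary least squares with
intercept, stretch and second-hit main effects (no interaction), and
two-sided t-tests on the residual degrees of freedom. No variance
moderation is applied: with pooled sample sizes in the dozens the plain
per-feature test is adequate, and moderation would add an assumption the
workflow does not need. If the second-hit indicator is constant it is
dropped and the model reduces to a two-group comparison (then the stretch
p-value equals the pooled-variance t-test exactly). Degenerate fits — zero
residual degrees of freedom, perfectly collinear factors, zero residual
variance — are reported as *untested* (`NA` p-values) rather than raising
errors or contributing spurious zeros.

P-values are adjusted by Benjamini–Hochberg step-up **separately per
coefficient** (all stretch p-values form one family, all second-hit
p-values another), with untested features excluded from the family size.
Signature selection thresholds the adjusted stretch p-value — by
convention 0.1 for the small miRNA analyses (protecting against false
negatives at n ≈ 24) and 0.01 for the gene analyses — and splits features
by coefficient sign into up- and down-regulated sets. A `stretch_only`
switch optionally excludes features that are also significant for the
second hit; both variants are exposed because the partition of
stretch-only versus dual-response genes is itself of interest, and the
selection counts (stretch-only / hit-only / both) are always attached to
the result.

# Transcriptomic scores

For a signature with up-set $U$ and down-set $D$, each sample's score is

$$ s_j = \Big(\prod_{g \in U} y_{jg}\Big)^{1/|U|} -
         \Big(\prod_{g \in D} y_{jg}\Big)^{1/|D|}, $$

the geometric mean of up-regulated expression minus the geometric mean of
down-regulated expression. An empty side contributes 0, so one-sided
signatures (such as an all-up-regulated refined set) score as a plain
geometric mean. Geometric means need positive values; if any required
value is non-positive the matrix is shifted once, globally, by
$1 - \min(Y)$ and the shift is recorded in the report. A single global
shift (rather than per-sample shifts) is used because the score exists to
compare samples: per-sample shifts would distort exactly the contrast
being measured. The synthetic generator defaults to log2-scale baselines
(mean 8, SD 2), matching microarray conventions, so shifts are rarely
triggered in practice.

# Greedy AUROC refinement

Large threshold-selected signatures are refined by forward selection: from
the empty set, every remaining candidate is tentatively added on its
DE-derived direction side, and the candidate that maximizes the AUROC of
the resulting score against the stretch labels is kept. Selection stops
when no addition *strictly* improves the AUROC, when the AUROC reaches 1,
or at `max_size` (default 10). Ties are broken by smaller adjusted stretch
p-value, then lexicographic feature id, which makes the output invariant
to candidate order. The direction of each candidate is fixed by its DE
coefficient sign rather than searched, because the score definition ties
direction to the regulation sense. Forward selection was chosen over
backward elimination because it reaches small signatures directly from
large candidate pools; a backward mode (`method = "backward"`) is provided
for comparison. The returned trace (feature, direction, AUROC per step) is
strictly increasing by construction and the final AUROC dominates every
single-candidate AUROC.

# Evaluation

* **AUROC** uses the Mann–Whitney formulation (fraction of
  positive/negative pairs ordered correctly, ties counting 1/2), computed
  via mid-ranks. It is exact, rank-based, and cross-checked in the tests
  against both exhaustive pair enumeration and an independent ROC
  implementation.
* **Confidence intervals** come from a stratified bootstrap (resampling
  within class, `B = 2000` by default, percentile 2.5/97.5 interval). A
  percentile bootstrap was preferred to a closed-form variance because it
  matches the resampling character of the rest of the evaluation and makes
  no normality assumption near AUROC 1.
* **Random-signature null**: `B` random disjoint up/down sets matching the
  evaluated signature's split sizes are drawn uniformly without
  replacement, scored, and their AUROCs collected; the exceedance
  probability at a query threshold (default 0.9) estimates how often a
  random signature of the same structure performs as well. Matching the
  split sizes keeps the null comparable to the score's structure.
* **Leave-one-study-out**: each study is excluded in turn and the entire
  pooling is re-fitted from scratch before re-scoring — robustness is
  assessed against the full pipeline, not just the final score. Rounds
  left with a single class are flagged, not fatal.
* **Dose–response**: Spearman's rank correlation (Pearson on mid-ranks,
  t-approximation p-value) between score and the study-level stretch
  magnitude, with unstretched samples at magnitude 0.
* **Group comparisons**: pooled-variance t-test for two groups; one-way
  ANOVA for more, with Tukey HSD pairwise comparisons gated on ANOVA
  p < 0.05 (conventional post-hoc usage).

# The synthetic generator

`generate_studies()` draws per-feature log2 baselines
$b_g \sim N(8, 2^2)$, per-study batch shifts $\sim N(0,
\texttt{batch\_loc\_sd}^2)$ and log-scales $\sim N(0,
\texttt{batch\_scale\_sd}^2)$, and produces

$$ y = b_g + \text{shift}_i + \text{scale}_i\big(\beta_g\,
\text{stretch}\,(1 + \lambda m_i) + \eta_g\,\text{hit} +
\varepsilon\big), $$

where $\beta_g$ is the planted stretch effect (±`effect_size` in residual
SD units), $\eta_g$ the planted second-hit effect, $\lambda$ the
dose–response slope and $m_i$ the study-level magnitude (a tidal-volume
analog; per-study rather than per-sample, as ventilator settings are
study-level choices in animal work). Effects are defined in residual-SD
units; in diagnostic no-noise configurations the unit degenerates, so the
generator then interprets `effect_size` in log2 units directly. Noise is
homoscedastic by default — the within-group variance structure of real
repositories is unknown, and a homoscedastic default keeps planted effect
sizes interpretable. Second-hit effects are additive with stretch effects
(no interaction), mirroring the two-main-effects analysis model. A single
seed drives one documented pseudo-random stream, so ground truth can be
replayed; `generate_studies(config, truth = …)` regenerates an
independent cohort carrying the same planted signature, which is how
test-set AUROCs are obtained.

`simulate_discovery_bundle()` assembles the three-tier input the full
workflow expects — miRNA studies, cell gene studies with second-hit
groups, animal studies with magnitudes (defaults 0/10/15/30, slope 0.03
per unit) — plus a target map in which planted genes are targets of the
planted miRNAs, diluted with decoy targets and background targets of
non-signature miRNAs, and with a fraction (default 20%) of non-planted
genes missing from the animal tier to emulate cross-platform feature
availability.

What the generator does **not** emulate: platform-specific probe
behavior, missingness patterns, correlated co-expression modules,
count-based single-cell noise, or heteroscedasticity calibrated to any
real repository (a heteroscedastic option exists but is uncalibrated).
Tests passing on synthetic data therefore demonstrate the statistical
correctness and calibration of the machinery under the stated model, not
performance on any particular public data set.

# Problem sizes used in the checks

The packaged statistical checks run at desk scale, chosen to keep each
property statistically decidable: AUROC/BH oracle equivalence on
500/1000 random instances; false-discovery calibration on 200 replicates
of a 1000-feature, 40-sample global null; co-normalization alignment on 3
studies × 160 samples; greedy recovery with 6 planted genes among 144
candidates over 5 studies × 20 samples with an independent test cohort;
null calibration with 1000 random signatures; leave-one-study-out
stability over 50 replicates of 3-study designs. `scripts/acceptance.R`
runs the full three-tier workflow on the default bundle and reports the
headline quantities it computes.

# Known limitations

* The empirical-Bayes correction assumes exchangeable per-feature batch
  effects; with feature-homogeneous batch shifts it deliberately leaves a
  shrinkage-dependent share of sampling noise (see above).
* Per-feature OLS assumes homoscedastic residuals within the pooled
  matrix; no surrogate-variable or study covariate is added after
  pooling, on the premise that control-anchored correction has removed
  study effects.
* The greedy search optimizes discovery-set AUROC and can overfit small
  pools; the independent-cohort evaluation and leave-one-study-out
  analyses are the intended guardrails, not cross-validated selection.
* Scores are not z-scored or rank-transformed; samples are comparable
  only within a co-normalized pool.
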