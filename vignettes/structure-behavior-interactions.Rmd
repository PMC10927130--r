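---
title: "Structure-behavior interactions: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-behavior interactions: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rptfusion)
```

rptfusion asks whether the *relationships* between operant reward/aversion
behavior and normalized brain-structure volumes — rather than either
variable set alone — separate clinical groups (healthy controls, major
depressive disorder, cocaine-dependence polysubstance use). This vignette
is the package's own account of the models it implements, the conventions
it had to choose where the methodology is underdetermined, and what its
synthetic validation does and does not establish.

## The behavioral model

In an operant keypress task, participants trade keypresses to lengthen
(approach, "inc") or shorten (avoid, "dec") the viewing time of pictures
drawn from four categories of twenty pictures each. Relative preference
theory (RPT) summarizes each participant's judgment pattern with three
curves over the per-category summary variables
$\{K_\pm, H_\pm, \sigma_\pm\}$ — mean keypress intensity, Shannon entropy
(bits) of the keypress distribution over pictures, and keypress standard
deviation, per valence:

* **Value function** $H = b\,\ln(K - x_0)$: entropy of judgments against
  their intensity. On the avoidance limb, the curvature $b$ is *loss
  resilience* and the offset $x_0$ the *negative offset*. Both parameters
  are free; $b$ is profiled out analytically and $x_0$ found by a coarse
  grid over $(\min K - 10\,\mathrm{range}, \min K)$ refined with
  one-dimensional minimization to a $10^{-12}$ objective tolerance. A
  power-law form $H = aK^b$ is the fallback when the log fit is
  numerically degenerate, and can be forced by configuration.
* **Limit function** $\sigma = aK^2 + bK + c$: judgment variability rises
  with intensity to a peak and falls back. Features are the closed-form
  vertex — turning point $-b/2a$, apex $c - b^2/4a$ — and the quadratic
  area between the real roots, $(b^2-4ac)^{3/2}/6a^2$. When the fitted
  parabola has no real roots ($\mathrm{disc} \le 0$) or no curvature
  ($|a| < 10^{-10}$), the area is undefined and the fit is flagged failed:
  the area is a required downstream feature.
* **Trade-off function**: per category, the point $(H_+, H_-)$ has radial
  distance $r = \sqrt{H_+^2 + H_-^2}$ and polar angle
  $\theta = \arctan(H_-/H_+)$ in degrees from the $H_+$ axis; the four
  trade-off metrics are the across-category mean and sample SD of each.

The fifteen *keypress metrics* are the nine RPT features (avoidance value
and limit features plus the four trade-off features) and the six base
variables averaged across categories. Positive-limb value/limit features
remain computable by the valence-generic fitting code but are not part of
the metric canon: in practice approach-side data are too sparse to fit
reliably, so the negative limb carries the individual-difference signal.

Participants whose avoidance value fit, avoidance limit fit, or trade-off
construction fails are flagged invalid with a reason code and excluded
from group-level analyses — the same exclusion logic applied to real
cohorts, where a substantial minority of recruited participants cannot be
fit.

### Conventions the entropy and moments require

The entropy operationalization is the within-category entropy of a
participant's keypress counts over pictures, $-\sum p_i \log_2 p_i$ with
$p_i = k_i/\sum k$ over nonzero counts, ceiling $\log_2 20$. $K$ and
$\sigma$ are computed over pictures with nonzero counts of the given
valence — the work actually traded — with a zero-inclusive switch
(`include_zeros`). Across-category dispersions use the sample SD
($n-1$), 0 when only one category is usable. Each fit needs at least
three distinct-$K$ category points; with four categories there is little
redundancy, which is faithful to the task design and is the main reason
individual fits can fail.

## The synthetic cohort generator

The generator is first-class, tested code: it is the ground truth against
which every downstream stage is validated. It emulates

* three groups with the study design's sizes (40 CTRL, 25 MDD, 46 CD by
  default);
* per-picture keypress counts: each picture gets a latent valence per
  participant (approach with probability 0.5 per category by default) and
  a count on that side only, drawn negative-binomially with configurable
  dispersion (Poisson in the default $\text{size} \to \infty$ limit).
  Category means default to approach (3, 5, 8, 12) and avoid
  (2, 4, 7, 11) keypresses per picture: the spread makes the four
  per-category points identifiable for the value and limit fits, and the
  Poisson $\sigma = \sqrt{\mu}$ concavity gives the limit function its
  downward curvature on average;
* 29 regional volumes as fractions of total brain volume around
  anatomically plausible baselines (summing to about 0.95), with planted
  couplings: for a coupled (volume, metric, group), the volume z-score is
  $\rho\, z_{\text{metric}} + \sqrt{1-\rho^2}\,\varepsilon$, so $\rho$ is
  the within-group population standardized slope. Z-scores map to
  fractions via a 6% coefficient of variation, floored at 5% of baseline;
* demographics (age 37.9 ± 10.6 years, education 14.5 ± 2.5 years,
  70% male, ethnicity mostly White with a small Asian stratum) sampled
  independently of volumes, with an optional `age_volume_slope` switch
  that plants an age effect to exercise covariate screening.

What it deliberately does **not** emulate: anatomical covariance between
regions (volumes are conditionally independent given the planted
couplings), trial-level task mechanics (a single count per picture
abstracts the trading process), longitudinal or scanner noise, and any
group differences in mean behavior unless planted. Passing the
calibration and recovery checks therefore shows the *pipeline* is
statistically sound, not that real cohorts satisfy its assumptions.
Roughly a quarter of generated participants fail the RPT fit-validity
rule under the defaults — a smaller exclusion fraction than real
recruitment typically suffers, but qualitatively the same mechanism.

## The regression grid

Within each group, each of the 15 metrics (response) is regressed on
each of the 29 volumes (predictor): 435 cells. Demographic covariates
are screened per (group, volume): ethnicity by rank-sum between the two
largest strata (Asian participants dropped from the test, and from
regressions where ethnicity enters), age and education by Spearman
correlation, included when $p < .05$. Retained observations are z-scored
within group after outlier removal, so the volume coefficient is a
standardized $\beta$ equal to the Pearson correlation in the
covariate-free case. q-values are Benjamini–Hochberg within the
15-metric family sharing one (group, volume) — the convention that makes
a rank-1 $p = .001$ into $q = .015$ — with a global-family switch for
sensitivity analyses. Regressions need $n \ge 10$ complete cases; cells
failing preconditions are carried as skipped rows.

### Cook's-distance filtering, and why the calibration checks bypass it

The filter refits iteratively, removing the single worst observation
while $\max_i D_i > 4/n$, capped at 20% of the sample (a single-pass
variant is available; which convention original analyses of this kind
used is generally not reported). This is a faithful implementation of a
widespread practice — and that practice is anti-conservative. Deleting
the most influential points and re-testing inflates the nominal 5% level
several-fold at these sample sizes: the acceptance script's
`null_grid_significant_fraction_cooks` quantity measures the filtered
null rejection rate on a fully null cohort (around four times nominal at
$n = 40$/group under the iterative default), against
`null_grid_significant_fraction` for the unfiltered grid, which sits on
the nominal level. The filter can also *erase* genuine couplings planted
on heavy-tailed metrics (the quadratic turning point is the worst case:
near-degenerate parabola fits put its distribution's mass in extreme
values, exactly the points the filter deletes, a pure
range-restriction loss).

For these reasons the generator-validation checks — null calibration
within the exact binomial 99% band around 0.05, and recovery of planted
$|\rho| \ge 0.5$ couplings at 200/group — run the grid with
`cooks = FALSE`, one consistent estimator convention for both; the
filtered rates are computed and reported alongside rather than asserted.
Analyses of real cohorts keep the filter on by default for comparability
with the practice they mirror, and every switch
(`cooks`, `cutoff_factor`, `cap`, `convention`) is exposed.

Cross-group overlap accounting counts the cells significant in two
groups, flags whether the two $\beta$s share a sign, and reports the
"$2c$ of $T$" consistency percentage over the total significant
regressions, plus the volumes shared between groups outside the common
cells.

## Heatmap comparison framework

From covariate-free $\beta$ matrices (filtering conventions as
configured), group pairs are compared elementwise on three axes:
valence $|\beta_A| - |\beta_B|$, intensity $|\beta_A - \beta_B|$, and
sign agreement ($\pm 1$). All 435 defined cells enter the summary tests
— the framework compares whole association patterns, not only the
significant fringe — with pairwise deletion of undefined cells.
Valence is tested with a one-sample t-test against mean 0. Intensity is
summarized by its median and tested with a one-sample Wilcoxon
signed-rank test against 0 (the nominal description of this test in the
literature this mirrors conflates rank-sum and signed-rank; the
one-sample signed-rank form is the coherent reading for a single
difference distribution, and the values being nonnegative makes it
essentially a sign test of any difference at all — the median is the
interpretable quantity). The direction test treats same-sign cells as
successes against a null success probability of 0.5, via the
normal-approximation z-test without continuity correction (exact
binomial by configuration). Heatmap images are deterministic ggplot2
tile maps, volumes on y, metrics on x, diverging scales anchored at the
documented ranges ($\beta$: −1 red to +1 blue).

## Feature selection and kNN fusion

Candidate classification features are screened across the three groups
with Kruskal–Wallis and Dunn's pairwise post-hoc test (mean-rank z with
tie correction, implemented in closed form and verified against an
exhaustive small-sample oracle), BH-corrected within each feature's
three pairs; a feature is selected when any pairwise $q < .05$.

Pairwise leave-one-out kNN (k = 5) then classifies each group pair over
six feature combinations (metrics, volumes, demographics, and their
unions). Continuous features are whitened by the inverse principal
square root of the pooled within-group covariance — the Mahalanobis
transform, making Euclidean distance covariance-adjusted — with a ridge
fallback for singular covariances; one-hot demographic indicators bypass
the whitening and are appended unscaled. The class score is
$\text{prior}_g \times \text{votes}_g / k$ with priors defaulting to
class proportions; score ties break toward the larger prior, then
lexicographically, and distance ties by stable index order, making the
procedure fully deterministic. The transform is refit inside every
leave-one-out fold by default: fitting it once on the whole sample leaks
the held-out point into the metric (the original practice this mirrors
most likely fit once; `refit_transform = FALSE` reproduces that).

## Problem sizes and numerical choices

The test suite validates calibration on a 40/40/40 null cohort (three
435-cell grids against the exact binomial 99% band), recovery on eight
planted couplings at 200/group, and every closed-form feature against
independent oracles (exhaustive enumeration for the signed-rank test,
normal-equation solutions for the quadratic, brute-force distance
matrices for kNN). Monte-Carlo checks use 100 replicates. These sizes
were chosen as the smallest that make the binomial bands and power
statements sharp.

Remaining numerical conventions: value-function offset search tolerance
$10^{-12}$ on the objective; quadratic degeneracy threshold
$|a| < 10^{-10}$; Mahalanobis ridge default $10^{-8}$ in the classifier;
entropy of a single active picture defined as 0 bits; a category with
both entropies zero contributes no trade-off point; all-zero count
vectors yield undefined (not zero) entropy.

## Known limitations

* The entropy estimator and the per-participant (vs pooled) fitting
  scheme are operationalizations; the upstream literature defers their
  details to task-specific conventions, so they are isolated behind
  single functions and switches.
* Exact replication of published per-cell coefficients is sensitive to
  the unstated Cook's convention (cutoff, iteration, order) of the
  original statistical software.
* The generator's independence assumptions make the 435 grid cells more
  independent than real data, where volumes correlate anatomically; the
  binomial calibration band is therefore cleaner in simulation than it
  would be on real cohorts.
* kNN accuracy statements on synthetic cohorts reflect planted geometry
  only; nothing here validates clinical discriminability.
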