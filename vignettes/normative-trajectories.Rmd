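---
title: "Normative brain-volume trajectories: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative brain-volume trajectories: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braintraj)
```

## The problem

Cross-sectional MRI volumetry yields, per subject, the volumes (mm^3) of 95
brain structures under the Desikan-Killiany-Tourville convention: 45
left/right pairs plus 5 midline structures. Pooling several cohorts buys
age coverage and demographic diversity at the price of two confounds —
sex (male brains are systematically larger) and cohort membership
(scanner, site, recruitment). `braintraj` implements the full descriptive
pipeline from such tables to a normative reference of age-related change:
confound removal, decade-binned summaries, symmetric percent-change
statistics, and classification of non-monotonic (U / inverted-U)
trajectories, together with inter-pipeline agreement metrics and a
synthetic cohort generator that makes every stage testable without any
subject data.

## Dual confound correction

For each region independently, observed volume is modelled by ordinary
least squares as

$$V_i = \beta_0 + \beta_1\,\mathrm{Sex}_i + \beta_2\,\mathrm{Age}_i +
\sum_{k=1}^{K-1}\gamma_k\,\mathbf{1}\{\mathrm{Cohort}_i = k\} +
\varepsilon_i,$$

with sex coded male = 1, female = 0, age in years, and cohort indicators
relative to a reference cohort (first in lexicographic order unless
configured; the choice shifts corrected volumes by a constant that cancels
in every downstream change statistic). Corrected volumes subtract only the
fitted sex and cohort contributions,

$$V_i^{\mathrm{corr}} = V_i - \big[\hat\beta_1\,\mathrm{Sex}_i +
\textstyle\sum_k \hat\gamma_k\,\mathbf{1}\{\mathrm{Cohort}_i=k\}\big],$$

so the age trend and residual individual differences pass through intact;
reference-cohort females are untouched by construction.

Removal is verified by refitting the sex + cohort terms on corrected
volumes and adjusting the coefficient p-values by Benjamini-Hochberg in
two families: one sex test per region, and one test per region x
non-reference cohort. A deliberate design choice: **the verification model
retains age as a covariate by default**. The cohorts cover different age
ranges (the ADNI-like cohort contributes only ages 51-90), so an age-blind
re-test would attribute genuine age-trajectory signal to the cohort
indicators and could never declare cohort effects eliminated no matter how
good the correction. With age retained, the re-test asks the right
question — is there a residual sex/cohort difference *at fixed age?* — and
refitting the same design on residualized data returns exactly zero
coefficients (a projection identity), which is what a complete elimination
report means. `verify_correction(include_age = FALSE)` gives the
age-blind variant.

Correction quality is summarized by the marginal sex effect size per
region (Cohen's d with the pooled-variance denominator, not Hedges' g),
the preserved age-related variance (squared correlation of corrected
volume with age — the marginal age r^2, with no partialling of other
covariates), and preserved individual differences (ICC(2,1) between raw
and corrected volumes).

## Binned summaries and the three change statistics

Ages map to seven decade bins, 21-30 through 81-90, inclusive integer
bounds. Ages below 21 are folded into the first bin with a warning (one
contributing cohort recruits from age 20); ages above 90 are excluded with
a warning. Within each (region, bin) cell the mean and SD are computed
after excluding zero volumes — a zero is a segmentation failure, not a
measurement — and the 95% CI is the normal-theory
$\bar V \pm 1.96\,s/\sqrt{n}$. A subject missing a region is excluded from
that region's summaries only, never dropped globally.

All change statistics are symmetric percent changes,
$100\,(b-a)/\tfrac{a+b}{2}$: bounded in (-200, 200), antisymmetric, and
scale-invariant. Three are reported per region over the vector of seven
bin means: **endpoint change** (youngest vs oldest bin), **range change**
(smallest vs largest bin mean; by construction at least the absolute
endpoint change, and the statistic that exposes mid-life extremes), and
**maximum consecutive change** (largest absolute change between adjacent
bins — the steepest decade).

## Trajectory classification

Each region's seven bin means are fitted against bin midpoint ages (25.5,
35.5, ..., 85.5) with a line and a cubic
$V = \alpha_0 + \alpha_1 A + \alpha_2 A^2 + \alpha_3 A^3$. Midpoints are
the natural abscissa for decade-bin summaries and keep the coefficients in
year units; the classification itself is invariant to affine re-coding of
age. The R^2 gain of the cubic over the line (non-negative; nested models)
must exceed 0.2 for a region to be called non-linear — with only seven
points a cubic always fits somewhat better, and the threshold separates
structure from flexibility.

Peak detection is analytic: the real roots of the cubic's derivative that
lie strictly inside the fitted age range are candidate extrema; positive
second derivative means a local minimum (U-shaped), negative a local
maximum (inverted-U). When both a minimum and a maximum are interior, the
extremum whose fitted value deviates farther from the chord joining the
endpoint fits wins — the cubic's two bends are then both real, and the
dominant one names the pattern. Fewer than four points fall back to the
linear fit.

Applied to the bundled normative table, this labels caudate, pallidum and
insula U-shaped and entorhinal, hippocampus, amygdala and brain stem
inverted-U, with every other region linear; the R^2 improvements under the
midpoint encoding (0.766 for the caudate down to 0.231 for the brain
stem) and the change statistics can be recomputed with
`trajectory_table(bin_means_matrix())`.

## Agreement between segmentation pipelines

When two pipelines measure the same subjects, volumes are combined
bilaterally, grouped into the six-category validation grouping (frontal,
parietal, temporal, occipital lobes, limbic structures, cerebellum), and
pooled within groups as (subject, structure) targets. Per group the report
carries the two method means, the SD of paired differences, ICC(2,1),
between-subject CoV, Cohen's D, the Bland-Altman reproducibility
coefficient, and R^2. Definitions that were genuinely open, fixed as
follows:

* **ICC form**: ICC(2,1) — two-way random effects, single rater, absolute
  agreement — the method-comparison convention; a constant offset between
  pipelines lowers it, unlike a consistency ICC.
* **CoV**: between-subject SD over the grand mean of the pooled values of
  both methods, in percent. This reads as biological spread (a few
  percent), the only interpretation consistent with method differences an
  order of magnitude smaller.
* **Effect size D**: method offset over pooled *between-subject* SD, not
  over the SD of differences, so it is commensurable with biological
  effect sizes.
* **Reproducibility coefficient**: the standard Bland-Altman
  $1.96 \times \mathrm{SD}(\mathrm{differences})$.
* **R^2**: squared Pearson correlation of the pooled paired values.

## The synthetic cohort generator

`synthetic_spec()` defines the study conditions the package is tested
under; `generate_volumes()` draws from them. The default plan reproduces a
three-cohort adult design of about 1830 subjects — a Korean community
sample (ages 21-80, male-heavy young bins), an IXI-like sample (21-90,
midlife-heavy, more women than men), and an ADNI-like sample contributing
only ages 51-90 — with exact per-cell sex counts and integer ages uniform
within each decade bin. Volumes follow the additive model the correction
stage assumes:

$$V = \mathrm{baseline} + f(\mathrm{Age} - 55.5) +
\delta_s\,\mathbf{1}\{\mathrm{male}\} + \mathrm{offset}_{\mathrm{cohort}} +
\mathcal N(0, \sigma^2),$$

with $f$ a cubic (linear by default), homoscedastic Gaussian noise (the
simplest model consistent with the OLS machinery), and negative draws
clipped at zero with a warning. Per-region defaults come from the bundled
normative table: baseline and slope from the least-squares line through
the seven bin means, $\sigma$ from the 21-30 bin SD. Cohort offsets
default to 0 / +0.5 / -0.5 noise SDs for the ADNI-like (reference),
IXI-like and Korean cohorts.

The sex offset is calibrated, not fixed: because the sexes differ in age
and cohort mix, a naive offset of $0.427\sigma$ would miss the *measured*
marginal effect size per region by up to ±0.2. With `sex_delta = NA`
(default) the generator solves for the offset that makes the realized
marginal Cohen's d equal the target (default 0.427) under the sampled
demographics, netting out the deterministic male-female cross-term.

What the generator deliberately does **not** emulate: heteroscedastic
noise (real within-bin SDs grow with age, drastically for ventricular
compartments), longitudinal correlation, scanner/site structure below the
cohort level, and non-Gaussian tails. Tests passing under these conditions
therefore certify the estimators and the pipeline logic, not robustness to
those features of real data.

## Numerical choices and degenerate inputs

* Table comparisons round half-away-from-zero to 1 decimal place,
  matching display precision of normative references.
* Percent-change statistics require strictly positive inputs and signal
  otherwise; a missing interior bin degrades the consecutive/range
  statistics to the available pairs with a warning.
* `bh_fdr()` delegates to `stats::p.adjust(method = "BH")`; the test suite
  holds it against a brute-force step-up oracle at 1e-12.
* ICC(2,1) is computed from explicit mean-squares sums; tests verify it
  against `stats::aov` decompositions at 1e-10, and it is signalled as
  undefined when between-target variance vanishes.
* Cubic fits use `stats::lm`; tests verify coefficients against explicit
  normal equations at 1e-8. A derivative whose leading coefficient is
  numerically zero is handled as the quadratic/linear special case.
* Collinear confound designs (e.g. a cohort containing only one sex) stop
  with the aliased terms named; single-sex or single-cohort inputs are
  legal and simply drop the constant term, making correction the
  identity there.

## Known limitations

* **The sex-age imbalance leaves a floor under the marginal post-correction
  d.** Correction removes the sex effect at fixed age exactly, but the
  marginal male-female contrast retains `slope x (age gap between sexes)`
  — about 3.4 years under the default demographics. Under the default
  noise scale this floor is a mean |d| near 0.08, so the measured mean
  reduction sits near 80% rather than at 100%; in real data the same
  comparison lands somewhat higher because within-bin dispersion grows
  with age and dilutes the confound. This is a property of marginal
  effect sizes under confounded demographics, not an estimation error —
  the age-adjusted residual sex coefficients are zero to machine
  precision.
* Decade bins with very few subjects (the oldest bins of small cohorts)
  make noisy endpoints; the change statistics use bin means without
  shrinkage.
* The improvement threshold 0.2 on seven points is a convention; patterns
  whose curvature is real but mild (R^2 gain below the threshold) are
  reported linear.
* No spline/GAMLSS centile modelling, no ComBat-style empirical-Bayes
  harmonization, no subject-level brain-age prediction — the package is
  descriptive by design.

## Problem sizes used by the test suite

Chosen to exercise each claim at meaningful power: parameter recovery on
~3,000 synthetic subjects; the correction-effectiveness reproduction on
the full default plan (50 regions x ~1,830 subjects); oracle comparisons
on 1,000 random p-vectors, 20 ICC instances of n <= 20, and 20 random
7-point polynomial fits; classification recovery over 200 noise seeds;
CI coverage over 1,000 seeds at n = 50 per bin.
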