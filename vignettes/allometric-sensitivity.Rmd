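---
title: "Allometric sensitivity of lidar biomass estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric sensitivity of lidar biomass estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomap)
```

## The problem

A lidar biomass map is calibrated against field *estimates* of plot biomass,
and those estimates depend on which allometric model family converted the
tree list into kilograms. `allomap` runs one identical pipeline — height
imputation, Bitterlich expansion, lidar metrics, random-forest modeling,
model-assisted county inference — once per allometric family, so that every
downstream difference between the resulting maps and county totals is
attributable to allometry alone. The predictor set, filtering rules and
random-forest configuration are deliberately frozen across families for this
reason.

## Allometric engines

**Generalized ln–ln models.** Both the Jenkins-type (10 broad species
groups) and Chojnacky-type (finer taxonomic groups) families are evaluated as
`AGB_kg = exp(b0 + b1 ln(DBH_cm))`. The two families differ *only* through
the registry: which group a species resolves to and that group's
coefficients. This is a deliberate design point — with coefficients set
equal group-for-group the two families return identical estimates, a
structural property the test suite asserts. The shipped registry values are
illustrative; serious analyses should load the authoritative published
tables through `read_coefficient_registry()`, which reads long-format
delimited text (`family, group_id, parameter, value`) so no code changes are
needed. Each group may carry `dbh_max_sampled`, the largest destructively
sampled stem; estimates beyond it are flagged as extrapolations rather than
refused, since practitioners apply these models regardless of stem size and
the flag count is itself a useful diagnostic.

**Component Ratio Method.** The CRM chain is: merchantable volume →
specific gravity → bole mass → bark and branch components → total. The
volume model is pluggable per group; the default is the combined-variable
form `V = a + b · DBH² · H` (DBH cm, H m, V m³), the simplest widely
published regional form, chosen so any regional table can be dropped into
the registry. Bark and branch ratios are power functions of DBH
(`r0 · DBH^r1`), clamped to [0, 2] to keep pathological coefficient inputs
from producing negative or explosive components; a negative predicted volume
is clamped to zero with a warning. Additivity — `total = bole + bark +
branch` — is an invariant, tested to 1e-9 relative over randomized
coefficients. All computation is metric; the single conversion constant
(volume × specific gravity × 1000 kg/m³) lives in one place, so loading
tables published in imperial units requires converting the parameters, not
the code.

## Heights, the cap, and plot expansion

The CRM needs a height for every stem, but inventories typically measure only
the tallest one to three trees per plot. `fit_height_model()` is ordinary
least squares of height on DBH; its RMSE is `sqrt(mean(residual²))` on the
fitting data. A linear model over-predicts for diameters beyond its
calibration range, so imputed heights are capped at the maximum lidar return
height of the containing 30 m pixel. Two deliberate choices: the cap applies
only to *imputed* heights (a measured height is evidence, the model
prediction is not), and capped predictions are floored just above breast
height (1.40 m) so volume models stay valid when the containing pixel is
nearly empty. Measured heights are used whenever present;
`force_predicted = TRUE` switches every stem to (capped) predictions for the
sensitivity analysis of that choice.

"Plot area of a tree" in a variable-radius plot is interpreted as standard
Bitterlich sampling: a stem of basal area `g` (m²) counted under basal-area
factor `BAF` (m²/ha) represents `BAF/g` stems per hectare, so its density
contribution is `AGB_Mg · BAF / g`. Expansion is linear in biomass and
proportional to BAF, both asserted as properties. The BAF is a configuration
input (fixture default 2 m²/ha); absolute plot densities scale with it, so
results quoted from synthetic data are configuration-sensitive in that one
respect.

## Lidar metrics

Percentiles are **nearest-rank on sorted heights**: `z_sorted[ceil(p/100 ·
n)]`. LAS-processing tools differ in their percentile interpolation; nearest
rank is deterministic, tool-independent, and exactly reproducible by a
one-line oracle, which is how the tests check it. Bincentiles are the
percentage of returns between a height cutoff and the maximum return height;
canopy cover is the percentage of returns above the cover cutoff. Defaults
— cover cutoff 2 m, bincentile cutoffs {2, 5, 10, 20, 30, 40, 50} m — are
conventional choices for temperate conifer/hardwood canopies. "Canopy
density" is implemented as cover computed over first returns only (an
interpretation; with single-return data it degenerates to cover). Pixel
gridding uses half-open cells `[x0, x0 + 30)` so no return is double
counted. Empty return sets yield all-zero metrics with `n_returns = 0`
rather than an error, because zero-vegetation footprints are a legitimate
state that the outlier filters, not the metric engine, should reason about.
Supported lidar input is height-normalized delimited text
(x, y, z, intensity, class); ground classification and height normalization
are upstream concerns.

## Outlier filtering and the random forest

Two filters remove plots whose lidar canopy and field estimate cannot both
be right: (a) maximum return height > 10 m over a field biomass of zero, and
(b) field biomass < 50 Mg/ha under a > 30 m canopy. "Zero" means
< 1e-6 Mg/ha — an exact float comparison would silently stop matching if
density arithmetic ever changed. Filtering is idempotent and
order-independent.

The biomass model is a 500-tree random forest with mtry = 7. Fit statistics
(r², RMSE, %RMSE = 100·RMSE/mean observed) are **out-of-bag**: each plot is
predicted only by trees whose bootstrap sample excluded it, giving
leakage-free residuals from a single fit — the natural protocol when no
evaluation split is prescribed. The fit is seeded and reproducible.
Residual diagnostics stratify by canopy height classes {0–10, 10–25, 25–40,
40–55, > 55 m} and biomass classes {0–100, 100–200, 200–300, 300–400, > 400
Mg/ha}; empty classes are reported as absent, never as zero.

## County inference

The model-assisted estimator is implemented in its difference-estimator
form: `mu_MA = mean(map) − mean(predicted − observed)` over the plot sample,
with `SE = sqrt(sum((e − ē)²) / (n(n−1)))`. The variance is the
infinite-population form (no finite-population correction), conservative
when the sample is a non-trivial fraction of the pixel population. Percent
differences between families are reported relative to the second-named
family by default — the convention that makes "Jenkins is X% above CRM"
read naturally when CRM is the reference — with `reference = "first"` as the
switch. The significance flag uses |t| > 1.96 (normal approximation, 95%
confidence); `crit` accepts a t quantile for a degrees-of-freedom
refinement. The t test is applied to the model-assisted means, the less
optimistic of the two available choices. Class distributions conserve mass
exactly: per-class totals sum to the county total by construction, and the
tests assert it.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical structure* the pipeline assumes,
with defaults fixed at the study conditions:

* 179 plots stratified short (< 5 m) / medium (5–25 m) / tall (> 25 m) in
  proportions 0.25 / 0.40 / 0.35; BAF 2 m²/ha.
* Height–DBH truth: intercept 6 m, slope 0.55 m/cm, residual sd 5.85 m;
  with the lognormal diameter distribution used (meanlog log 30, sdlog
  0.55, truncated to 12.7–250 cm) this yields r² ≈ 0.8 on refit.
* Lidar clouds at 10.66 returns/m² over 15 m footprints: per-tree
  cone-surface sampling with Gaussian vertical jitter, one return pinned at
  each apex (so the cloud maximum tracks the tallest stem), plus near-ground
  background returns; cover rises with crown area as in real canopies.
* Contamination: 9 plots with zero biomass but a tall swapped-in canopy and
  4 low-biomass plots with a > 30 m swapped-in canopy — geolocation-error
  stand-ins implemented by swapping clouds between plots — so the two
  filters remove exactly 13 plots, 179 → 166. Natural plots are constructed
  so they cannot trigger either rule (tall stands carry at least 8 stems of
  ≥ 35 cm, putting them safely above 50 Mg/ha; medium canopies stay below
  30 m; short below 10 m), which makes the count deterministic across seeds.
* A county pixel population whose latent true biomass follows a right-skewed
  mixture (≈ 37% of forest area below 50 Mg/ha, a few percent above 400),
  with pixel metrics produced by the same cloud-to-metric pathway.

It does **not** emulate: radiometric intensity realism, terrain and slope
geometry, GPS error as a spatial process (contamination is injected at the
outcome level), species-environment sorting, or the imagery-based canopy
masking that produces the vegetation flags. Consequently, green tests
demonstrate the *estimators'* correctness and the pipeline's sensitivity
mechanics — not that any particular real county would show a 20% family
difference. The shipped coefficient fixtures are calibrated so the CRM runs
roughly 20% below the ln–ln families on typical stems, mirroring the
relationship repeatedly reported for US forests, but they remain
illustrative numbers.

## Numerical and testing choices

Problem sizes in the test suite are chosen to keep the full suite around
three minutes on one core while leaving comfortable statistical margins:
height-model recovery at n = 2000 trees (sampling sd of the RMSE ≈ 0.09 m,
asserted within ± 0.3 m of 5.85 m); estimator coverage over 200 Monte-Carlo
counties of 400 pixels with a fixed linear working model fit on an
independent training county (the difference estimator is design-unbiased
only for a fixed model; coverage is asserted in [0.91, 0.995], the upper
slack reflecting the omitted finite-population correction at n/N = 0.125);
the regression-to-the-mean sign pattern — mean residual positive in the
lowest biomass class, negative in the highest — over 10 generator seeds with
a 9-of-10 sign criterion. Randomized-coefficient property tests (CRM
additivity, the ln–ln scale law `AGB(c·d)/AGB(d) = c^b1`) run at 10⁴ cases.
All randomness in tests and in the acceptance script is seeded.

## Known limitations

* The ln–ln engines carry no ratio components, so component-level
  comparisons are only possible within the CRM.
* Cull/defect deduction, below-ground biomass and carbon conversion are out
  of scope.
* The percent-difference antisymmetry identity is
  `pct(A,B) = −pct(B,A) · (total_A / total_B)` under the second-named
  reference; mixing references across reports will not cancel.
* The variance of the model-assisted estimator reflects sample residual
  dispersion only; allometric parameter uncertainty is not propagated (the
  necessary covariances are generally unpublished), which is precisely why
  the family-sensitivity analysis exists.
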