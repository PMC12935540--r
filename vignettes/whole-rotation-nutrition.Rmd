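---
title: "Whole-rotation nutritional output: model, conversions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-rotation nutritional output: model, conversions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Whether diversifying cereal-dominated crop rotations sacrifices food
production is usually argued crop by crop. `rotanutri` takes the
whole-rotation view: every crop grown in a rotation contributes calories
and macronutrients (carbohydrates, proteins, fats) for human consumption,
and the right unit of comparison is the annual output of the *entire*
rotation per hectare, with crops weighted by the share of land each
occupies. The package turns long-term rotation-experiment yield tables
into such outputs, models them against crop functional richness and time,
and assesses how close the resulting macronutrient mix is to recommended
human diets.

Functional richness (FR) counts the functionally distinct crop types in a
rotation — annual cereals, annual legumes, annual broadleaves (root and
oil crops) and ley. Cereal-only systems are split into single-species
monocultures (FR 1M) and multi-species cereal rotations (FR 1C), because
rotating several cereals is a different agronomic proposition from
growing one forever.

## From yield to human-available nutrients

For an edible crop the food-balance conversion is

$$M_{n,c} = Y_c \, (1 - f_{H_2O,c})^{-1} \, \alpha_c \, f_{ref,c} \, \gamma_{n,c},$$

where $Y_c$ is the dry yield (kg ha$^{-1}$ yr$^{-1}$), $f_{H_2O,c}$ the
water fraction of the retail product (flour, raw beans, oil, sugar, ...),
$\alpha_c$ the crop-to-retail factor, $f_{ref,c}$ the edible fraction of
the retail product, and $\gamma_{n,c}$ the nutrient content per unit
retail product (Gcal kg$^{-1}$ for calories, kg kg$^{-1}$ for
macronutrients). The whole-rotation output is the area-weighted sum

$$O_n = \sum_c M_{n,c} \, F_{A,c}, \qquad F_{A,c} = \frac{\text{years of } c}{\text{rotation length}},$$

so a four-year rotation behaves like a 1-ha farm with a quarter hectare
under each phase. Fallow years keep their weight and contribute zero.

Forage crops (ley, ryegrass, forage rape, silage maize) reach human
nutrition only through an end use. Three scenarios are supported: dairy
(1.05 l whole milk per kg dry-matter intake), beef (0.047 kg boneless
meat per kg DM) and biofuel (no food output). Dry-matter intake is taken
equal to the crop's dry yield; feed-out losses are not modelled. Crop
residues are never credited back to feed, which penalizes rotations with
oilseed crops in the beef and biofuel scenarios. Crops grown for forage
in some rotations and food in others (maize, notably) are disambiguated
by a per-rotation-year `use` column in the rotation catalog.

The conversion catalog shipped in `inst/extdata/` carries factor values
assembled from public food-composition sources. They are replaceable
defaults, not authoritative constants: any serious application should
substitute its own catalog, which is why every numerical test in the
package uses test-local fixtures instead of the shipped file.

One dimensional note: energy densities of macronutrients (Atwater
factors) are applied as 4 kcal g$^{-1}$ for carbohydrate and protein and
9 kcal g$^{-1}$ for fat when computing dietary calorie shares. Shares are
invariant to the mass unit as long as it is consistent, so this choice
affects nothing but the units discussion.

## Quality control of yield records

Raw yield tables contain missing records, unexplained zeros and
implausible values. The QC chain:

1. converts reported yields to dry weight via the record's water content;
2. flags missing records, explained zeros (fallow, annotated frost
   damage) and unexplained zeros;
3. screens each site × crop pool (all years, rotations and groups
   together) against the closed interval $[Q_1 - 2\,\mathrm{IQR},
   Q_3 + 2\,\mathrm{IQR}]$, flagging values strictly outside it;
4. replaces each missing / implausible / unexplained-zero value with the
   mean of donor records sharing crop, site, calendar year and rotation
   in other groups (same treatment when a `treatment` column is present);
5. excludes the whole site × year × rotation × group cell when a record
   has no donors, and reports every exclusion.

Numerical conventions worth stating: quartiles use linear interpolation
(`type = 7`), configurable because flags can differ between conventions
at small group sizes; bounds are closed, so a value exactly on a bound is
kept; zeros are never treated as outliers (they have their own flags);
site × crop pools with fewer than four usable values are skipped with a
warning. Gap filling is idempotent and the original flag of every filled
record is retained in `qc_flag_orig`. Two sensitivity switches —
`keep_unexplained_zeros` and `do_gap_fill = FALSE` — reproduce the
robustness variants of the analysis; with gap filling off, reported
values stand as they are and only truly missing records force cell
exclusion.

## The mixed model

Outputs are analysed per nutrient (four separate models) on the square
root scale:

$$\sqrt{O_n} = \beta_0 + \beta_t t_s + \beta_{t^2} t_s^2
  + \sum_i \beta_{FR_i} FR_i + \sum_i \beta_{FR_i t} FR_i\,t_s
  + \sum_i \beta_{FR_i t^2} FR_i\,t_s^2
  + b_{site} + b_{group(site)} + b_{year} + \varepsilon,$$

with FR 1M as reference. Random intercepts: site (pedoclimatic
potential), group nested in site (replicates crossed with non-rotation
treatments), and calendar year as a categorical factor crossed with the
site structure. Calendar year absorbs year-specific growing conditions
while time since the start of the experiment stays continuous, so
long-run trends and weather anomalies are separated. Fits are REML via
`lmerTest::lmer` with the bobyqa optimizer; marginal convergence warnings
are recorded in the fitted object rather than escalated, but a fit that
fails outright is an error, as is any negative output (the square root
must exist). Variance components estimated at zero are reported as
singular fits, mirroring standard mixed-model software.

**Time scaling.** Time since start is divided by the dataset's maximum
before fitting, so $t_s \in [0, 1]$ and time coefficients are "per full
observed span". The divisor is stored in the fitted object and echoed in
every serialization. This is the most consequential free choice in the
reconstruction: coefficient values are not comparable across datasets —
or against any externally published coefficient table — without knowing
the scaling, which is why the package's checks rest on back-transformed
predictions and their arithmetic relations rather than on raw
coefficients.

Predictions square the fixed linear predictor; 5–95% intervals are
formed on the sqrt scale from the coefficient covariance, by default
widened by the sum of the random-intercept variances ("including the
random component"; `include_random = FALSE` gives the fixed-only
alternative, `include_residual = TRUE` a prediction interval for a single
new observation), and the clamped endpoints are squared — squaring is
monotone for non-negative bounds, so interval ordering survives the back
transform. Contrasts across FR at fixed times, and across time within an
FR level, are computed with Satterthwaite degrees of freedom and adjusted
for multiplicity over the family with the equicoordinate multivariate
*t* distribution (`emmeans`, `adjust = "mvt"`); the Monte-Carlo
integration behind the multivariate *t* is seeded, making adjusted *p*
values reproducible to within integration tolerance. Marginal and
conditional $R^2$ are the variance-partition kind: fixed-effect variance
over total for the marginal, fixed plus random over total for the
conditional.

## The synthetic experiment generator

Real long-term experiments cannot be shipped, so the package carries a
generator whose defaults emulate the study conditions it was designed
for: 16 sites observed 11–53 years with staggered start years, rotations
covering FR 1M/1C/2/3 (ley in the FR 3 rotations, one fallow year in
one rotation), six treatment × replicate groups per site, 2.28% missing
records and 0.92% unexplained zeros injected completely at random (no
missingness mechanism is modelled, since none is known).

The generating model is deliberately the analysis model. For each cell
(site × year × rotation × group) a latent value is drawn on the sqrt
scale of the cell's area-weighted total dry yield: the rotation's
deterministic baseline $\sqrt{\bar O_r}$ (area-weighted crop baselines
times a multiplicative FR effect), plus per-FR linear and quadratic
trends in scaled time, plus site, calendar-year and group intercepts and
a residual, all Gaussian. The cell total is the squared positive part of
this latent value, and every crop yield in the cell is scaled
proportionally to reproduce it exactly. Consequences:

- random effects are shared by all crops of a cell — a good year lifts
  the whole rotation, which is what the model's crossed year effect
  assumes;
- the multiplicative FR yield effect maps to the sqrt scale as
  $\sqrt{\bar O_{FR}} - \sqrt{\bar O_{1M}}$ (`true_params()` performs the
  mapping, warning when rotations within an FR level differ in baseline
  so no single truth exists);
- with a unit conversion catalog (`dry_matter_catalog()`), the fitted
  response *is* the latent variable, so parameter-recovery and
  interval-coverage tests are exactly calibrated rather than
  approximately so;
- truncation at zero is the one deviation from Gaussianity; with
  realistic baselines it is vanishingly rare, and yields are never
  negative.

What the generator does not emulate: weather-driven yield physiology,
spatial plot layout, autocorrelated year effects, crop-specific
year × site interactions, and any real-data missingness mechanism. A
green recovery suite therefore certifies the statistical machinery, not
the agronomic realism of any particular dataset.

Noise is Gaussian on the sqrt-yield scale by construction; the field
offers no distributional consensus for yields, and this choice is ours,
made so that the analysis model is exactly correct for the simulated
data.

## Classification conventions

Functional richness counts distinct types among non-fallow rotation
years. A rotation containing one cereal species plus fallow classifies as
1M — fallow is land use, not a crop type — and such cases carry a
`has_fallow` flag so downstream reports can surface them. Ley mixtures
are one catalog entry of type ley regardless of botanical composition;
species identity is taken at the catalog-name level, ignoring cultivars.
Every retained rotation must contain at least one cereal year; violating
that is an error, not a warning, because it breaks the population the
analysis is defined over.

## Problem sizes used by the test suite

Parameter recovery runs 100 replicates of 30 sites × 30 years (7,200
outputs per replicate), checking that 95% Wald intervals cover the truth
at the nominal rate within five points and that mean variance-component
estimates land within 10% of the generating values. Contrast calibration
fits 200 small null experiments (two identically distributed rotations
labelled as different FR levels) and requires raw *p* values compatible
with uniformity (Kolmogorov–Smirnov) and a family-of-one multivariate-*t*
adjustment that is the identity. Interval coverage pools six replicates
of a 10-site × 12-year design against fresh data from the same
configuration. These sizes were chosen as the smallest that make the
calibration checks statistically meaningful.

## Known limitations

- Conversion factors are treated as constants — independent of location,
  rotation position, time and management — which likely understates
  protein at high FR (legume and oilseed residues feed nitrogen to the
  following cereal).
- Micronutrients, metabolizable-energy feed accounting and herd dynamics
  are out of scope; so are cover crops and intercropping of annuals.
- The outlier screen produces candidates; it cannot reproduce
  case-by-case expert judgement, so by default every flagged value is
  treated as missing and gap-filled.
- Back-transformed predictions are conditional on average random effects;
  "including the random component" widens intervals but the point
  prediction stays the square of the fixed predictor. Both interval modes
  are exposed because the published practice this follows is ambiguous on
  the point.
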