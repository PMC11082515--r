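# heartwoodkit

Tools for analysing **heartwood formation** in trees from stem-disc
measurements: when does a stem start converting sapwood to heartwood, how
fast does heartwood accumulate, and how much of that accumulation is driven
by ageing versus by the tree's hydraulic architecture?

The package is written for ecophysiologists and forest scientists working
with destructively sampled stem discs (cross-sections cut at several heights
along the trunk and at branch bases), together with xylem-anatomy
(vessel) measurements, leaf samples and stomatal counts. It implements the
complete analysis chain for a two-cohort contrast — slower-growing shaded
trees versus faster-growing sun-exposed trees — and ships a seeded
synthetic-data generator that emulates such a study design end to end, so
every statistical procedure can be exercised and calibrated against known
truths.

## What it computes

**Derived traits** (per disc / per tree). Quadratic-mean stem and heartwood
radii from 8-direction calliper measurements; sapwood width and area by
difference; the hydraulically weighted vessel diameter for elliptical
conduits,

    D_H = [ (1/n) * sum 2 a_i^3 b_i^3 / (a_i^2 + b_i^2) ]^(1/4),

which reduces to the classical fourth-power-mean diameter for circular
vessels; vessel lumen fraction F_V, total conductive vessel area
TCVA = A_V · N_V · SWa; per-disc growth rate GR = D / cambial age; and the
anatomical maximum stomatal conductance G_max from stomatal density and
size.

**Heartwood onset** (`fit_occurrence`, `onset_threshold`). The probability
of heartwood presence is modelled as P = logistic(a + b·ln x [+ c·z]) with
x the stem diameter or cambial age and z an optional site indicator or ln
growth rate. The size/age threshold of onset is the inflection point
x₀.₅ = exp(−(a + c·z)/b), with delta-method or bootstrap intervals, and
covariate effects are tested by likelihood ratio.

**Heartwood dynamics** (`fit_family`, `select_model`, `group_lrt`,
`first_ring_age`). Four candidate models — linear, quadratic, power
y = a·x^b, and the three-parameter asymptotic exponential
y = a0 + (a1 − a0)·exp(−a2·x) — are fitted by (nonlinear) least squares and
ranked by residual standard error; cohort differences are tested with a
Gaussian likelihood-ratio test, and the age at which the first ring is
converted to heartwood is the x-intercept of the ring-count regression.

**Allometry and tapering** (`sma_fit`, `common_slope_test`,
`conduit_taper`). Standardized major axis regression on ln-transformed
variables (slope = sign(r)·sd(y)/sd(x)), slope confidence intervals, a
likelihood-ratio common-slope test across cohorts with a permutation
reference, and tree-level conduit-tapering indices.

**Drivers** (`fit_path`, `wald_contrast`). A recursive path model separates
the **direct** effects of stem age and a hydraulic variable (TCVA at the
trunk, total leaf area at branches) on heartwood/sapwood area from their
**indirect** effects through stem diameter; effects are standardized, with
delta-method standard errors propagated through the sampling distribution
of the covariance matrix, and contrasts between effects are Wald
chi-square tests.

**Pipeline** (`run_pipeline`). One seeded call runs
simulate → derive → onset → dynamics → SMA → path models → cohort report
and returns frozen-schema result tables plus a manifest that fully
determines every number.

## Worked example

```r
library(heartwoodkit)

# hydraulically weighted diameter of two elliptical vessels (um)
hydraulic_diameter(a = c(120, 95), b = c(80, 90))
#> [1] 94.28715

# the full study pipeline on the default two-cohort design
bundle <- run_pipeline(run_config(seed = 1))
bundle$onset[, c("model", "evaluated_at", "threshold", "ci_low", "ci_high", "scale")]
#>          model            evaluated_at threshold ci_low ci_high scale
#> 1         logD                     all      3.64   3.14    4.22    cm
#> 2       logAge                     all     15.77  14.91   16.67 years
#> 3    logD+site                  site=0      2.04   1.72    2.43    cm
#> 4    logD+site                  site=1      5.49   4.84    6.23    cm
#> 5 logAge+logGR gr<=0.55 (median 0.319)     15.09  14.19   16.05 years
#> 6 logAge+logGR  gr>0.55 (median 1.070)     12.41  10.84   14.21 years
```

Reading the threshold table: heartwood appears above ~3.6 cm diameter
overall; sun-exposed stems (site = 1) need a *larger* diameter (5.5 cm vs
2.0 cm) but, per the growth-rate model, a *younger* age (12.4 yr vs 15.1 yr
at the class-median growth rates) — faster growers start forming heartwood
earlier in life but at a bigger size. The bundle also prints the qualitative
sign pattern of the cohort contrast:

```r
bundle$qualitative
#>                                   check pass
#> 1     earlier_age_threshold_fast_growers TRUE
#> 2 larger_diameter_threshold_fast_growers TRUE
#> 3                higher_ring_rate_shaded TRUE
#> 4           steeper_hwa_age_power_shaded TRUE
#> 5     positive_indirect_age_both_cohorts TRUE
#> 6           direct_hydraulic_only_shaded TRUE
```

`bundle$ring` holds the cohort ring-conversion rates (here 1.04 and 0.96
rings yr⁻¹) and first-heartwood-ring ages (15.2 and 11.3 yr);
`bundle$path_effects` holds the standardized direct/indirect effect table.

## Vignette

`vignettes/heartwood-analysis.Rmd` documents the statistical models and
their assumptions, the generator's design (what it emulates and what it
does not), all numerical choices, and known limitations.
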