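---
title: "Consolidating the global carbon budget: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating the global carbon budget: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonledger)
```

## The accounting problem

Mass conservation ties the five components of the global carbon budget
together: fossil and industry emissions (E_FOS) plus net land-use-change
emissions (E_LUC) must equal the uptake by the land and ocean sinks
(S_LAND, S_OCEAN) plus the growth of the atmospheric burden (G_ATM), all in
GtC/yr. The residual

B_IM = E_FOS + E_LUC − S_LAND − S_OCEAN − G_ATM

is the budget imbalance; with perfect estimates it is zero. Persistent
non-zero imbalance — and especially a *trend* in the imbalance — signals
systematic bias in one or more components and blocks any confident reading
of how the sinks are evolving. `carbonledger` implements a set of
process-motivated corrections that close the budget, together with the
uncertainty calibrations that go with them, and a synthetic-ensemble
generator that lets every stage be tested against known truth.

Sign conventions are fixed throughout: sinks positive, sources positive,
atmospheric growth positive; every correction is a signed addition to the
stored component value. A missing 1-sigma is stored as `NA`, never as zero.
Reported tables round half-up to one decimal in GtC/yr; all internal
computation is at full precision.

## The four flux corrections

**Transient carbon densities (delta-L, on E_LUC).** Bookkeeping models of
land-use emissions traditionally assign each land-cover type a static
equilibrium carbon density. Because rising CO2 has been raising biomass and
soil carbon, clearing a present-day forest releases more carbon than the
static density implies, so static-density E_LUC is biased low. Models that
ran with both density modes define, per emission subcomponent
(deforestation, regrowth, wood-harvest sources and sinks, other
transitions) and year, the ratio transient/static; these ratios — averaged
across the reference models — rescale the subcomponents of models that only
ran statically, and the rescaled subcomponents are summed back into net
E_LUC (`eluc_component_ratios()`, `eluc_apply_scaling()`). Where a static
subcomponent is essentially zero (|flux| < 1e-6 GtC/yr) the ratio carries
no information and defaults to 1. Ratios are formed and applied per year;
the "average" in the procedure is across reference models, which is the
reading we adopt. The per-model corrections combine in `delta_L()` with an
unweighted cross-model mean and a random-effects uncertainty: the
DerSimonian–Laird between-model variance tau^2 plus the mean within-model
variance, sigma = sqrt(tau^2 + mean(sigma_i^2)). DerSimonian–Laird is the
standard non-iterative random-effects estimator, and adding the mean
within-model variance keeps the reported sigma at least as large as either
uncertainty source alone. Models whose transient densities are endogenous
enter as precomputed (transient − static) series.

**Replaced sinks and sources (RSS, on S_LAND).** The land sink is assessed
from vegetation-model simulations run under fixed pre-industrial land cover
(S2), which keeps direct land-use fluxes out of S_LAND but leaves roughly
20% too much forest on the map; since forests out-absorb the systems that
replaced them, S2 overestimates the sink. The correction recombines the S2
per-PFT flux densities with the transient cover fractions of the land-use
run (S3): S_corr(t) = sum over cells and PFTs of density_S2 × fraction_S3 ×
area (`reconstruct_sland()`), and the bias is S2 − S_corr
(`rss_bias()`). PFT-level net biome production is interpreted as flux per
unit PFT area, which is what makes the recombination dimensionally
meaningful; residual bare fraction carries zero flux; per-PFT soil and
litter pools are assumed embedded in the PFT-level flux. Anthropogenic PFTs
absent from the S2 flux set are handled in two modes — `"proxy"`
(cover-weighted mean density of the PFTs present, the default, which avoids
silently dropping area) and `"exclude"` — because the matching rule for
newly created cover types is genuinely underdetermined; neither mode is
asserted as canonical. Ensemble aggregation is an unweighted mean with the
inter-model (n−1) standard deviation (`aggregate_rss()`).

**Lateral carbon export (LCE, on S_LAND).** Human activity has increased
the flux of carbon washed from land into inland waters (F'_LI), which is
partitioned downstream into added aquatic CO2 evasion (F'_IA), aquatic
sediment burial (F'_IS) and export to the open ocean (F'_IE), and by origin
into displaced dissolved soil CO2 versus terrestrial organic carbon. Both
partitions must conserve carbon (`validate_partition()`, default tolerance
0.005 GtC/yr, i.e. printed rounding). Only organic carbon that is
decomposed and evaded in inland waters is a genuine loss of land uptake, so
the land-sink reduction is organic_share − F'_IS − F'_IE
(`sland_lce_correction()`); the dissolved share merely moves the outgassing
point. No ocean-sink correction is ever produced: exported carbon is
assumed to stay stored in the ocean. The assessed numbers describe only the
recent decade, so the historical shape is a configurable per-year ramp in
[0, 1]; the default is linear from 0 at the start of the record to 1 at its
end — the minimal assumption for a perturbation defined as
"recent-decade minus pre-industrial". The correction sigma (0.06 GtC/yr) is
carried as assessed, not re-derived.

**Ocean-sink biases (on S_OCEAN).** Ocean biogeochemical models
underestimate the sink by about 10% (weak simulated overturning, spin-up
shortfalls, interior-ocean constraints), applied here as a multiplicative
scaling of the model stream (`scale_gobm()`). Observation-based fCO2
products miss the temperature gradient across the sub-millimetre surface
skin: a cool-skin effect of 0.42 GtC/yr (strengthening uptake) partly
offset by a 0.24 GtC/yr warm-layer measurement-depth effect, a net additive
+0.18 GtC/yr (`skin_adjust()`). Whether the 10% applies to annual fluxes or
only to the decadal mean is not specified by the assessment; we scale
annual values, which reproduces the printed decadal numbers. Both
uncertainties are calibrated from stated sign confidences: if a correction
c > 0 is positive with probability p, the implied Gaussian sigma solves
P(N(c, sigma) > 0) = p, i.e. Z = qnorm(1 − p) and sigma = c/|Z|
(`confidence_sigma()`; 90% gives Z = −1.28 and sigma ≈ 8% of the scaling,
66% gives sigma ≈ 0.44 ≈ 0.4 GtC/yr). R's `qnorm` is accurate to well below
1e-8, tighter than any tolerance used here. The assessed sink is the
unweighted mean of the two corrected streams; the combined correction
carries sigma = ½·sqrt(sigma_gobm^2 + sigma_fco2^2). That half-quadrature
rule is our choice — the assessment states no propagation rule — justified
both because it is the exact variance of an average of two independent
streams and because it reproduces the printed combined uncertainty
(±0.23 from ±0.21 and ±0.4). The skin adjustment is applied as
time-constant; only a single-period estimate exists.

## Conversion factor and the G_ATM uncertainty band

The observed atmospheric growth rate is measured in ppm/yr and converted to
mass with a constant 2.124 GtC/ppm. Atmospheric-inversion ensembles let the
factor be estimated rather than assumed: each member's net annual input of
CO2 (fossil emissions plus inverse-derived net land and ocean fluxes)
divided by that member's own annual growth rate is a per-year conversion
factor (`member_conversion_factor()`). Growth rates come from monthly
station-sampled mole fractions: we regress the series on a linear trend
plus the first two annual harmonics, subtract the fitted seasonal terms,
interpolate the deseasonalised series linearly to 1-January boundaries and
difference consecutive boundaries (`annual_growth_ppm()`). This is an
approximation to the observatory-style curve-fitting procedures; it is
exact for linear-plus-sinusoidal records and recovers stepwise growth to
better than 0.01 ppm/yr when samples fall on month boundaries. Years with
|growth| below 0.05 ppm/yr give unstable ratios and are flagged and
excluded from ensemble statistics. Three uncertainty sources propagate to
G_ATM: the annual observation uncertainty of the growth rate, the
interannual variability of the factor over the analysis window (2001–2023,
the period most inversions cover), and the mean ensemble spread; we combine
them as *relative* errors in quadrature times G_ATM — the assessment says
"propagate" without a formula, quadrature is the convention used elsewhere
in this accounting, and the relative scale keeps the band proportional to
the growth itself. G_ATM's central value is never adjusted; only its sigma
band is produced, and years with |B_IM| inside k·sigma (default k = 1) are
flagged non-significant (`bim_band()`).

## Climate-change attribution

Paired historical simulations — one with observed CO2 and climate, one with
the same CO2 but constant early-period climate — isolate the climate effect
on each sink (`climate_effect()`). We store the effect as *positive
weakening* (fixed-climate minus full run), so the atmospheric contribution
G_ATM_clim = AF × (S_LAND_clim + S_OCEAN_clim) comes out positive; display
layers negate it where a negative-flux convention is wanted. The airborne
fraction AF is not given a unique definition in the literature; we default
to the annual ratio G_ATM/(E_FOS + E_LUC) and expose a cumulative mode and
a constant-AF option (`airborne_fraction()`, `gatm_clim()`). Because the AF
definition and accumulation convention are open, the cumulative ppm
contribution is treated as a consistency quantity rather than an exact
target. Percentage reductions are quoted against the no-climate-change
counterfactual, 100 × effect/(sink + effect). Regional decompositions
(CO2-fertilisation sink, climate source, land-use source) form net = co2 −
climate − luc with a quadrature sigma (`regional_decomposition()`).

## The synthetic world

`simulate_world()` generates every input the pipeline needs with known
truth and exact internal mass balance; it is first-class, tested code, not
a fixture. Design choices, made once:

* **Truth trajectories.** E_FOS grows exponentially at 2.8%/yr anchored to
  a 9.7 GtC/yr 2014–2023 mean; S_LAND and S_OCEAN scale sublinearly with
  it (exponents 0.8 and 0.9) anchored to 2.7 and 3.1; E_LUC is flat at
  1.2; G_ATM closes the budget identically, so truth closure is exact by
  construction. These anchors are the consolidated decadal means; the
  shapes are generic emission-driven growth, not a claim about history.
* **Interannual variability.** AR(1) with phi = 0.5 and innovation sigmas
  largest on land (0.40 GtC/yr; ocean 0.12, fossil 0.05, land-use 0.10),
  mimicking ENSO-scale variability. These are configuration defaults, not
  assessed values.
* **Bias knobs.** Bookkeeping nets run low by a delta-L trajectory,
  carried entirely by the deforestation subcomponent so reference ratios
  recover it; fixed-cover land-sink members run high by an RSS trajectory
  realised as per-member PFT worlds whose closed-form bias is exact; fCO2
  members run low by a constant skin deficit; ocean models low by the
  multiplicative fraction; paired constant-climate runs add a known
  weakening. Growth-shaped biases rise linearly from the first year and
  are normalised so their 2014–2023 mean equals the knob; the
  lateral-export excess is injected exactly as correction × linear ramp so
  the standard correction closes it. CO2 for the transient-density toy
  model follows an exponential anchored at 316 ppm (1960) and 423 ppm
  (2024) over a 277 ppm base.
* **PFT worlds.** Three cover types (forest/grass/crop) on a handful of
  explicit-area cells; densities are base values plus a common per-year
  offset chosen so the fixed-cover global sum reproduces the member's
  sink series exactly — the additive form stays well defined even in
  weak-sink years — and the forest-to-crop conversion fraction delivers
  the requested bias in closed form.
* **Reproducibility.** One master seed; each ensemble draws from its own
  deterministic sub-stream, so changing one knob never reshuffles the
  noise of unrelated ensembles. Same seed, byte-identical CSV output
  (written at 17 significant digits).
* **Mole fractions.** Monthly samples stamped on the first of each month,
  with a fixed two-harmonic seasonal cycle and per-member offsets; the
  shared decimal-year convention maps 1 January exactly to the year
  boundary, so boundary values are interpolation nodes.

What the generator does *not* emulate: geography, seasonality in fluxes,
process-based land or ocean physics, transport, station-network design.
Passing tests therefore demonstrate that the accounting machinery is
unbiased and exact under its stated assumptions — not that the corrections
are right for the real Earth, which is a matter of the underlying process
studies.

## What the package computes at desk scale

```{r desk}
revised <- budget_table(
  flux_series("E_FOS", 2014:2023, 9.7, 0.5),
  flux_series("E_LUC", 2014:2023, 1.2, 0.7),
  flux_series("S_LAND", 2014:2023, 2.7, 0.9),
  flux_series("S_OCEAN", 2014:2023, 3.1, 0.5),
  flux_series("G_ATM", 2014:2023, 5.2, 0.02)
)
decadal_mean(budget_imbalance(revised), 2014, 2023)

scale_gobm(flux_series("S_OCEAN", 2014:2023, 2.6, 0.4))$correction$value[1]
sland_lce_correction(lateral_flux_perturbation())
confidence_sigma(0.10, 0.90)
```

## Numerical choices and degenerate inputs

* Quadrature is used for every combination of independent 1-sigma values.
* Decadal sigma is the mean of annual sigmas, not sigma/sqrt(n): these
  uncertainties are dominated by systematic error shared across years, and
  the assessed decadal sigmas are of the same size as annual ones.
* Trend tests are plain OLS with an iid-error two-sided t-test and no
  autocorrelation correction, matching how imbalance trends are
  conventionally quoted; the suite verifies the test holds its nominal
  size on white-noise nulls.
* Zero static subcomponents, single-member ensembles, years with fewer
  than two inversion members, and near-zero growth years all have explicit
  fallback-or-flag behaviour rather than silent NaN propagation.
* Half-up rounding is used for display only.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on generated data:
64-year worlds (1960–2023), ensembles of 4 bookkeeping / 7 vegetation / 10
ocean-model / 10 fCO2 / 14 inversion members, PFT grids of 4 cells × 3
cover types, 100-seed Monte Carlo for the end-to-end bias-recovery check,
2000 replicates for the trend-test size check, and 600–1000 replicates for
estimator-calibration checks. These sizes give Monte-Carlo standard errors
comfortably below the tolerances being asserted.

## Known limitations

* The historical shapes of the delta-L, RSS and lateral-export
  perturbations are not observable from the assessed decadal numbers; the
  linear ramps are assumptions, and cumulative quantities inherit them.
* The growth-rate algorithm is a documented approximation to the
  observatory procedures; with real (gappy, unevenly sampled) records its
  boundary interpolation would need the full curve-fitting treatment.
* The random-effects sigma rule (DL tau^2 plus mean within-variance) is
  one defensible reading of an under-specified procedure; alternatives
  (e.g. the DL standard error of the pooled mean) would give smaller
  sigmas.
* The airborne-fraction definition is configurable precisely because the
  cumulative ppm attribution depends on it; headline ppm numbers should be
  read with that sensitivity in mind.
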