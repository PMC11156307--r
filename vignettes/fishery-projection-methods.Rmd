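---
title: "Methods: climate-scenario projection of fishery abundance and bioeconomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-scenario projection of fishery abundance and bioeconomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishcast)
```

## The projection chain

`fishcast` projects species abundance and fishery bioeconomics under
contrasting climate scenarios through five coupled stages:

1. **Environmental baseline and scenarios.** Six layers on a fine
   (default 0.25°) cell-center registered lon/lat grid: winter sea
   surface temperature (WSST, °C), winter sea ice concentration (WSIC,
   %), winter and summer sea bottom temperature (WSBT/SSBT, °C), summer
   net primary production (SNPP, mg C m⁻² d⁻¹), and static depth (m).
   Scenario projections arrive on a coarser grid (default 1°) as a small
   ensemble of model members. Winter is January–April and summer
   June–August; seasonal means are plain per-cell arithmetic means with
   mask propagation (cells averaged over an incomplete season are
   flagged, not dropped).

2. **Delta-method downscaling.** For each variable, scenario and period
   the cross-member mean anomaly (future − historical) is formed on the
   coarse grid, resampled to the fine grid, and added to the fine
   present-day layer. Anchoring projections to the observed baseline
   removes each model's mean bias but assumes the anomaly field itself
   is transferable across resolutions.

3. **Abundance models.** Per species, survey CPUE (kg km⁻²) is regressed
   on the six covariates with a random forest and a boosted-trees model;
   the ensemble prediction is their inverse-RMSE weighted average.
   Present-day predictions and future projections are evaluated on the
   (downscaled) environmental stacks.

4. **Bioeconomics.** Predicted density surfaces are integrated to
   regional biomass `B` (mt) and pushed through the Pella–Tomlinson
   surplus-production chain: MSY, maximum catch potential
   `MCP = B·U_MSY`, revenue `R = p·MCP`, the open-access cost parameter
   `c`, profit at MSY `π = R − c·g^β`, and the fleet sums MRP and MPP.
   Present-day biomass is assumed to be at carrying capacity, and all
   reference parameters are held constant over time, so projected
   bioeconomic change is driven solely by projected abundance change.

5. **Spatial summaries.** Biomass-weighted centers of gravity (COG) and
   decadal shift rates, percent changes relative to present, 100-km
   port-ring MCP profiles, and fishing-ground comparisons across
   jurisdictions.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| fine / coarse resolution | 0.25° / 1° | degrees | observational vs scenario-model grids; fine must divide coarse |
| ensemble members | 4 | — | small multi-model ensemble; the anomaly uses the cross-member mean |
| train fraction | 0.8 | — | 80/20 split, stratified by year so every survey year trains the model |
| CV folds (tuning) | 5 | — | cross-validation inside the training split only, avoiding holdout leakage |
| RF grid | mtry {2,3,5} × node size {5,10} × trees {200,500} | — | compact default; any user grid (thousands of points) is evaluated exhaustively |
| BRT grid | rate {0.05,0.1} × depth {2,3} × trees {100,300} | — | same |
| CPUE noise σ | 0.3 | log scale | lognormal dispersion typical of trawl-survey skew |
| cold-pool threshold | ≤ 2 | °C | configurable comparator (`lte`/`lt`) |
| cost exponent β | 1.3 | — | cost per unit effort increases with each added unit (β > 1) |
| yield-curve shape φ | 0.188 / −0.093 | — | fixes B_MSY/K at 0.40 (groundfish) / 0.35 (crab) |
| sensitivity ramp | +20 % at 2100 | — | linear from 2019; period midpoints 2030.5/2050.5/2070.5/2090.5 |
| effort threshold | 1000 | hours | defines present-day fishing grounds |
| ring width | 100 | km | port-buffer averaging distance |

Time windows are fixed: present 2000–2019 (midpoint 2009.5), coarse
historical reference 2000–2014, futures 2021–2040 through 2081–2100 in
20-year steps.

## The synthetic study system

The generator (`synth_config()`, `generate_environment()`,
`sample_surveys()`, `generate_reference_params()`,
`generate_geography()`) emulates the statistical design of a
high-latitude shelf study, not its geography. Defaults: a 12° × 11°
domain, colder and icier to the north, NPP peaking mid-basin, depth
increasing offshore, an eastern land margin; four scenarios whose
end-of-century basin SSBT warming amplitudes are 1.0, 2.0, 3.5 and
5.0 °C (within the range ocean models span for severe forcing on
subarctic shelves), with winter ice declining 20–75 % and NPP 5–20 %.
Trends scale across periods with the period-midpoint fraction of the
2009.5→2090.5 interval, so the final window carries exactly the
configured amplitude.

Design choices worth knowing:

* **Member texture.** Each pseudo-model member owns a fixed smooth
  spatial texture shared between its historical and future layers (its
  "model identity"). Future = historical + trend, so a zero-amplitude
  scenario reproduces the historical stack bit-exactly and the
  cross-member anomaly is exact — which is what makes the downscaling
  identity tests sharp rather than approximate.
* **Niches.** Species respond to SSBT, depth and SNPP through
  independent Gaussian kernels; expected CPUE equals maximum density at
  the multivariate optimum. Temperature optima spread from cold to warm
  across species; species with optima below the basin midpoint are
  flagged cold-optimum. WSST, WSIC and WSBT influence nothing directly —
  they enter the models only as correlated covariates, as in real data.
* **Survey noise.** The CPUE error structure is not something surveys
  report; we chose multiplicative lognormal noise with a mean-one
  correction (`meanlog = −σ²/2`), keeping CPUE nonnegative, right-skewed
  and unbiased around the niche expectation. At σ = 0 observations equal
  the expectation exactly, which the closed-form kernel tests exploit.
* **Effort field.** A Gaussian plume around the southern port, roughened
  lognormally and rescaled so that exactly the configured number of
  marine cells reaches the 1000-hour threshold — fishing-ground tests
  are therefore counting, not estimating.

What the generator does **not** emulate: real bathymetry or coastlines,
survey gear selectivity, species interactions, zero-inflation beyond
what the niche tails produce, spatially correlated survey placement, or
disagreement among ensemble members about the *trend* (members differ
only in texture). Passing tests therefore demonstrate that the chain is
implemented correctly and recovers known structure under its own
assumptions — not that those assumptions hold for any real survey.

## Numerical choices

* **Resampling kernel.** Bilinear on cell centers (nearest-neighbour
  available for categorical masks). Fine cells outside the outermost
  coarse centers receive clamped (constant-edge) extrapolation. Source
  land holes are filled with the basin mean before interpolating and
  re-masked afterwards, so coastal anomaly values are never NA-poisoned.
* **Clamping.** Applied after anomaly addition, per variable: WSIC to
  [0, 100] %, SNPP and depth to ≥ 0 — an additive anomaly can push
  bounded quantities out of range. Linearity of the downscaling
  operator holds before clamping.
* **Cell areas.** Spherical rectangles, `R²·Δφ·Δλ·cos(φ)` with
  R = 6371 km; all distances are haversine on the same sphere. These
  constants make every area- and distance-dependent output reproducible
  bit-for-bit.
* **Tuning tie-breaks.** Grid points tied on CV RMSE resolve toward the
  simpler model: fewer trees, then smaller complexity (mtry /
  interaction depth), then grid order. A degenerate response (constant
  CPUE) short-circuits to the simplest point with a warning.
* **Ensemble weights.** `w_m ∝ 1/RMSE_m`; a zero-RMSE member takes all
  weight; two zero-RMSE members split evenly. Weighted predictions are
  floored at zero.
* **Degenerate inputs.** Empty survey tables return the full schema;
  all-zero surfaces have no COG (error); zero present values make
  percent change undefined (NA with warning); empty fishing-ground
  masks report missing, never zero.
* **MSY exponent convention.** The yield relation is implemented as
  `MSY = g·B·(φ+1)^(1/φ)` (the `printed` convention, default) with a
  `bmsy_consistent` switch using `(φ+1)^(−1/φ)`. The two differ by the
  square of the B_MSY/K ratio, and the literature's typeset forms are
  ambiguous; rather than guess which was actually run we expose both
  and record the choice in the result's metadata. Fleet aggregates MCP,
  MRP and MPP are unaffected (they do not pass through MSY, only the
  cost parameter and profit do).
* **Cost-parameter grouping.** `c = p·f̄·b̄·MSY/(g·f̄)^β` is the unique
  grouping that yields exactly zero profit at the open-access
  equilibrium (catch `f̄·b̄·MSY`, mortality `g·f̄`); the identity is
  enforced to 1e-9 relative tolerance over 1,000 random draws.
* **COG weighting.** Density × cell area (true biomass weighting), not
  raw density — at high latitudes equal-density northern cells carry
  less biomass, and the centroid should say so.
* **Shift-rate time base.** Distances divide by midpoint-to-midpoint
  decades (2009.5 → 2030.5/2050.5/2070.5/2090.5); start-to-start is the
  main alternative and would scale rates by a constant per period.
* **Buffer rings.** Half-open `((k−1)·100, k·100]` km on cell centers;
  the port's own cell belongs to ring 1.

## Problem sizes used by the test suite

The suite builds everything it needs in code: unit tests run on toy
grids of ≤ 25 cells and a 6° × 5° synthetic domain (~480 marine cells,
40 stations yr⁻¹); the niche-recovery experiment uses the full default
domain with 2 species, σ = 0.1 and 2,000 stations per species; the
directional experiment runs five seeded replicates of the scenario
chain; the exhaustive-tuning smoke test evaluates a 2,700-point grid on
40 rows with 2 folds. These sizes were chosen so the full suite runs in
about a minute while every property is still exercised at scale.

## Known limitations

* **Extrapolation under severe forcing.** Tree ensembles predict
  constants outside the training hull. Under the mildest scenarios the
  fitted chain reproduces the designed poleward COG shifts; under the
  severest amplitude most of the basin's covariate combinations leave
  the hull, predicted surfaces flatten, and fitted-model COG shifts can
  understate (even reverse) the true niche displacement, while the true
  scenario chain itself remains strictly monotone in severity. This is
  the familiar SDM transferability problem, inherent to the method, and
  is why the directional acceptance property is defined on the scenario
  chain (generator → downscaling → niche response → COG) rather than on
  fitted-model projections.
* **No population dynamics.** Abundance is a static environmental
  response; there is no age/size structure, no density dependence beyond
  the carrying-capacity assumption, no species interactions, and
  reference parameters are frozen at their baseline values.
* **Constant economics.** Prices and costs are constant (2012 USD)
  apart from the linear ±20 % sensitivity ramps; no discounting, price
  formation or fleet-dynamics feedback.
* **Regular grids only.** All layers must be on regular lon/lat meshes;
  curvilinear ocean-model output must be regridded upstream.

## Session

```{r}
sessionInfo()
```
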