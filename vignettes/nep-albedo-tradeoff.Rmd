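---
title: "Methods: the NEP-albedo trade-off pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the NEP-albedo trade-off pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nepalbedo)
```

This vignette documents the scientific model behind `nepalbedo`, the
assumptions baked into each stage, the tunable parameters with their
defaults and units, and the design choices made where more than one
reasonable implementation existed. Nothing stated here goes beyond what
the package's tests and acceptance script themselves compute.

## The problem

Two properties of the land surface pull climate in opposite directions
when land use changes. Net ecosystem productivity (NEP, gC m⁻² yr⁻¹,
positive = CO₂ sink; the sign-flipped eddy-covariance flux NEE_VUT_REF)
removes carbon gradually, so its radiative effect is cumulative and
delayed. Surface albedo (α_s, dimensionless) changes the shortwave budget
instantly. Across flux-tower networks the two are negatively related, and
their *maxima* limit each other along a roughly hyperbolic envelope: no
observed ecosystem combines very high albedo with very high uptake. The
package quantifies this co-variability and asks what a network-wide
land-use permutation — every site moving to the state of a climate-matched
partner — would do to top-of-atmosphere (TOA) net radiation over a
century.

## Flux processing

**Stable-albedo windows.** Surface albedo is nearly piecewise-constant in
time (vegetation states, snow cover), which is what makes gap-filling of
SW_out possible without bias. `detect_stable_windows()` grows a window day
by day while each new day's daytime flux-ratio albedo stays within
`drift_tol` (default 0.03, absolute albedo) of the running window value;
on a break, the boundary is refined to the first deviating daytime
half-hour. Days with no daytime SW_out observation extend the current
window — absence of evidence is not a regime change. Records only count as
daytime above `swin_floor` (default 20 W m⁻²) to avoid dawn/dusk ratio
blow-up. Two consequences are tested as invariants: windows partition the
timeline exactly, and a change point aligned with a day boundary is
recovered to within one half-hour.

**Imputation.** A missing SW_out becomes `window albedo × SW_in` (exactly
zero at night). Because the window albedo is itself the flux-weighted
ratio of the window's observed pairs, imputation cannot shift the
interval albedo: with 30 % of SW_out removed at random, the annual albedo
error stays below 0.003 (tested over 20 generator seeds; observed errors
are of order 10⁻⁵).

**Snow and conditions.** A window is snow/hoar-frost-affected when its
albedo is at least `snow_albedo_min` (0.30) *and* its minimum half-hourly
air temperature is at most `snow_tmax` (0.5 °C). The albedo threshold
separates vegetation and most soils (α ≲ 0.25) from snow (α ≈ 0.4–0.8);
the temperature condition excludes bright warm surfaces (dry soils, sand).
Snow-free windows are *active* when their NEP is positive and *dormant*
otherwise (NEP = 0 counts as dormant). Snow takes precedence over both.

**Aggregation conventions.** Interval albedo is always `Σ SW_out / Σ
SW_in` — the flux-weighted albedo — never the arithmetic mean of
instantaneous ratios, which over-weights low-radiation periods (the two
agree only under constant SW_in). NEP totals use 1800 s per half-hour and
12.011 g mol⁻¹. Only full calendar years with all core variables
(SW_in, gap-filled SW_out, NEE) complete enter cross-site statistics, so
site means are not biased by partial seasons; sites missing long-term MAT
or MAP metadata fall back to the means of their own series. The
photosynthetic energy fraction is E_GPP = 0.469 J µmol⁻¹ × Σ GPP / Σ
(SW_in − SW_out), comparing energy fixed by gross photosynthesis to
absorbed shortwave radiation.

## Distribution analysis

`kde_tradeoff()` contrasts the bivariate kernel density of (α_s, NEP)
with the product of its marginals — the density the data would have if
the two variables were unrelated — and reports the difference surface.
Gaussian kernels; bandwidth per axis is Scott's rule for two dimensions,
`sd × n^(−1/6)`, used for the joint *and* the marginals so that the
product surface is the exact independence counterpart of the joint
estimate (a d = 1 bandwidth for the marginals would produce a spurious
nonzero difference for independent data). Grids have 256 points per axis
and extend past the data by 10 % of the range or four bandwidths,
whichever is larger, so all three densities integrate to 1 within 10⁻³ on
the grid and the difference integrates to 0 within 2 × 10⁻³. Rank
correlation is Spearman's ρ with average ranks for ties and a
large-sample two-sided p-value.

Two theoretical bounds accompany the monthly trade-off view. The
PAR-limited maximum assumes an available photosynthetically active
radiation flux of 100 W m⁻², of which the fraction (1 − α) is absorbed
and all of it fixed at 0.469 J µmol⁻¹, converted to gC m⁻² month⁻¹ with a
30.44-day month. (Whether "absorbed" should scale with (1 − α) or be a
fixed 100 W m⁻² is ambiguous; the package scales with (1 − α), which is
the stricter reading — the bound then falls to zero for a perfectly
reflective surface.) The combination envelope treats monthly (α, NEP)
states as freely combinable under constant SW_in: every attainable annual
value is then a convex combination of monthly points, so the attainable
set is their convex hull and the frontier is the hull's upper chain,
computed with a monotone-chain algorithm that treats near-collinear
vertices (within floating-point slack) as collinear, making the envelope
idempotent.

**Seasonal group statistics.** Within groups (IGBP classes,
species-dominated subsets versus mixed sites, and the forest contrasts
broadleaf/needleleaf and deciduous/evergreen), NEP is arithmetically
averaged across sites while albedo is the pooled ratio of summed SW_out
and SW_in. A condition (dormant, snow) contributing less than 10 % of a
site's total period is neglected for that site; Δ columns are then
computed against the active-season values *of the remaining sites only*,
so that a Δ never mixes baselines. Standard errors (sd/√n across sites)
appear only for groups with more than one site.

## Paired-site permutation scenarios

A candidate partner must match the focal site's climate: |ΔMAT| ≤ 1.5 °C
and relative differences of mean SW_in, MAP and snow-day count each
within 20 %. Relative differences use the focal site's value as the
denominator (directional matching; a site with zero snow days only
matches other zero-snow sites). Matching is therefore not guaranteed to
be symmetric, and the exhaustive reference oracle in the test suite
applies the identical rule.

Per site: SC1 adopts the partner with the highest multi-annual NEP
(including that partner's albedo); SC2 the partner with the highest
albedo; SC3 the partner maximising the balanced score x — the
displacement projected onto the diagonal of the range-normalised
(α, NEP) plane — accepting the least-bad trade-off when every candidate
scores negative (a switch `sc3_require_improvement` forces zero change
instead; default off, because a "balanced" policy plausibly still acts
when no strict joint improvement exists); SC4 combines SC1's NEP with
SC2's albedo. Sites whose partners offer no improvement keep zero deltas
but still count in ensemble averages; sites with no climate partner at
all are excluded from them. Ties break on the lexicographically smallest
partner id, which makes assignments invariant to input order.

## Radiative forcing over 100 years

**Carbon.** Each site runs a factual track (effective NEP ramping
linearly from old to new over the member's transition time — 0 or 30
years — with albedo ramping identically) and a business-as-usual
counterfactual (old NEP throughout). Both evolve a carbon stock from
14,498 gC m⁻² with net flux NEP_eff − harvest, hard-capped at the
member's maximum stock (50,000 or 100,000 gC m⁻²) above and 0 below; the
net flux shuts off while a cap binds in the flux direction (a saturated
ecosystem neither grows nor is harvested; a cap is escaped if the flux
direction reverses). The cap brackets any smooth saturation taper.
Harvest is 247 (low) to 335 (high) gC m⁻² yr⁻¹ for cropland, 0 to 100 %
of positive NEP for grassland, 0 to 61 gC m⁻² yr⁻¹ for forests and all
other classes; harvested carbon returns to the atmosphere in its harvest
year, since no storage pool is modelled. The same IGBP class (the site's
own) governs both tracks — whether a converted site should inherit its
partner's harvest regime is an open question and a known limitation. The
yearly atmospheric uptake perturbation is the factual-minus-counterfactual
net flux; a mass-balance identity (cumulative perturbation = stock-change
difference; per track, applied NEP − harvest = stock change) holds to
10⁻⁶ gC m⁻² and is asserted network-wide in the tests.

**CO₂ forcing.** The network-mean cumulative uptake, applied to 1 % of
the global land surface (1.489 × 10¹⁴ m²) and reduced by the airborne
fraction 0.44, converts to a mixing-ratio change via 2.124 × 10¹⁵ gC
ppm⁻¹ and to global forcing via RF = 5.35 ln((C₀ + ΔC)/C₀) W m⁻² with
C₀ = 420 ppm. The coefficient, conversion factor and areas are
literature constants exposed in `forcing_constants()` so the whole chain
is explicit and overridable.

**Albedo effect.** Because surface SW_in × Δα is not the TOA effect,
monthly albedo kernels stand in for SW_in. Kernel datasets are strongly
correlated with surface SW_in, with proportionality factors spanning
0.81–1.03; `synthetic_kernels()` builds k_m = −factor × SW_in,m at the
bounds of that range as the *weak* and *strong* ensemble members (a
measured kernel table can be supplied instead). A monthly sub-loop
(1/12 Σ_m k_m Δα_m) is used rather than annual products because Δα and k
co-vary seasonally — snow-season albedo changes coincide with low sun.
Monthly deltas in months without insolation are undefined and set to
zero change; their kernels are zero regardless. The per-site annual
effect is scaled by 0.01 × land/Earth area, ramped like NEP, and added to
the CO₂ forcing; ΔR < 0 is cooling. Tropospheric adjustments that
distinguish effective from instantaneous forcing are deliberately out of
scope.

The full ensemble is the 16-member factorial of transition × stock cap ×
harvest × kernel set; trajectories are reported per member plus the
ensemble mean and min–max envelope.

## The synthetic network generator

The generator emulates the statistical structure the analysis relies on,
not any real geography. Defaults (the package's study conditions, chosen
once): 50 sites in 5 climate clusters of 10, one calendar year each.
Cluster centres span MAT −2 to 22 °C, MAP 450–1100 mm, mean SW_in
120–215 W m⁻²; within-cluster jitter (±0.5 °C, ±5 %) is well inside the
matching tolerances so cluster members are mutual climate partners, while
centres are far apart. Latitude follows a continental-interior mapping
(≈ 28° + 1.3° per °C below 22 °C MAT, capped at 62°) so even the coldest
cluster keeps winter daylight — albedo-based snow detection is physically
impossible in a polar night. Snow-free albedo targets spread evenly
within clusters over 0.07–0.24 (cool) and 0.12–0.45 (warm); restricting
bright surfaces to warm clusters keeps the synthetic world coherent
(bright *cold* soils would be indistinguishable from snow under any
α/temperature rule). IGBP classes, canopy height (decreasing in albedo)
and occasional dominant species are assigned consistently with the
albedo target.

Annual NEP is placed at a site-specific fraction (−0.1 to 0.9) of the
upper envelope NEP_max(α) = a/(α − α₀) − b, with defaults a = 55
gC m⁻² yr⁻¹, b = 50 gC m⁻² yr⁻¹, α₀ = 0.02 — a shifted hyperbola (the
qualitative "hyperbola-like" shape made concrete) spanning annual NEP
from weak sources to ≈ 750 gC m⁻² yr⁻¹ at forest albedos, the range a
global flux compilation exhibits. Half-hourly series use a clear-sky
cosine-of-zenith cycle scaled to the site mean with daily lognormal cloud
noise; SW_out = α(t) SW_in plus small multiplicative sensor noise; snow
episodes (α = 0.65) occupy the site's coldest days with sub-freezing
temperatures enforced; dormant-season albedo sits `dormant_albedo_offset`
(0.05) above the growing-season value, which both creates realistic
Δα_dorm contrasts and gives the window detector genuine change points.
GPP is proportional to radiation times a temperature-driven phenology,
respiration follows an exponential temperature response, and the
photosynthesis scale is solved so the realised annual NEP hits its target
exactly at zero noise — hence the envelope is a true upper bound on
noise-free networks, which is tested exhaustively. Gaps (default 10 % of
SW_out) use the FLUXNET sentinel −9999 on disk and NA in memory. NEE gaps
default to zero because the emulated source variable ships gap-filled; a
separate `gap_fraction_nee` exists to exercise full-year screening.

A daily-resolution fast path (`simulate_network_annual()`) reuses the
same construction for scenario and forcing experiments at a fraction of
the cost; it agrees with the half-hourly route to within ~1 % and is used
where only annual values and monthly climatologies matter (e.g. the
200-site oracle-equivalence tests).

**What the generator does not emulate** — and therefore what passing
tests cannot show about real data: sensor drift and systematic (non-random)
gap patterns, partial snow cover and canopy snow masking, interannual
climate variability, advection or u*-filtering artefacts in NEE, and any
real geographic covariance structure. Tests against the generator
establish that the algorithms recover known truth under the stated
statistical structure, not that FLUXNET data satisfy that structure.

## Numerical choices and problem sizes

Deterministic behaviour: every generator call derives its RNG stream from
the parameter seed (sub-seeds per site and year, kept below 2³¹) and
restores the caller's RNG state. The test suite and the acceptance script
run the pipeline at its default size — 50 sites × 1 year of half-hourly
data end to end in a few seconds, 20 networks of up to 200 sites against
the exhaustive scenario oracle, 20 seeds for the imputation/snow recovery
study — sizes chosen so the full chain, including the 16 × 4 × 50
carbon-conservation sweep, completes in well under a minute while still
exercising every rule path.

Known limitations, beyond the generator scope above: the stability
criterion and snow thresholds are plausible defaults, not fitted to any
instrument; the saturation cap is a bracket, not a process model; the
balanced scenario's behaviour when no joint improvement exists is a
policy choice exposed as a switch; ensemble means across sites weight
every site equally (no area weighting); and effective-forcing adjustments
(clouds, evapotranspiration, roughness) are intentionally excluded.
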