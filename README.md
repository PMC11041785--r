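# nepalbedo

Land surfaces influence climate through two competing channels: net
ecosystem productivity (NEP = −NEE, the CO₂ sink strength of an ecosystem,
gC m⁻² yr⁻¹) and surface albedo (α_s = SW_out / SW_in, the fraction of
incoming shortwave radiation reflected back). Ecosystems that fix a lot of
carbon tend to be dark — forests more than grasslands, dense canopies more
than sparse ones — so maximising carbon uptake usually lowers albedo and
causes an immediate warming that the slow, cumulative CO₂ cooling only
later overcomes. `nepalbedo` is an R toolkit for quantifying this
trade-off from networks of eddy-covariance flux towers, for land-surface
and carbon-cycle researchers who work with FLUXNET2015-format half-hourly
data (or want a faithful synthetic stand-in).

The package implements the full chain:

1. **Flux processing** — half-hourly SW_in/SW_out/NEE series are screened
   for time windows of approximately constant albedo; missing SW_out is
   imputed as the window albedo times concurrent SW_in (keeping annual
   albedo unbiased); windows are classified as snow (α ≥ 0.30 and minimum
   temperature ≤ 0.5 °C), active (NEP > 0) or dormant (NEP ≤ 0); albedo is
   always aggregated flux-weighted, `Σ SW_out / Σ SW_in`, never as a mean
   of instantaneous ratios; only full calendar years enter cross-site
   statistics.
2. **Co-variability analysis** — bivariate Gaussian kernel density of
   (α_s, NEP) versus the product of its marginals, Spearman rank
   correlations, per-group growing-season/dormancy/snow statistics, and
   trade-off envelopes (the theoretical PAR-limited NEP maximum and the
   convex-hull bound on freely combined monthly states).
3. **Paired-site permutation scenarios** — each site may adopt the (α_s,
   NEP) state of a climate partner (mean annual temperature within
   ±1.5 °C; incoming shortwave, precipitation and snow days within ±20 %):
   SC1 maximises NEP, SC2 maximises albedo, SC3 maximises the balanced
   score

   x = (1/√2) Δα/(α_max − α_min) + (1/√2) ΔNEP/(NEP_max − NEP_min),

   and SC4 combines SC1's NEP with SC2's albedo (the breakthrough bound).
4. **Radiative forcing** — scenario deltas, applied to 1 % of the global
   land surface, drive 100-year trajectories of global top-of-atmosphere
   net radiation change ΔR: CO₂ forcing RF = 5.35 ln(C/C₀) W m⁻² of the
   cumulative uptake perturbation (reference 420 ppm, airborne fraction
   0.44, carbon stocks evolving from 14,498 gC m⁻² with transition ramps,
   saturation caps and harvest exports) plus a monthly albedo-kernel
   effect (kernels proportional to site SW_in by factors 0.81–1.03), over
   a 16-member assumption ensemble.
5. **Synthetic network generator** — FLUXNET-dialect site networks with
   diurnal/seasonal radiation cycles, snow episodes, climate clusters that
   admit partner matching, and a hyperbolic upper envelope of annual NEP
   against albedo, with ground-truth logs so every stage is testable.

## Worked example

```r
library(nepalbedo)

params <- generator_params(seed = 7)          # 50 sites, 5 climate clusters
net <- simulate_network_annual(params)        # annual-scale synthetic network

cor <- spearman_cor(net$annual$albedo, net$annual$nep)
round(cor$rho, 2)
kde <- kde_tradeoff(net$annual$albedo, net$annual$nep)
print(kde)

asn <- assign_scenarios(net$annual, net$meta, monthly = net$monthly)
scenario_summary(asn)
traj <- build_trajectories(asn, net$annual, net$meta, net$monthly)
print(traj)
```

which prints:

```
[1] -0.43
NEP-albedo kernel density analysis
  n = 50 points, grid 256 x 256
  bandwidths: albedo 0.04605, NEP 56.4
  integrals: joint 1.0000, product 1.0000, difference +8.53e-12
  max |difference| / max joint = 0.235
  scenario mean_delta_nep mean_delta_albedo n_with_partners n_sites
1      SC1          179.8           -0.0925              50      50
2      SC2          -62.2            0.1034              50      50
3      SC3           93.3            0.0383              50      50
4      SC4          179.8            0.1034              50      50
TOA net radiation trajectories
  SC1: year 1 mean +0.0233 [+0.001319, +0.05061]; year 100 mean -0.007863
  SC2: year 1 mean -0.02542 [-0.05511, -0.001443]; year 100 mean -0.02819
  SC3: year 1 mean -0.01243 [-0.02691, -0.0007079]; year 100 mean -0.05302
  SC4: year 1 mean -0.02588 [-0.05605, -0.001472]; year 100 mean -0.1031
```

Reading the numbers: Spearman ρ(α_s, NEP) = −0.43 across the 50 synthetic
sites (high albedo pairs with low uptake); the joint kernel density
deviates from the independence product by up to 23 % of the joint maximum.
NEP maximisation (SC1) raises mean NEP by 180 gC m⁻² yr⁻¹ but darkens the
surface by 0.09, so its ensemble-mean ΔR starts at +0.023 W m⁻² (warming)
and only turns negative decades later; albedo maximisation (SC2) cools
immediately (−0.025 W m⁻² in year 1) at the cost of carbon losses; the
balanced scenario (SC3) avoids initial warming entirely; the hypothetical
breakthrough (SC4) dominates both components. Negative ΔR is cooling; all
values are global means per 1 % of land surface changed.

The staged command-line pipeline writes the same artifacts as delimited
tables plus a run manifest:

```sh
Rscript inst/scripts/nepalbedo.R --out results/run1 --seed 7
```

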