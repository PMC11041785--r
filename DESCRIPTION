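Package: nepalbedo
Title: Trade-Offs Between Land Carbon Uptake and Surface Albedo from Flux-Tower Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the trade-off between net ecosystem productivity
    (NEP) and surface albedo across eddy-covariance flux networks. Processes
    half-hourly FLUXNET2015-dialect radiation and CO2 flux series into
    gap-filled albedo, snow and dormancy labels, and annual and monthly site
    aggregates; quantifies NEP-albedo co-variability with bivariate kernel
    densities and rank correlations; runs paired-site permutation scenarios
    that move each site to a climate-matched partner maximising NEP, albedo
    or a balanced score; and converts the scenario deltas into 100-year
    top-of-atmosphere net radiation trajectories combining CO2 radiative
    forcing (with transition, carbon-stock saturation and harvest export)
    and monthly albedo-kernel effects over a bounded assumption ensemble.
    Includes a synthetic flux-network generator so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
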