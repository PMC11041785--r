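#' Parameters for the synthetic flux-network generator
#'
#' Bundles all knobs of the synthetic FLUXNET-like network: network size,
#' the NEP-albedo envelope coefficients, gap and noise scales, and the
#' snow/dormancy albedo conventions.  Defaults define the study conditions
#' used throughout the package's tests and examples: 50 sites in 5 climate
#' clusters of 10, one calendar year each, an envelope spanning realistic
#' annual NEP (up to ~750 gC m-2 yr-1 at forest albedos) over the albedo
#' range 0.07-0.45.
#'
#' @param n_sites number of sites (>= 2).
#' @param years_per_site calendar years generated per site.
#' @param n_clusters number of climate clusters; sites are spread round-robin
#'   so each cluster admits mutual partner matching.
#' @param start_year first calendar year of each site's record.
#' @param envelope_a,envelope_b,envelope_alpha0 coefficients of the upper
#'   envelope NEP_max(alpha) = a / (alpha - alpha0) - b (gC m-2 yr-1).
#' @param gap_fraction fraction of half-hours with missing SW_OUT, in [0, 1).
#' @param gap_fraction_nee fraction of half-hours with missing NEE.  The
#'   FLUXNET source product ships NEE already gap-filled, so the default is
#'   0; set > 0 only to exercise full-year screening.
#' @param snow_albedo albedo during snow episodes (dimensionless).
#' @param dormant_albedo_offset albedo increase of snow-free dormant
#'   vegetation/soil relative to the growing season.
#' @param noise_radiation relative (lognormal) scale of daily cloud noise on
#'   SW_IN; also scales multiplicative SW_OUT sensor noise (x 0.2).
#' @param noise_flux additive NEE noise, umol CO2 m-2 s-1.
#' @param noise_tair additive air-temperature noise, degrees C.
#' @param cluster_tightness multiplier > 0 shrinking within-cluster climate
#'   jitter; larger values give tighter clusters and hence more partners.
#' @param seed integer RNG seed; all generator output is a deterministic
#'   function of the parameters including this seed.
#' @return a list of class \code{generator_params}.
#' @export
generator_params <- function(n_sites = 50L, years_per_site = 1L,
                             n_clusters = 5L, start_year = 2015L,
                             envelope_a = 55, envelope_b = 50,
                             envelope_alpha0 = 0.02,
                             gap_fraction = 0.1, gap_fraction_nee = 0,
                             snow_albedo = 0.65,
                             dormant_albedo_offset = 0.05,
                             noise_radiation = 0.1, noise_flux = 0.5,
                             noise_tair = 0.8,
                             cluster_tightness = 1, seed = 1L) {
  p <- list(n_sites = as.integer(n_sites),
            years_per_site = as.integer(years_per_site),
            n_clusters = as.integer(n_clusters),
            start_year = as.integer(start_year),
            envelope_a = envelope_a, envelope_b = envelope_b,
            envelope_alpha0 = envelope_alpha0,
            gap_fraction = gap_fraction,
            gap_fraction_nee = gap_fraction_nee,
            snow_albedo = snow_albedo,
            dormant_albedo_offset = dormant_albedo_offset,
            noise_radiation = noise_radiation, noise_flux = noise_flux,
            noise_tair = noise_tair,
            cluster_tightness = cluster_tightness,
            seed = as.integer(seed))
  if (p$gap_fraction < 0 || p$gap_fraction >= 1)
    stop("gap_fraction must lie in [0, 1)")
  if (p$gap_fraction_nee < 0 || p$gap_fraction_nee >= 1)
    stop("gap_fraction_nee must lie in [0, 1)")
  if (p$envelope_a <= 0 || p$envelope_alpha0 >= 1)
    stop("envelope must yield NEP_max > 0 somewhere in (alpha0, 1)")
  if (p$cluster_tightness <= 0) stop("cluster_tightness must be positive")
  class(p) <- "generator_params"
  p
}

#' Upper envelope of annual NEP attainable at a given albedo
#'
#' The network-wide scatter of annual NEP against albedo is bounded above by
#' a hyperbola-like curve; the generator realises it as a shifted hyperbola
#' NEP_max(alpha) = a / (alpha - alpha0) - b, strictly decreasing in alpha
#' and approaching -b for bright surfaces.  For alpha <= alpha0 the bound is
#' infinite (no generated site lies there).
#'
#' @param albedo dimensionless albedo, strictly inside (0, 1).
#' @param params a \code{\link{generator_params}} object supplying a, b and
#'   alpha0.
#' @return maximum annual NEP in gC m-2 yr-1 (vectorised over \code{albedo}).
#' @export
envelope_nep_max <- function(albedo, params = generator_params()) {
  if (any(!is.finite(albedo)) || any(albedo <= 0) || any(albedo >= 1))
    stop("albedo must lie strictly inside (0, 1)")
  a0 <- params$envelope_alpha0
  ifelse(albedo > a0, params$envelope_a / (albedo - a0) - params$envelope_b,
         Inf)
}

#' Generate metadata for a synthetic site network
#'
#' Sites are laid out in climate clusters (round-robin assignment): within a
#' cluster, mean annual temperature (MAT), precipitation (MAP), mean
#' incoming shortwave radiation and snow-day counts are jittered tightly
#' enough that all members remain mutual climate partners under the default
#' matching tolerances (MAT within 1.5 degrees C, the rest within 20
#' percent), while cluster centres are far apart.  Snow-free albedo targets
#' spread along the trade-off axis within each cluster; high albedos
#' (> 0.24) occur only in warm clusters, where bright dry soils rather than
#' seasonally frozen surfaces populate the bright tail.  IGBP class, canopy
#' height (decreasing in albedo) and an optional dominant species are
#' assigned consistently with the albedo target.
#'
#' The columns \code{alpha_sf} (snow-free albedo) and \code{nep_frac}
#' (fraction of the envelope NEP realised) are generator ground truth used
#' by \code{\link{generate_halfhourly}}; they are not part of the metadata
#' that real networks provide.
#'
#' @param params a \code{\link{generator_params}} object; \code{n_sites}
#'   must be at least 2.
#' @return a data.frame of class \code{site_meta} with one row per site.
#' @export
generate_site_metadata <- function(params = generator_params()) {
  if (params$n_sites < 2) stop("n_sites must be at least 2")
  with_seed(params$seed, {
    n <- params$n_sites
    k <- max(1L, min(params$n_clusters, n))
    cluster <- rep_len(seq_len(k), n)
    centres <- data.frame(
      mat  = seq(-2, 22, length.out = k),
      map  = seq(450, 1100, length.out = k),
      sw   = seq(120, 215, length.out = k))
    centres$snow_days <- ifelse(centres$mat < 5, 60,
                                ifelse(centres$mat < 10, 25, 0))
    jit <- function(centre, abs_scale = NULL, rel_scale = NULL) {
      s <- if (is.null(abs_scale)) abs(centre) * rel_scale else abs_scale
      centre + runif(n, -1, 1) * s / params$cluster_tightness
    }
    mat <- jit(centres$mat[cluster], abs_scale = 0.5)
    map <- jit(centres$map[cluster], rel_scale = 0.05)
    sw  <- jit(centres$sw[cluster],  rel_scale = 0.05)
    snow_days <- ifelse(centres$snow_days[cluster] == 0, 0,
                        jit(centres$snow_days[cluster], rel_scale = 0.05))

    # Albedo targets: evenly spread within cluster (plus jitter) so every
    # cluster spans a stretch of the trade-off curve.
    warm <- centres$mat[cluster] >= 16
    lo <- ifelse(warm, 0.12, 0.07)
    hi <- ifelse(warm, 0.45, 0.24)
    rank_in_cluster <- stats::ave(seq_len(n), cluster, FUN = seq_along)
    n_in_cluster <- stats::ave(seq_len(n), cluster, FUN = length)
    frac <- (rank_in_cluster - 0.5) / n_in_cluster
    alpha_sf <- lo + frac * (hi - lo) +
      runif(n, -0.01, 0.01) / params$cluster_tightness
    alpha_sf <- pmin(pmax(alpha_sf, 0.05), 0.45)
    nep_frac <- runif(n, -0.1, 0.9)

    igbp <- character(n)
    for (i in seq_len(n)) {
      a <- alpha_sf[i]
      cold <- mat[i] < 8
      igbp[i] <-
        if (a < 0.12) sample(c("ENF", "EBF", "MF"), 1,
                             prob = if (cold) c(0.7, 0, 0.3) else c(0.3, 0.4, 0.3))
        else if (a < 0.17) sample(c("DBF", "MF", "WSA", "WET"), 1)
        else if (a < 0.23) sample(c("GRA", "CRO", "WET", "SAV"), 1)
        else sample(c("OSH", "CSH", "GRA", "CRO", if (cold) "SNO" else "SAV"), 1)
    }
    species_pool <- list(ENF = c("Picea abies", "Pinus sylvestris"),
                         DBF = c("Fagus sylvatica", "Quercus cerris"),
                         EBF = c("Quercus ilex"))
    species <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      pool <- species_pool[[igbp[i]]]
      if (!is.null(pool) && runif(1) < 0.5) species[i] <- sample(pool, 1)
    }
    canopy_height <- pmax(0.2, 38 * (0.40 - alpha_sf)) * exp(rnorm(n, 0, 0.15))
    # continental-interior mapping: cold clusters at boreal mid-latitudes
    # (winter daylight preserved, so albedo stays observable year-round)
    lat <- pmin(62, pmax(5, 28 + (22 - centres$mat[cluster]) * 1.3 +
                           runif(n, -2, 2)))
    lon <- runif(n, -10, 30)

    meta <- data.frame(
      site_id = sprintf("SYN-%03d", seq_len(n)),
      igbp = igbp, mat = mat, map = map, mean_sw_in = sw,
      snow_days = snow_days, canopy_height = canopy_height,
      species = species, lat = lat, lon = lon,
      cluster = cluster, alpha_sf = alpha_sf, nep_frac = nep_frac,
      stringsAsFactors = FALSE)
    class(meta) <- c("site_meta", "data.frame")
    meta
  })
}

# Day-level ground truth shared by the half-hourly generator and the annual
# fast path: daily mean SW_in (clear-sky seasonal cycle x cloud noise scaled
# to the site mean), seasonal air temperature, snow episodes on the coldest
# days, growing-season flag, daily true albedo and the vegetation-uptake /
# respiration shapes used to hit the target annual NEP.
daily_truth <- function(site, year, params) {
  n_days <- if ((year %% 4 == 0 && year %% 100 != 0) || year %% 400 == 0)
    366L else 365L
  doy <- seq_len(n_days)
  phi <- site$lat * pi / 180
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365) * pi / 180
  cosws <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  ws <- acos(cosws)
  pot <- pmax(0, ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  cloud <- exp(rnorm(n_days, 0, params$noise_radiation))
  sw <- pot * cloud
  if (mean(sw) <= 0) stop("site receives no radiation; check latitude")
  sw <- sw * site$mean_sw_in / mean(sw)

  amp <- 8 + pmax(0, 15 - site$mat) * 0.55
  tair <- site$mat + amp * (-cos(2 * pi * (doy - 15) / n_days))

  snow <- rep(FALSE, n_days)
  target_snow <- round(site$snow_days)
  if (target_snow > 0) {
    target_snow <- min(target_snow, n_days - 30L)
    snow[order(tair)[seq_len(target_snow)]] <- TRUE
    tair[snow] <- pmin(tair[snow], -1)
  }
  growing <- tair > 5 & !snow
  veg <- pmin(1, pmax(0, (tair - 5) / 15))
  veg[snow] <- 0

  alpha <- rep(site$alpha_sf, n_days)
  alpha[!growing] <- site$alpha_sf + params$dormant_albedo_offset
  alpha[snow] <- params$snow_albedo

  list(n_days = n_days, doy = doy,
       date = as.Date(sprintf("%d-01-01", year)) + doy - 1,
       sw = sw, tair = tair, snow = snow, growing = growing,
       veg = veg, alpha = alpha, resp = exp(0.07 * tair))
}

# Contiguous runs of TRUE in a logical vector -> data.frame(start, end)
# of day indices.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Generate one calendar year of half-hourly flux-tower data
#'
#' Produces a FLUXNET-like half-hourly series (17,520 or 17,568 records)
#' with a clear-sky diurnal/seasonal SW_IN cycle scaled to the site mean
#' and modulated by daily cloud noise; SW_OUT = alpha_true(t) x SW_IN with
#' small multiplicative sensor noise; air temperature with seasonal and
#' diurnal cycles, clamped below freezing during snow episodes; GPP,
#' ecosystem respiration and NEE = Reco - GPP whose annual NEP equals
#' \code{nep_frac} x the envelope value at the realised annual flux-weighted
#' albedo; and missing-value gaps injected into SW_OUT (and optionally NEE).
#' Snow episodes (albedo = \code{snow_albedo}) occupy the site's coldest
#' days, day-aligned.
#'
#' @param site one row of \code{\link{generate_site_metadata}} output.
#' @param year calendar year.
#' @param params a \code{\link{generator_params}} object.
#' @return a list with elements \code{series} (a \code{flux_series}
#'   data.frame with columns timestamp, sw_in, sw_out, nee, gpp, reco, tair,
#'   precip; NA marks missing) and \code{truth} (realised annual
#'   flux-weighted albedo and NEP of the gap-free series, snow intervals,
#'   gap positions, and the generator targets).
#' @export
generate_halfhourly <- function(site, year, params = generator_params()) {
  if (is.data.frame(site)) {
    if (nrow(site) != 1) stop("site must be a single metadata row")
    site <- as.list(site)
  }
  idx <- sum(utf8ToInt(as.character(site$site_id))) %% 99991L
  with_seed(derive_seed(params$seed, idx, year), {
    day <- daily_truth(site, year, params)
    n_days <- day$n_days
    n <- n_days * 48L

    ts0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
    timestamp <- ts0 + (seq_len(n) - 1L) * 1800
    day_of <- rep(seq_len(n_days), each = 48L)
    hour <- rep((0:47) / 2 + 0.25, n_days)      # interval midpoint, local time

    phi <- site$lat * pi / 180
    decl <- 23.45 * sin(2 * pi * (284 + day$doy[day_of]) / 365) * pi / 180
    hang <- (hour - 12) * 15 * pi / 180
    cosz <- pmax(0, sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(hang))
    day_mean_cosz <- tapply(cosz, day_of, mean)
    scale_d <- ifelse(day_mean_cosz > 0, day$sw / day_mean_cosz, 0)
    sw_in <- cosz * scale_d[day_of]

    tair <- day$tair[day_of] - 4 * cos(2 * pi * (hour - 14) / 24) +
      rnorm(n, 0, params$noise_tair)
    snow_hh <- day$snow[day_of]
    tair[snow_hh] <- pmin(tair[snow_hh], -0.5)

    alpha_t <- day$alpha[day_of]
    sw_out <- pmax(0, alpha_t * sw_in *
                     (1 + rnorm(n, 0, 0.2 * params$noise_radiation)))
    sw_out[sw_in == 0] <- 0

    alpha_annual <- sum(sw_out) / sum(sw_in)
    target_nep <- site$nep_frac * envelope_nep_max(alpha_annual, params)

    uptake <- day$veg[day_of] * sw_in
    resp <- exp(0.07 * tair)
    cscale <- (target_nep / UMOL_TO_GC + sum(resp)) / sum(uptake)
    gpp <- cscale * uptake
    reco <- resp
    nee <- reco - gpp + rnorm(n, 0, params$noise_flux)

    wet <- runif(n_days) < 0.3
    amounts <- stats::rexp(n_days) * wet
    if (sum(amounts) > 0) amounts <- amounts / sum(amounts) * site$map
    precip <- numeric(n)
    precip[(seq_len(n_days) - 1L) * 48L + 1L] <- amounts

    truth_albedo <- alpha_annual
    truth_nep <- UMOL_TO_GC * sum(-nee)

    gaps_swout <- sort(sample.int(n, floor(params$gap_fraction * n)))
    gaps_nee <- sort(sample.int(n, floor(params$gap_fraction_nee * n)))
    if (length(gaps_swout)) sw_out[gaps_swout] <- NA_real_
    if (length(gaps_nee)) nee[gaps_nee] <- NA_real_

    runs <- logical_runs(day$snow)
    snow_intervals <- if (nrow(runs))
      data.frame(start = ts0 + (runs$start - 1) * 86400,
                 end = ts0 + runs$end * 86400)
    else data.frame(start = as.POSIXct(character()),
                    end = as.POSIXct(character()))

    series <- data.frame(timestamp = timestamp, sw_in = sw_in,
                         sw_out = sw_out, nee = nee, gpp = gpp, reco = reco,
                         tair = tair, precip = precip)
    attr(series, "site_id") <- site$site_id
    attr(series, "year") <- year
    class(series) <- c("flux_series", "data.frame")

    list(series = series,
         truth = list(site_id = site$site_id, year = year,
                      albedo = truth_albedo, nep = truth_nep,
                      target_nep = target_nep, alpha_sf = site$alpha_sf,
                      snow_intervals = snow_intervals,
                      snow_days = day$snow,
                      gaps_swout = gaps_swout, gaps_nee = gaps_nee))
  })
}

#' Generate a full synthetic network (metadata plus half-hourly series)
#'
#' Convenience wrapper: metadata via \code{\link{generate_site_metadata}},
#' then one \code{\link{generate_halfhourly}} call per site and year.
#'
#' @param params a \code{\link{generator_params}} object.
#' @return a list with \code{meta}, \code{series} (nested list,
#'   site -> year -> \code{flux_series}) and \code{truth} (site -> year ->
#'   truth log).
#' @export
generate_network <- function(params = generator_params()) {
  meta <- generate_site_metadata(params)
  years <- params$start_year + seq_len(params$years_per_site) - 1L
  series <- list(); truth <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$site_id[i]
    series[[sid]] <- list(); truth[[sid]] <- list()
    for (y in years) {
      g <- generate_halfhourly(meta[i, ], y, params)
      series[[sid]][[as.character(y)]] <- g$series
      truth[[sid]][[as.character(y)]] <- g$truth
    }
  }
  list(meta = meta, series = series, truth = truth)
}

#' Fast annual-scale synthetic network
#'
#' Generates site metadata plus annual and monthly-climatology tables
#' directly from the generator's day-level ground truth, skipping the
#' half-hourly layer.  Intended for scenario-engine and forcing experiments
#' where only annual NEP/albedo and monthly climatologies matter; the
#' construction (clear-sky cycle, cloud noise, snow episodes, envelope
#' scaling) is the same as in \code{\link{generate_halfhourly}}, evaluated
#' at daily resolution.
#'
#' @param params a \code{\link{generator_params}} object.
#' @return a list with \code{meta}, \code{annual} (site_id, albedo, nep:
#'   multi-annual site means) and \code{monthly} (site_id, month, albedo,
#'   nep in gC m-2 month-1, sw_in mean).
#' @export
simulate_network_annual <- function(params = generator_params()) {
  meta <- generate_site_metadata(params)
  years <- params$start_year + seq_len(params$years_per_site) - 1L
  gc_day <- 86400 * MOLAR_MASS_C * 1e-6
  annual <- list(); monthly <- list()
  for (i in seq_len(nrow(meta))) {
    site <- as.list(meta[i, ])
    idx <- sum(utf8ToInt(as.character(site$site_id))) %% 99991L
    acc <- NULL
    for (y in years) {
      day <- with_seed(derive_seed(params$seed, idx, y),
                       daily_truth(site, y, params))
      alpha_annual <- sum(day$alpha * day$sw) / sum(day$sw)
      target_nep <- site$nep_frac * envelope_nep_max(alpha_annual, params)
      cscale <- (target_nep / gc_day + sum(day$resp)) /
        sum(day$veg * day$sw)
      nep_day <- gc_day * (cscale * day$veg * day$sw - day$resp)
      mon <- as.integer(format(day$date, "%m"))
      df <- data.frame(
        month = 1:12,
        swout_sum = as.numeric(tapply(day$alpha * day$sw, mon, sum)),
        swin_sum = as.numeric(tapply(day$sw, mon, sum)),
        nep = as.numeric(tapply(nep_day, mon, sum)),
        sw_in = as.numeric(tapply(day$sw, mon, mean)))
      df$year_albedo <- alpha_annual
      df$year_nep <- target_nep
      acc <- if (is.null(acc)) df else {
        acc$swout_sum <- acc$swout_sum + df$swout_sum
        acc$swin_sum <- acc$swin_sum + df$swin_sum
        acc$nep <- acc$nep + df$nep
        acc$sw_in <- acc$sw_in + df$sw_in
        acc$year_albedo <- acc$year_albedo + df$year_albedo
        acc$year_nep <- acc$year_nep + df$year_nep
        acc
      }
    }
    ny <- length(years)
    annual[[i]] <- data.frame(site_id = site$site_id,
                              albedo = acc$year_albedo[1] / ny,
                              nep = acc$year_nep[1] / ny,
                              stringsAsFactors = FALSE)
    monthly[[i]] <- data.frame(site_id = site$site_id, month = 1:12,
                               albedo = acc$swout_sum / acc$swin_sum,
                               nep = acc$nep / ny, sw_in = acc$sw_in / ny,
                               stringsAsFactors = FALSE)
  }
  list(meta = meta, annual = do.call(rbind, annual),
       monthly = do.call(rbind, monthly))
}
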