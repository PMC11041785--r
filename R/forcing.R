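#' Physical constants of the radiative-forcing chain
#'
#' Defaults: reference CO2 concentration 420 ppm; airborne fraction 0.44;
#' simplified-expression forcing coefficient 5.35 W m-2; initial ecosystem
#' carbon stock 14,498 gC m-2; atmospheric mass-to-mixing-ratio conversion
#' 2.124e15 gC per ppm; global land and Earth surface areas; and the
#' affected land fraction (1 percent) to which per-site effects are scaled.
#'
#' @param co2_ref ppm.
#' @param airborne_fraction fraction of an uptake perturbation removed from
#'   the atmosphere.
#' @param rf_coeff W m-2 coefficient of RF = coeff x ln(C/C0).
#' @param c_init initial carbon stock, gC m-2.
#' @param ppm_to_mass gC per ppm CO2.
#' @param land_area,earth_area m2.
#' @param land_fraction_changed fraction of the land surface on which land
#'   use changes.
#' @return list of class \code{forcing_constants}.
#' @export
forcing_constants <- function(co2_ref = 420, airborne_fraction = 0.44,
                              rf_coeff = 5.35, c_init = 14498,
                              ppm_to_mass = 2.124e15,
                              land_area = 1.489e14, earth_area = 5.101e14,
                              land_fraction_changed = 0.01) {
  k <- list(co2_ref = co2_ref, airborne_fraction = airborne_fraction,
            rf_coeff = rf_coeff, c_init = c_init,
            ppm_to_mass = ppm_to_mass, land_area = land_area,
            earth_area = earth_area,
            land_fraction_changed = land_fraction_changed)
  if (any(unlist(k) <= 0)) stop("all constants must be positive")
  class(k) <- "forcing_constants"
  k
}

#' The 16-member assumption ensemble
#'
#' Full factorial over transition time (0 or 30 years), maximum achievable
#' carbon stock (50,000 or 100,000 gC m-2), harvest level (low or high) and
#' albedo-kernel strength (weak or strong).
#'
#' @return data.frame with columns transition_years, c_max, harvest_level,
#'   kernel_set and label (16 rows).
#' @export
ensemble_members <- function() {
  g <- expand.grid(transition_years = c(0, 30),
                   c_max = c(50000, 100000),
                   harvest_level = c("low", "high"),
                   kernel_set = c("weak", "strong"),
                   stringsAsFactors = FALSE)
  g$label <- sprintf("t%02d_c%03dk_h%s_k%s", g$transition_years,
                     g$c_max / 1000, g$harvest_level, g$kernel_set)
  g
}

#' Annual harvest export for an IGBP class
#'
#' Carbon removed by harvest and assumed re-emitted in the harvest year:
#' crops 247 (low) to 335 (high) gC m-2 yr-1; grassland 0 to 100 percent
#' of positive NEP; forests and all other classes 0 to 61 gC m-2 yr-1.
#'
#' @param igbp IGBP class code.
#' @param level "low" or "high".
#' @param nep_eff current effective NEP, gC m-2 yr-1 (used for grassland).
#' @return harvest flux, gC m-2 yr-1 (>= 0).
#' @export
harvest_rate <- function(igbp, level, nep_eff) {
  if (igbp == "CRO") {
    if (level == "low") 247 else 335
  } else if (igbp == "GRA") {
    if (level == "low") 0 else max(nep_eff, 0)
  } else {
    if (level == "low") 0 else 61
  }
}

# Evolve one carbon-stock track from c_init under a yearly effective NEP
# series, with harvest export and a hard cap at [0, c_max] that shuts the
# net flux off once it binds.  Returns per-year applied fluxes and stocks.
evolve_stock <- function(nep_eff, igbp, level, c_max, constants) {
  years <- length(nep_eff)
  stock <- numeric(years + 1)
  stock[1] <- constants$c_init
  net <- nep_app <- harv_app <- numeric(years)
  for (t in seq_len(years)) {
    at_cap <- stock[t] >= c_max || stock[t] <= 0
    if (at_cap && ((stock[t] >= c_max && nep_eff[t] >= 0) ||
                   (stock[t] <= 0 && nep_eff[t] <= 0))) {
      stock[t + 1] <- stock[t]
      next
    }
    h <- harvest_rate(igbp, level, nep_eff[t])
    flux <- nep_eff[t] - h
    s_new <- min(max(stock[t] + flux, 0), c_max)
    applied <- s_new - stock[t]
    if (applied != flux && flux != 0) {
      # cap binds mid-year: the applied fraction of both components
      frac <- applied / flux
      nep_app[t] <- nep_eff[t] * frac
      harv_app[t] <- h * frac
    } else {
      nep_app[t] <- nep_eff[t]
      harv_app[t] <- h
    }
    net[t] <- applied
    stock[t + 1] <- s_new
  }
  list(net = net, nep = nep_app, harvest = harv_app, stock = stock[-1])
}

#' Yearly net atmospheric uptake perturbation of a changed site
#'
#' Evolves a factual track (effective NEP ramping linearly from the old to
#' the new value over the member's transition time, or stepping if it is
#' zero) and a business-as-usual counterfactual track (old NEP throughout),
#' both from the initial stock with the member's harvest level and hard
#' stock caps at 0 and c_max (net flux shut off once a cap binds).  The
#' perturbation is the factual-minus-counterfactual net land carbon flux;
#' harvested carbon counts as returned to the atmosphere in its harvest
#' year.
#'
#' @param nep_old site NEP before the change, gC m-2 yr-1.
#' @param delta_nep scenario NEP change, gC m-2 yr-1.
#' @param igbp IGBP class (sets the harvest rule).
#' @param member one row of \code{\link{ensemble_members}}.
#' @param constants a \code{\link{forcing_constants}} object.
#' @param years horizon (default 100).
#' @return list with \code{perturbation} (gC m-2 yr-1, length \code{years})
#'   and the factual/counterfactual diagnostics (net fluxes, applied NEP,
#'   harvest, stocks).
#' @export
carbon_perturbation <- function(nep_old, delta_nep, igbp, member,
                                constants = forcing_constants(),
                                years = 100L) {
  if (member$c_max <= constants$c_init)
    stop("invalid ensemble member: c_max must exceed the initial stock")
  t <- seq_len(years)
  ramp <- if (member$transition_years == 0) rep(1, years)
  else pmin(t / member$transition_years, 1)
  fact <- evolve_stock(nep_old + ramp * delta_nep, igbp,
                       member$harvest_level, member$c_max, constants)
  cf <- evolve_stock(rep(nep_old, years), igbp, member$harvest_level,
                     member$c_max, constants)
  list(perturbation = fact$net - cf$net, ramp = ramp,
       factual = fact, counterfactual = cf)
}

#' CO2 radiative forcing of a cumulative uptake perturbation
#'
#' The network-mean cumulative uptake (gC m-2), applied to the changed
#' fraction of the global land surface and reduced by the airborne
#' fraction, is converted to a CO2 mixing-ratio change and then to global
#' mean radiative forcing with the simplified logarithmic expression
#' RF = rf_coeff x ln((C0 + dC)/C0).  Net uptake gives negative forcing
#' (cooling).
#'
#' @param cum_uptake cumulative mean uptake perturbation, gC m-2
#'   (vectorised, e.g. one value per year).
#' @param constants a \code{\link{forcing_constants}} object.
#' @return radiative forcing, W m-2 global mean.
#' @export
rf_co2 <- function(cum_uptake, constants = forcing_constants()) {
  dppm <- -(cum_uptake * constants$land_fraction_changed *
              constants$land_area * constants$airborne_fraction) /
    constants$ppm_to_mass
  ratio <- (constants$co2_ref + dppm) / constants$co2_ref
  if (any(ratio <= 0)) stop("unphysical CO2 drawdown")
  constants$rf_coeff * log(ratio)
}

#' Global TOA effect of a monthly albedo change
#'
#' Each site's local annual effect is the mean over months of kernel times
#' albedo change, k_m x dalpha_m (kernels are negative: TOA net radiation
#' decreases when the surface brightens); the global value scales the
#' site mean by the changed land fraction of the Earth's surface.
#'
#' @param delta_alpha monthly albedo changes: vector of 12 or matrix
#'   (sites x 12).
#' @param kernels monthly kernels, same shape, W m-2 per unit albedo
#'   increase (<= 0).
#' @param constants a \code{\link{forcing_constants}} object.
#' @return W m-2 global mean.
#' @export
albedo_effect <- function(delta_alpha, kernels,
                          constants = forcing_constants()) {
  if (any(kernels > 0, na.rm = TRUE))
    warning("positive albedo-kernel entries violate the sign convention")
  if (is.null(dim(delta_alpha))) delta_alpha <- matrix(delta_alpha, 1)
  if (is.null(dim(kernels))) kernels <- matrix(kernels, 1)
  # months without radiation have zero kernel and an undefined (NA) albedo;
  # their contribution is physically zero
  term <- kernels * delta_alpha
  term[kernels == 0] <- 0
  local <- rowMeans(term)
  mean(local) * constants$land_fraction_changed *
    constants$land_area / constants$earth_area
}

#' Synthetic albedo kernels proportional to measured SW_IN
#'
#' Radiative-kernel datasets are highly correlated with surface SW_IN and
#' related to it by factors between 0.81 (weak) and 1.03 (strong); when no
#' kernel table is supplied, monthly kernels are built as
#' k_m = -factor x SW_IN_m.
#'
#' @param monthly_sw_in monthly mean SW_IN, vector of 12 or matrix
#'   (sites x 12), W m-2.
#' @param kernel_set "weak" or "strong".
#' @return kernels, same shape, W m-2 per unit albedo (<= 0).
#' @export
synthetic_kernels <- function(monthly_sw_in, kernel_set = c("weak", "strong")) {
  kernel_set <- match.arg(kernel_set)
  factor <- c(weak = 0.81, strong = 1.03)[[kernel_set]]
  -factor * monthly_sw_in
}

#' 100-year TOA net radiation trajectories for all scenarios and members
#'
#' For every scenario and ensemble member, the yearly global TOA net
#' radiation change is the CO2 forcing of the cumulative network-mean
#' uptake perturbation plus the albedo effect of the (transition-ramped)
#' monthly albedo deltas under the member's kernels; NEP and albedo ramp
#' together.  Sites without climate partners are excluded.  Negative
#' delta_r means cooling.
#'
#' @param assignments \code{\link{assign_scenarios}} output with monthly
#'   delta columns.
#' @param annual site-level table (site_id, nep) giving pre-change NEP.
#' @param meta site metadata (IGBP classes).
#' @param monthly monthly climatology (site_id, month, sw_in) used to build
#'   synthetic kernels.
#' @param members ensemble grid (default \code{\link{ensemble_members}}).
#' @param constants a \code{\link{forcing_constants}} object.
#' @param years horizon (default 100).
#' @return object of class \code{forcing_trajectories}: list with
#'   \code{trajectories} (long data.frame scenario, member, year, rf_co2,
#'   rf_albedo, delta_r) and \code{summary} (per scenario and year:
#'   ensemble mean, min, max).
#' @export
build_trajectories <- function(assignments, annual, meta, monthly,
                               members = ensemble_members(),
                               constants = forcing_constants(),
                               years = 100L) {
  sw_m <- matrix(NA_real_, nrow(annual), 12,
                 dimnames = list(annual$site_id, NULL))
  for (m in 1:12) {
    sel <- monthly$month == m
    sw_m[monthly$site_id[sel], m] <- monthly$sw_in[sel]
  }
  nep_old <- setNames(annual$nep, annual$site_id)
  igbp <- setNames(meta$igbp, meta$site_id)
  dalb_cols <- paste0("dalb_m", 1:12)
  if (!all(dalb_cols %in% names(assignments)))
    stop("assignments lack monthly albedo deltas; pass `monthly` to",
         " assign_scenarios()")

  out <- list()
  for (sc in unique(assignments$scenario)) {
    a <- assignments[assignments$scenario == sc & assignments$has_partners, ,
                     drop = FALSE]
    if (!nrow(a)) stop("no site with partners for scenario ", sc)
    dalb <- as.matrix(a[, dalb_cols])
    for (k in seq_len(nrow(members))) {
      member <- members[k, ]
      pert <- vapply(seq_len(nrow(a)), function(i)
        carbon_perturbation(nep_old[[a$site_id[i]]], a$delta_nep[i],
                            igbp[[a$site_id[i]]], member, constants,
                            years)$perturbation,
        numeric(years))
      pert <- matrix(pert, nrow = years)
      cum_mean <- cumsum(rowMeans(pert))
      rfc <- rf_co2(cum_mean, constants)
      kern <- synthetic_kernels(sw_m[a$site_id, , drop = FALSE],
                                member$kernel_set)
      base_alb <- albedo_effect(dalb, kern, constants)
      ramp <- if (member$transition_years == 0) rep(1, years)
      else pmin(seq_len(years) / member$transition_years, 1)
      rfa <- ramp * base_alb
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, member = member$label, year = seq_len(years),
        rf_co2 = rfc, rf_albedo = rfa, delta_r = rfc + rfa,
        stringsAsFactors = FALSE)
    }
  }
  traj <- do.call(rbind, out)
  summ <- stats::aggregate(delta_r ~ scenario + year, traj, function(v)
    c(mean = mean(v), min = min(v), max = max(v)))
  summ <- cbind(summ[c("scenario", "year")], as.data.frame(summ$delta_r))
  structure(list(trajectories = traj, summary = summ, members = members),
            class = "forcing_trajectories")
}

#' @export
print.forcing_trajectories <- function(x, ...) {
  cat("TOA net radiation trajectories\n")
  s <- x$summary
  for (sc in unique(s$scenario)) {
    y1 <- s[s$scenario == sc & s$year == 1, ]
    yN <- s[s$scenario == sc & s$year == max(s$year), ]
    cat(sprintf("  %s: year 1 mean %+0.4g [%+0.4g, %+0.4g]; year %d mean %+0.4g\n",
                sc, y1$mean, y1$min, y1$max, yN$year, yN$mean))
  }
  invisible(x)
}

#' First sign change of a trajectory
#'
#' Smallest year whose delta_r has the opposite sign of year 1; NA when no
#' crossing occurs or year 1 is exactly zero.
#'
#' @param delta_r numeric trajectory.
#' @return integer year or NA.
#' @export
sign_crossing <- function(delta_r) {
  if (!length(delta_r) || delta_r[1] == 0) return(NA_integer_)
  idx <- which(delta_r * delta_r[1] < 0)
  if (length(idx)) idx[1] else NA_integer_
}
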