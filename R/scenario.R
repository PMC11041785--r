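#' Climate-partner matching tolerances
#'
#' A candidate qualifies as a climate partner of a focal site when its mean
#' annual temperature lies within \code{mat_abs} degrees C and its mean
#' incoming shortwave radiation, mean annual precipitation and number of
#' snow-affected days each lie within the stated relative fraction of the
#' focal site's value.
#'
#' @param mat_abs absolute MAT tolerance, degrees C (default 1.5).
#' @param sw_rel,map_rel,snowdays_rel relative tolerances (default 0.20).
#' @return list of class \code{match_tolerances}.
#' @export
match_tolerances <- function(mat_abs = 1.5, sw_rel = 0.20, map_rel = 0.20,
                             snowdays_rel = 0.20) {
  if (mat_abs <= 0 || sw_rel <= 0 || map_rel <= 0 || snowdays_rel <= 0)
    stop("all tolerances must be strictly positive")
  structure(list(mat_abs = mat_abs, sw_rel = sw_rel, map_rel = map_rel,
                 snowdays_rel = snowdays_rel), class = "match_tolerances")
}

# Relative-difference criterion with focal-site denominator; a zero focal
# value matches only a zero candidate value.
rel_ok <- function(focal, candidate, tol) {
  if (focal == 0) candidate == 0
  else abs(candidate - focal) / abs(focal) <= tol
}

#' Find the climate partners of a site
#'
#' Directional matching: relative differences use the focal site's value as
#' denominator, so partnership is not necessarily symmetric.
#'
#' @param site one metadata row (the focal site).
#' @param pool metadata of candidate sites (the focal site is excluded if
#'   present).
#' @param tol a \code{\link{match_tolerances}} object.
#' @return character vector of partner site_ids (sorted).
#' @export
find_climate_partners <- function(site, pool, tol = match_tolerances()) {
  if (is.data.frame(site)) site <- as.list(site[1, ])
  pool <- pool[pool$site_id != site$site_id, , drop = FALSE]
  keep <- vapply(seq_len(nrow(pool)), function(j) {
    abs(pool$mat[j] - site$mat) <= tol$mat_abs &&
      rel_ok(site$mean_sw_in, pool$mean_sw_in[j], tol$sw_rel) &&
      rel_ok(site$map, pool$map[j], tol$map_rel) &&
      rel_ok(site$snow_days, pool$snow_days[j], tol$snowdays_rel)
  }, logical(1))
  sort(pool$site_id[keep])
}

#' Balanced improvement score for a candidate partner
#'
#' Projection of the candidate's (albedo, NEP) displacement onto the unit
#' diagonal of the range-normalised plane:
#' x = (1/sqrt(2)) (alpha_new - alpha_site) / (alpha_max - alpha_min)
#'   + (1/sqrt(2)) (NEP_new - NEP_site) / (NEP_max - NEP_min),
#' where the extrema are taken over the whole site network.  x is the
#' relative improvement parallel to the axis connecting the global minima
#' and maxima; the balanced scenario selects the partner with the largest x.
#'
#' @param alpha_site,nep_site focal site values.
#' @param alpha_new,nep_new candidate values (vectorised).
#' @param alpha_range,nep_range numeric length-2 global (min, max).
#' @return dimensionless score x.
#' @export
balanced_score <- function(alpha_site, nep_site, alpha_new, nep_new,
                           alpha_range, nep_range) {
  da <- diff(alpha_range); dn <- diff(nep_range)
  if (da <= 0 || dn <= 0)
    stop("degenerate global albedo or NEP range")
  ((alpha_new - alpha_site) / da + (nep_new - nep_site) / dn) / sqrt(2)
}

#' Assign paired-site permutation scenarios
#'
#' For each site with at least one climate partner, four hypothetical
#' land-use changes are evaluated:
#' \describe{
#'   \item{SC1}{move to the partner with the highest (multi-)annual NEP
#'     (adopting that partner's albedo too);}
#'   \item{SC2}{move to the partner with the highest albedo;}
#'   \item{SC3}{move to the partner with the largest balanced score
#'     (\code{\link{balanced_score}}), accepting the smallest relative
#'     trade-off when every candidate scores negative (set
#'     \code{sc3_require_improvement = TRUE} to stay put instead);}
#'   \item{SC4}{combine SC1's partner NEP with SC2's partner albedo.}
#' }
#' A site whose partners offer no improvement keeps zero deltas but still
#' counts towards ensemble averages; a site without any climate partner is
#' flagged \code{has_partners = FALSE} and excluded from averages.  Ties
#' are broken by the lexicographically smallest partner site_id, making the
#' assignment invariant to input order.
#'
#' @param annual site-level table: site_id, albedo, nep (multi-annual
#'   means).
#' @param meta site metadata used for matching.
#' @param monthly optional monthly climatology (site_id, month, albedo)
#'   used to attach monthly albedo deltas (columns dalb_m1..dalb_m12).
#' @param tol a \code{\link{match_tolerances}} object.
#' @param sc3_require_improvement if TRUE, SC3 keeps zero deltas when no
#'   candidate has positive score.
#' @return data.frame of class \code{scenario_assignments}: one row per
#'   site x scenario with partner ids, delta_nep, delta_albedo, monthly
#'   albedo deltas and has_partners.
#' @export
assign_scenarios <- function(annual, meta, monthly = NULL,
                             tol = match_tolerances(),
                             sc3_require_improvement = FALSE) {
  if (!nrow(annual)) stop("empty annual table")
  annual <- annual[order(annual$site_id), , drop = FALSE]
  meta <- meta[match(annual$site_id, meta$site_id), , drop = FALSE]
  if (anyNA(meta$site_id)) stop("metadata missing for some sites")
  alpha_range <- range(annual$albedo)
  nep_range <- range(annual$nep)

  alb_m <- NULL
  if (!is.null(monthly)) {
    alb_m <- matrix(NA_real_, nrow(annual), 12,
                    dimnames = list(annual$site_id, NULL))
    for (m in 1:12) {
      sel <- monthly$month == m
      alb_m[monthly$site_id[sel], m] <- monthly$albedo[sel]
    }
  }

  pick_best <- function(values, ids) {
    # largest value; ties by smallest site_id (ids are sorted)
    ids[which.max(values)]
  }

  rows <- list()
  for (i in seq_len(nrow(annual))) {
    sid <- annual$site_id[i]
    partners <- find_climate_partners(meta[i, ], meta, tol)
    has <- length(partners) > 0
    pidx <- match(partners, annual$site_id)

    mk <- function(scenario, nep_partner, albedo_partner) {
      dnep <- if (!has) NA_real_
      else if (is.na(nep_partner)) 0
      else annual$nep[match(nep_partner, annual$site_id)] - annual$nep[i]
      dalb <- if (!has) NA_real_
      else if (is.na(albedo_partner)) 0
      else annual$albedo[match(albedo_partner, annual$site_id)] -
        annual$albedo[i]
      out <- data.frame(site_id = sid, scenario = scenario,
                        nep_partner = nep_partner,
                        albedo_partner = albedo_partner,
                        delta_nep = dnep, delta_albedo = dalb,
                        has_partners = has, stringsAsFactors = FALSE)
      if (!is.null(alb_m)) {
        dm <- if (!has) rep(NA_real_, 12)
        else if (is.na(albedo_partner)) rep(0, 12)
        else alb_m[albedo_partner, ] - alb_m[sid, ]
        # months without insolation have undefined albedo at one of the two
        # sites; they carry no albedo change (and a near-zero kernel anyway)
        if (has && !is.na(albedo_partner)) dm[is.na(dm)] <- 0
        out[paste0("dalb_m", 1:12)] <- as.list(dm)
      }
      out
    }

    if (!has) {
      for (sc in c("SC1", "SC2", "SC3", "SC4"))
        rows[[length(rows) + 1L]] <- mk(sc, NA_character_, NA_character_)
      next
    }
    p1 <- pick_best(annual$nep[pidx], partners)
    if (annual$nep[match(p1, annual$site_id)] <= annual$nep[i])
      p1 <- NA_character_
    p2 <- pick_best(annual$albedo[pidx], partners)
    if (annual$albedo[match(p2, annual$site_id)] <= annual$albedo[i])
      p2 <- NA_character_
    x <- balanced_score(annual$albedo[i], annual$nep[i],
                        annual$albedo[pidx], annual$nep[pidx],
                        alpha_range, nep_range)
    p3 <- pick_best(x, partners)
    if (sc3_require_improvement && max(x) < 0) p3 <- NA_character_

    rows[[length(rows) + 1L]] <- mk("SC1", p1, p1)
    rows[[length(rows) + 1L]] <- mk("SC2", p2, p2)
    rows[[length(rows) + 1L]] <- mk("SC3", p3, p3)
    rows[[length(rows) + 1L]] <- mk("SC4", p1, p2)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_assignments", "data.frame")
  out
}

#' Per-scenario ensemble means of the assigned changes
#'
#' Averages the albedo and NEP deltas across all sites that have climate
#' partners (zero-change sites included).
#'
#' @param assignments output of \code{\link{assign_scenarios}}.
#' @return data.frame: scenario, mean_delta_nep, mean_delta_albedo,
#'   n_with_partners, n_sites.
#' @export
scenario_summary <- function(assignments) {
  out <- lapply(split(assignments, assignments$scenario), function(a) {
    w <- a[a$has_partners, , drop = FALSE]
    data.frame(scenario = a$scenario[1],
               mean_delta_nep = if (nrow(w)) mean(w$delta_nep) else NA_real_,
               mean_delta_albedo = if (nrow(w)) mean(w$delta_albedo)
               else NA_real_,
               n_with_partners = nrow(w), n_sites = nrow(a),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
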