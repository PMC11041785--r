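#' Bivariate density analysis of the NEP-albedo trade-off
#'
#' Estimates the univariate kernel densities of albedo and NEP, their
#' bivariate kernel density, the product of the marginals (the expected
#' joint density for uncorrelated variables) and the difference surface
#' joint - product, all on one shared regular grid.  Gaussian kernels with
#' Scott's-rule bandwidths per axis (sd x n^(-1/6)); the same per-axis
#' bandwidths are used for the marginals and the joint so the product
#' surface is the exact independence counterpart of the joint estimate.
#' The grid extends beyond the data range by 10 percent of the range or 4
#' bandwidths, whichever is larger, so all densities integrate to 1 on the
#' grid.
#'
#' @param albedo,nep numeric vectors of equal length (>= 10 finite pairs).
#' @param n_grid grid points per axis.
#' @return an object of class \code{nep_albedo_kde}: list with axes
#'   \code{alpha}, \code{nep}; densities \code{d_alpha}, \code{d_nep}
#'   (vectors), \code{d_joint}, \code{d_prod}, \code{d_diff} (matrices,
#'   albedo x NEP); bandwidths and n.
#' @export
kde_tradeoff <- function(albedo, nep, n_grid = 256L) {
  ok <- is.finite(albedo) & is.finite(nep)
  x <- albedo[ok]; y <- nep[ok]
  n <- length(x)
  if (n < 10) stop("at least 10 finite (albedo, nep) pairs are required")
  bw_x <- sd(x) * n^(-1 / 6)
  bw_y <- sd(y) * n^(-1 / 6)
  if (bw_x <= 0 || bw_y <= 0) stop("degenerate input: zero variance")
  pad_x <- max(0.1 * diff(range(x)), 4 * bw_x)
  pad_y <- max(0.1 * diff(range(y)), 4 * bw_y)
  lim <- c(min(x) - pad_x, max(x) + pad_x, min(y) - pad_y, max(y) + pad_y)
  # marginals evaluated exactly on the grid (same evaluation scheme as the
  # joint estimate in MASS::kde2d)
  gx <- seq(lim[1], lim[2], length.out = n_grid)
  gy <- seq(lim[3], lim[4], length.out = n_grid)
  d_alpha <- rowMeans(stats::dnorm(outer(gx, x, "-") / bw_x)) / bw_x
  d_nep <- rowMeans(stats::dnorm(outer(gy, y, "-") / bw_y)) / bw_y
  joint <- MASS::kde2d(x, y, h = c(4 * bw_x, 4 * bw_y), n = n_grid,
                       lims = lim)
  d_prod <- outer(d_alpha, d_nep)
  structure(list(alpha = joint$x, nep = joint$y,
                 d_alpha = d_alpha, d_nep = d_nep,
                 d_joint = joint$z, d_prod = d_prod,
                 d_diff = joint$z - d_prod,
                 bw = c(alpha = bw_x, nep = bw_y), n = n),
            class = "nep_albedo_kde")
}

#' Grid-quadrature integrals of a density analysis
#'
#' @param kde a \code{\link{kde_tradeoff}} object.
#' @return named vector with the integrals of the two marginals, the joint,
#'   the product and the difference surface (rectangle rule).
#' @export
kde_integrals <- function(kde) {
  da <- diff(kde$alpha[1:2]); dn <- diff(kde$nep[1:2])
  c(alpha = sum(kde$d_alpha) * da,
    nep = sum(kde$d_nep) * dn,
    joint = sum(kde$d_joint) * da * dn,
    prod = sum(kde$d_prod) * da * dn,
    diff = sum(kde$d_diff) * da * dn)
}

#' @export
print.nep_albedo_kde <- function(x, ...) {
  ints <- kde_integrals(x)
  cat("NEP-albedo kernel density analysis\n")
  cat(sprintf("  n = %d points, grid %d x %d\n", x$n, length(x$alpha),
              length(x$nep)))
  cat(sprintf("  bandwidths: albedo %.4g, NEP %.4g\n", x$bw[1], x$bw[2]))
  cat(sprintf("  integrals: joint %.4f, product %.4f, difference %+.2e\n",
              ints["joint"], ints["prod"], ints["diff"]))
  cat(sprintf("  max |difference| / max joint = %.3f\n",
              max(abs(x$d_diff)) / max(x$d_joint)))
  invisible(x)
}

#' Spearman rank correlation with large-sample p-value
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' from the large-sample approximation.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return list with \code{rho}, \code{p} and \code{n}.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 complete pairs are required")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Monthly NEP-albedo trade-off table
#'
#' One row per site-month from the monthly climatologies, with the site's
#' IGBP class and monthly fAPAR attached, plus the annual site values
#' rescaled to gC m-2 month-1 (annual NEP / 12) for overlay.
#'
#' @param monthly monthly climatology table (site_id, month, albedo, nep,
#'   optionally fapar).
#' @param annual site-level annual table (site_id, albedo, nep in
#'   gC m-2 yr-1).
#' @param meta site metadata (for IGBP classes).
#' @return list with \code{monthly} (site_id, month, albedo, nep, fapar,
#'   igbp) and \code{annual} (site_id, albedo, nep_month, igbp).
#' @export
monthly_tradeoff <- function(monthly, annual, meta) {
  igbp <- setNames(meta$igbp, meta$site_id)
  m <- monthly[, intersect(c("site_id", "month", "albedo", "nep", "fapar"),
                           names(monthly))]
  if (is.null(m$fapar)) m$fapar <- NA_real_
  m$igbp <- unname(igbp[m$site_id])
  a <- data.frame(site_id = annual$site_id, albedo = annual$albedo,
                  nep_month = annual$nep / 12,
                  igbp = unname(igbp[annual$site_id]),
                  stringsAsFactors = FALSE)
  list(monthly = m, annual = a)
}

#' Theoretical NEP maximum from absorbed PAR energy
#'
#' Upper bound on monthly NEP if all absorbed photosynthetically active
#' radiation of an assumed 100 W m-2 PAR flux were used for CO2
#' sequestration: NEP_max = (1 - albedo) x PAR / 0.469 J umol-1, converted
#' to gC m-2 month-1 with a 30.44-day month.  The absorbed fraction is
#' taken as (1 - albedo) of the assumed PAR flux.
#'
#' @param albedo dimensionless, in [0, 1).
#' @param par_flux assumed PAR energy flux, W m-2.
#' @return gC m-2 month-1 (vectorised).
#' @export
theoretical_par_max <- function(albedo, par_flux = 100) {
  if (any(albedo < 0) || any(albedo >= 1))
    stop("albedo must lie in [0, 1)")
  umol_s <- (1 - albedo) * par_flux / ENERGY_INTENSITY_PHOTO
  umol_s * 30.44 * 86400 * MOLAR_MASS_C * 1e-6
}

#' Attainable-annual-value envelope from monthly states
#'
#' If monthly (albedo, NEP) states could be freely combined under constant
#' SW_IN, every attainable annual value is a convex combination of monthly
#' points, so the attainable set is their convex hull and the trade-off
#' frontier is the hull's upper-left boundary.  Returns the upper concave
#' chain from the lowest to the highest albedo.
#'
#' @param albedo,nep coordinates of the monthly points (>= 3, or 2 for a
#'   degenerate segment).
#' @return data.frame of boundary vertices (albedo, nep), ordered by
#'   albedo, with an \code{\link{envelope_value}} evaluator.
#' @export
annual_combination_envelope <- function(albedo, nep) {
  ok <- is.finite(albedo) & is.finite(nep)
  x <- albedo[ok]; y <- nep[ok]
  if (length(x) < 2) stop("at least 2 points are required")
  # keep only the max-NEP point at duplicated albedo values
  o <- order(x, -y)
  x <- x[o]; y <- y[o]
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 1)
    return(data.frame(albedo = x, nep = y))
  # Andrew's monotone chain, upper hull; near-collinear vertices (within
  # floating-point slack of the chord) are treated as collinear and dropped
  eps <- 1e-9 * diff(range(x)) * max(diff(range(y)), 1e-300)
  hx <- numeric(0); hy <- numeric(0)
  for (i in seq_along(x)) {
    while (length(hx) >= 2) {
      m <- length(hx)
      cross <- (hx[m] - hx[m - 1]) * (y[i] - hy[m - 1]) -
        (hy[m] - hy[m - 1]) * (x[i] - hx[m - 1])
      if (cross >= -eps) { hx <- hx[-m]; hy <- hy[-m] } else break
    }
    hx <- c(hx, x[i]); hy <- c(hy, y[i])
  }
  data.frame(albedo = hx, nep = hy)
}

#' Evaluate a combination envelope at given albedo values
#'
#' Linear interpolation along the envelope boundary; NA outside its albedo
#' range.
#'
#' @param env output of \code{\link{annual_combination_envelope}}.
#' @param albedo query points.
#' @return envelope NEP values.
#' @export
envelope_value <- function(env, albedo) {
  if (nrow(env) == 1)
    return(ifelse(albedo == env$albedo, env$nep, NA_real_))
  approx(env$albedo, env$nep, xout = albedo, rule = 1)$y
}

#' Rank correlations of site covariates with albedo
#'
#' Spearman correlations of site-mean albedo against fAPAR, the
#' photosynthetic energy fraction E_GPP, canopy height h_c, and
#' canopy-height-scaled ecosystem respiration R_eco / h_c.  Sites missing a
#' covariate are excluded pairwise for that covariate only; a missing
#' canopy height drops the site from both h_c panels.
#'
#' @param sites data.frame with columns albedo and any of fapar, egpp,
#'   canopy_height, reco (annual R_eco, gC m-2 yr-1).
#' @return data.frame (covariate, rho, p, n).
#' @export
covariate_correlations <- function(sites) {
  covs <- list(fapar = sites$fapar, egpp = sites$egpp,
               canopy_height = sites$canopy_height,
               reco_per_height = if (!is.null(sites$reco) &&
                                     !is.null(sites$canopy_height))
                 sites$reco / sites$canopy_height else NULL)
  covs <- covs[!vapply(covs, is.null, logical(1))]
  if (!length(covs)) stop("no covariates available")
  rows <- lapply(names(covs), function(nm) {
    v <- covs[[nm]]
    ok <- is.finite(v) & is.finite(sites$albedo)
    if (sum(ok) < 3)
      stop("covariate ", nm, ": fewer than 3 complete pairs")
    sc <- spearman_cor(v[ok], sites$albedo[ok])
    data.frame(covariate = nm, rho = sc$rho, p = sc$p, n = sc$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
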