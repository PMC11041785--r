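#' Processing thresholds for albedo windows and snow detection
#'
#' @param drift_tol absolute albedo drift tolerated within a stable window:
#'   a new day whose daytime flux-ratio albedo deviates from the running
#'   window albedo by at least this much starts a new window.
#' @param swin_floor minimum SW_IN (W m-2) for a record to count as daytime
#'   when forming instantaneous albedo ratios (avoids dawn/dusk blow-up).
#' @param snow_albedo_min,snow_tmax a window is flagged as snow / hoar frost
#'   when its albedo is at least \code{snow_albedo_min} and its minimum
#'   half-hourly air temperature is at most \code{snow_tmax} (degrees C).
#' @return a list of class \code{process_config}.
#' @export
process_config <- function(drift_tol = 0.03, swin_floor = 20,
                           snow_albedo_min = 0.30, snow_tmax = 0.5) {
  structure(list(drift_tol = drift_tol, swin_floor = swin_floor,
                 snow_albedo_min = snow_albedo_min, snow_tmax = snow_tmax),
            class = "process_config")
}

#' Detect periods of approximately constant albedo
#'
#' Screens the joint SW_IN / SW_OUT series for time windows of approximately
#' constant surface albedo.  A window grows day by day while each new day's
#' daytime flux-ratio albedo (sum SW_OUT / sum SW_IN over records with
#' SW_IN >= \code{swin_floor} and non-missing SW_OUT) stays within
#' \code{drift_tol} of the running window albedo; days without any daytime
#' SW_OUT observation extend the current window.  When a day breaks the
#' tolerance, the boundary is refined to the first deviating daytime
#' half-hour of that day (or the start of the day when it deviates from its
#' first daytime record onwards), so the windows partition the timeline at
#' half-hour resolution.
#'
#' @param series a \code{flux_series} data.frame; \code{sw_in} must be
#'   gap-free (the source product provides it gap-filled).
#' @param cfg a \code{\link{process_config}}.
#' @return a data.frame of class \code{albedo_windows} with one row per
#'   window: start/end timestamps (end exclusive), row range, albedo
#'   (flux-weighted; NA if the window has no daytime pair), minimum air
#'   temperature and record count.  Empty (with a warning) when the series
#'   has no daytime records.
#' @export
detect_stable_windows <- function(series, cfg = process_config()) {
  if (anyNA(series$sw_in))
    stop("sw_in contains missing values; it must be pre-gap-filled")
  n <- nrow(series)
  pair <- series$sw_in >= cfg$swin_floor & !is.na(series$sw_out)
  if (!any(pair)) {
    warning("series has no daytime SW_IN/SW_OUT pairs; no windows detected")
    return(empty_windows(series))
  }
  day_idx <- cumsum(c(TRUE, diff(as.integer(
    format(series$timestamp, "%Y%m%d", tz = "UTC"))) != 0))
  nd <- max(day_idx)
  din <- rowsum(ifelse(pair, series$sw_in, 0), day_idx)[, 1]
  dout <- rowsum(ifelse(pair, series$sw_out, 0), day_idx)[, 1]
  day_first <- match(seq_len(nd), day_idx)
  day_last <- c(day_first[-1] - 1L, n)

  starts <- integer(0); ends <- integer(0)
  win_start <- 1L; w_in <- 0; w_out <- 0
  for (d in seq_len(nd)) {
    if (din[d] <= 0) next
    if (w_in <= 0) { w_in <- din[d]; w_out <- dout[d]; next }
    albw <- w_out / w_in
    if (abs(dout[d] / din[d] - albw) < cfg$drift_tol) {
      w_in <- w_in + din[d]; w_out <- w_out + dout[d]
      next
    }
    rows <- day_first[d]:day_last[d]
    prow <- rows[pair[rows]]
    dev <- abs(series$sw_out[prow] / series$sw_in[prow] - albw) >=
      cfg$drift_tol
    split <- if (which(dev)[1] == 1L) day_first[d] else prow[which(dev)[1]]
    starts <- c(starts, win_start); ends <- c(ends, split - 1L)
    win_start <- split
    rest <- split:day_last[d]
    prest <- rest[pair[rest]]
    w_in <- sum(series$sw_in[prest]); w_out <- sum(series$sw_out[prest])
  }
  starts <- c(starts, win_start); ends <- c(ends, n)

  win <- data.frame(start_row = starts, end_row = ends)
  win$start <- series$timestamp[win$start_row]
  win$end <- series$timestamp[win$end_row] + 1800
  stats_w <- lapply(seq_len(nrow(win)), function(i) {
    rows <- win$start_row[i]:win$end_row[i]
    p <- rows[pair[rows]]
    c(albedo = if (length(p)) sum(series$sw_out[p]) / sum(series$sw_in[p])
      else NA_real_,
      t_min = if (all(is.na(series$tair[rows]))) NA_real_
      else min(series$tair[rows], na.rm = TRUE),
      n_records = length(rows))
  })
  stats_w <- do.call(rbind, stats_w)
  win$albedo <- stats_w[, "albedo"]
  win$t_min <- stats_w[, "t_min"]
  win$n_records <- as.integer(stats_w[, "n_records"])
  attr(win, "site_id") <- attr(series, "site_id")
  class(win) <- c("albedo_windows", "data.frame")
  win
}

empty_windows <- function(series) {
  win <- data.frame(start_row = integer(), end_row = integer(),
                    start = as.POSIXct(character()),
                    end = as.POSIXct(character()),
                    albedo = numeric(), t_min = numeric(),
                    n_records = integer())
  attr(win, "site_id") <- attr(series, "site_id")
  class(win) <- c("albedo_windows", "data.frame")
  win
}

#' Impute missing SW_OUT from stable-albedo windows
#'
#' Each missing SW_OUT is replaced by the albedo of its stable window times
#' the concurrent SW_IN (exactly zero at night), which leaves the window's
#' flux-weighted albedo unchanged and therefore keeps annual albedo
#' unbiased.  Non-missing values are untouched; imputed records are flagged
#' in a new logical column \code{swout_imputed}.
#'
#' @param series a \code{flux_series} data.frame.
#' @param windows output of \code{\link{detect_stable_windows}} for the same
#'   series; must partition the timeline.
#' @return the series with \code{sw_out} gap-filled.
#' @export
impute_swout <- function(series, windows) {
  n <- nrow(series)
  miss <- which(is.na(series$sw_out))
  if (!length(miss)) {
    series$swout_imputed <- rep(FALSE, n)
    return(series)
  }
  if (!nrow(windows) || windows$start_row[1] != 1L ||
      windows$end_row[nrow(windows)] != n ||
      (nrow(windows) > 1 &&
       any(windows$start_row[-1] != windows$end_row[-nrow(windows)] + 1L)))
    stop("windows do not cover the timeline; cannot impute sw_out")
  widx <- findInterval(miss, windows$start_row)
  alb <- windows$albedo[widx]
  sw_in <- series$sw_in[miss]
  bad <- is.na(alb) & sw_in > 0
  if (any(bad))
    stop("missing sw_out in a window with undefined albedo")
  filled <- ifelse(sw_in > 0, alb * sw_in, 0)
  series$sw_out[miss] <- filled
  series$swout_imputed <- rep(FALSE, n)
  series$swout_imputed[miss] <- TRUE
  series
}

#' Flag snow or hoar-frost windows
#'
#' A window is snow-affected when its albedo is at least
#' \code{snow_albedo_min} and its minimum half-hourly temperature is at most
#' \code{snow_tmax} (both from \code{\link{process_config}}; defaults 0.30
#' and 0.5 degrees C).
#'
#' @param windows an \code{albedo_windows} data.frame.
#' @param cfg a \code{\link{process_config}}.
#' @return logical vector, one flag per window.
#' @export
classify_snow <- function(windows, cfg = process_config()) {
  !is.na(windows$albedo) & !is.na(windows$t_min) &
    windows$albedo >= cfg$snow_albedo_min & windows$t_min <= cfg$snow_tmax
}

#' Assign the active / dormant / snow condition of each window
#'
#' Snow takes precedence; snow-free windows are active when their NEP is
#' positive and dormant when NEP <= 0.
#'
#' @param windows an \code{albedo_windows} data.frame.
#' @param snow logical snow flags (\code{\link{classify_snow}}).
#' @param nep window NEP totals (gC m-2), e.g. from
#'   \code{\link{aggregate_nep}} per window; NA gives condition NA for
#'   snow-free windows.
#' @return character vector in \{"active", "dormant", "snow"\}.
#' @export
classify_condition <- function(windows, snow, nep) {
  out <- ifelse(snow, "snow",
                ifelse(is.na(nep), NA_character_,
                       ifelse(nep > 0, "active", "dormant")))
  out
}

#' Flux-weighted albedo of a time interval
#'
#' The interval albedo is the ratio of summed SW_OUT to summed SW_IN over
#' pairwise-available records, equivalent to a flux-weighted average of
#' instantaneous albedo and deliberately different from the arithmetic mean
#' of instantaneous ratios.
#'
#' @param series a \code{flux_series} data.frame (gap-filled SW_OUT for
#'   unbiased annual values).
#' @param rows optional logical or integer row selection (default: all).
#' @return dimensionless albedo.
#' @export
aggregate_albedo <- function(series, rows = NULL) {
  s <- if (is.null(rows)) series else series[rows, , drop = FALSE]
  ok <- !is.na(s$sw_in) & !is.na(s$sw_out)
  total_in <- sum(s$sw_in[ok])
  if (!any(ok) || total_in <= 0)
    stop("albedo undefined: interval has no incoming shortwave radiation")
  sum(s$sw_out[ok]) / total_in
}

#' NEP total of a time interval
#'
#' NEP = -NEE summed over half-hours and converted to gC m-2 using 1800 s
#' per record and 12.011 g mol-1.
#'
#' @inheritParams aggregate_albedo
#' @return NEP in gC m-2 over the interval (positive = uptake).
#' @export
aggregate_nep <- function(series, rows = NULL) {
  s <- if (is.null(rows)) series else series[rows, , drop = FALSE]
  if (!nrow(s)) stop("empty interval")
  if (anyNA(s$nee)) stop("nee contains missing values; gap-fill first")
  sum(-s$nee) * UMOL_TO_GC
}

#' Fraction of non-reflected shortwave radiation used by photosynthesis
#'
#' E_GPP = 0.469 J umol-1 x sum(GPP) / sum(SW_IN - SW_OUT), a unitless
#' fraction comparing the energy fixed by gross photosynthesis to the
#' absorbed (non-reflected) incoming shortwave radiation.
#'
#' @inheritParams aggregate_albedo
#' @return unitless fraction.
#' @export
compute_egpp <- function(series, rows = NULL) {
  s <- if (is.null(rows)) series else series[rows, , drop = FALSE]
  ok <- !is.na(s$gpp) & !is.na(s$sw_in) & !is.na(s$sw_out)
  if (!any(ok)) stop("gpp is not available for this interval")
  sw_net <- sum(s$sw_in[ok] - s$sw_out[ok])
  if (sw_net <= 0) stop("non-positive SW_net; E_GPP undefined")
  ENERGY_INTENSITY_PHOTO * sum(s$gpp[ok]) / sw_net
}

expected_records <- function(year) {
  if ((year %% 4 == 0 && year %% 100 != 0) || year %% 400 == 0)
    17568L else 17520L
}

#' Screen for full calendar years and compute annual aggregates
#'
#' Only full calendar years of successfully gap-filled data are retained:
#' a year is complete when it holds every half-hour of the calendar year and
#' the core variables (SW_IN, gap-filled SW_OUT, NEE) contain no remaining
#' missing values.  Incomplete years are reported with \code{complete =
#' FALSE} and NA aggregates; a warning is raised when a site retains no
#' complete year.
#'
#' @param series_list list of (imputed) \code{flux_series}, one per year.
#' @param site_id site identifier for the output rows.
#' @return data.frame with columns site_id, year, nep (gC m-2 yr-1), albedo
#'   (flux-weighted) and complete.
#' @export
screen_full_years <- function(series_list, site_id = NULL) {
  rows <- lapply(series_list, function(s) {
    year <- attr(s, "year")
    if (is.null(year))
      year <- as.integer(format(s$timestamp[1], "%Y", tz = "UTC"))
    complete <- nrow(s) == expected_records(year) &&
      !anyNA(s$sw_in) && !anyNA(s$sw_out) && !anyNA(s$nee)
    data.frame(site_id = site_id %||% attr(s, "site_id") %||% NA_character_,
               year = year,
               nep = if (complete) aggregate_nep(s) else NA_real_,
               albedo = if (complete) aggregate_albedo(s) else NA_real_,
               complete = complete, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$complete))
    warning("site ", out$site_id[1] %||% "?",
            ": no complete calendar years; site dropped from",
            " cross-site statistics")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fill missing MAT / MAP metadata from the measured series
#'
#' Sites whose long-term mean annual temperature or precipitation is missing
#' receive the mean annual temperature and precipitation of their own time
#' series instead.
#'
#' @param meta a \code{site_meta} data.frame.
#' @param series_by_site named list (site_id -> list of \code{flux_series}).
#' @return the metadata with \code{mat}/\code{map} gaps filled.
#' @export
fill_missing_meta <- function(meta, series_by_site) {
  for (i in seq_len(nrow(meta))) {
    sid <- meta$site_id[i]
    sl <- series_by_site[[sid]]
    if (is.null(sl)) next
    if (is.na(meta$mat[i]))
      meta$mat[i] <- mean(vapply(sl, function(s)
        mean(s$tair, na.rm = TRUE), numeric(1)))
    if (!is.null(meta$map) && is.na(meta$map[i]))
      meta$map[i] <- mean(vapply(sl, function(s)
        sum(s$precip, na.rm = TRUE), numeric(1)))
  }
  meta
}

#' Aggregate 4-day fAPAR records to monthly means
#'
#' Records failing quality control (non-zero QC bits) are dropped, the rest
#' averaged per calendar month; interior monthly gaps are linearly
#' interpolated in time (leading/trailing gaps remain NA).
#'
#' @param fapar data.frame with columns \code{date}, \code{fapar},
#'   \code{qc} (0 = good).
#' @return data.frame with columns year, month, fapar.
#' @export
aggregate_fapar <- function(fapar) {
  ok <- fapar$qc == 0 & !is.na(fapar$fapar)
  if (!any(ok)) stop("all fAPAR records fail quality control")
  f <- fapar[ok, , drop = FALSE]
  ym <- format(as.Date(f$date), "%Y-%m")
  span <- seq(as.Date(paste0(min(ym), "-01")),
              as.Date(paste0(max(ym), "-01")), by = "month")
  key <- format(span, "%Y-%m")
  means <- tapply(f$fapar, ym, mean)
  val <- as.numeric(means[key])
  if (anyNA(val) && sum(!is.na(val)) >= 2) {
    idx <- seq_along(val)
    val <- approx(idx[!is.na(val)], val[!is.na(val)], xout = idx,
                  rule = 1)$y
  }
  data.frame(year = as.integer(substr(key, 1, 4)),
             month = as.integer(substr(key, 6, 7)),
             fapar = val)
}

#' Monthly climatology of albedo, NEP and SW_IN
#'
#' For each calendar month the albedo is the flux-weighted ratio pooled over
#' all complete years, NEP the mean monthly total (gC m-2 month-1) and
#' SW_IN the mean flux density, averaging across all available years.
#'
#' @param series_list list of complete, imputed \code{flux_series}.
#' @param site_id site identifier.
#' @param fapar optional monthly fAPAR (data.frame month, fapar or output of
#'   \code{\link{aggregate_fapar}}, averaged over years).
#' @return data.frame site_id, month, albedo, nep, sw_in, fapar.
#' @export
monthly_climatology <- function(series_list, site_id = NULL, fapar = NULL) {
  acc_out <- acc_in <- nep_sum <- sw_sum <- numeric(12)
  nyr <- length(series_list)
  for (s in series_list) {
    mon <- as.integer(format(s$timestamp, "%m", tz = "UTC"))
    for (m in 1:12) {
      rows <- mon == m
      acc_in[m] <- acc_in[m] + sum(s$sw_in[rows])
      acc_out[m] <- acc_out[m] + sum(s$sw_out[rows])
      nep_sum[m] <- nep_sum[m] + aggregate_nep(s, rows)
      sw_sum[m] <- sw_sum[m] + mean(s$sw_in[rows])
    }
  }
  out <- data.frame(site_id = site_id %||%
                      attr(series_list[[1]], "site_id") %||% NA_character_,
                    month = 1:12,
                    albedo = acc_out / acc_in,
                    nep = nep_sum / nyr,
                    sw_in = sw_sum / nyr,
                    stringsAsFactors = FALSE)
  if (!is.null(fapar)) {
    fm <- if ("year" %in% names(fapar))
      tapply(fapar$fapar, fapar$month, mean, na.rm = TRUE)
    else setNames(fapar$fapar, fapar$month)
    out$fapar <- as.numeric(fm[as.character(out$month)])
  } else out$fapar <- NA_real_
  out
}

#' Full per-site processing: windows, snow, imputation, conditions
#'
#' Runs the window detection, snow classification, SW_OUT imputation and
#' condition assignment for one site-year and returns both the gap-filled
#' series and the labelled windows.
#'
#' @param series a \code{flux_series} data.frame.
#' @param cfg a \code{\link{process_config}}.
#' @return list with \code{series} (imputed) and \code{windows} (with
#'   columns snow, nep, nep_month and condition added).
#' @export
process_site <- function(series, cfg = process_config()) {
  windows <- detect_stable_windows(series, cfg)
  if (!nrow(windows)) return(list(series = series, windows = windows))
  series <- impute_swout(series, windows)
  windows$snow <- classify_snow(windows, cfg)
  windows$nep <- vapply(seq_len(nrow(windows)), function(i) {
    rows <- windows$start_row[i]:windows$end_row[i]
    if (anyNA(series$nee[rows])) NA_real_ else aggregate_nep(series, rows)
  }, numeric(1))
  hours_per_month <- 30.44 * 24
  windows$nep_month <- windows$nep * hours_per_month /
    (windows$n_records * 0.5)
  windows$condition <- classify_condition(windows, windows$snow, windows$nep)
  windows$sw_in_sum <- vapply(seq_len(nrow(windows)), function(i) {
    rows <- windows$start_row[i]:windows$end_row[i]
    ok <- !is.na(series$sw_out[rows])
    sum(series$sw_in[rows][ok])
  }, numeric(1))
  windows$sw_out_sum <- vapply(seq_len(nrow(windows)), function(i) {
    rows <- windows$start_row[i]:windows$end_row[i]
    sum(series$sw_out[rows], na.rm = TRUE)
  }, numeric(1))
  list(series = series, windows = windows)
}
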