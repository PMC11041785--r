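#' Write a half-hourly series as a FLUXNET2015-dialect CSV
#'
#' One row per half-hour with columns TIMESTAMP_START, TIMESTAMP_END
#' (YYYYMMDDHHMM), NEE_VUT_REF, SW_IN_F, SW_OUT, TA_F, P, GPP, RECO.
#' Missing values are written as the sentinel -9999.
#'
#' @param series a \code{flux_series} data.frame (see
#'   \code{\link{generate_halfhourly}}).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_fluxnet_csv <- function(series, path) {
  ts <- series$timestamp
  out <- data.frame(
    TIMESTAMP_START = format(ts, "%Y%m%d%H%M", tz = "UTC"),
    TIMESTAMP_END = format(ts + 1800, "%Y%m%d%H%M", tz = "UTC"),
    NEE_VUT_REF = series$nee,
    SW_IN_F = series$sw_in,
    SW_OUT = series$sw_out,
    TA_F = series$tair,
    P = if (!is.null(series$precip)) series$precip else NA_real_,
    GPP = if (!is.null(series$gpp)) series$gpp else NA_real_,
    RECO = if (!is.null(series$reco)) series$reco else NA_real_)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    x <- round(x, 5)
    x[is.na(x)] <- FLUXNET_SENTINEL
    x
  })
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FLUXNET2015-dialect half-hourly CSV
#'
#' Inverse of \code{\link{write_fluxnet_csv}}: parses TIMESTAMP_START as the
#' interval-start timestamp and converts every -9999 sentinel to NA.
#'
#' @param path file path.
#' @param site_id optional site identifier attached as an attribute.
#' @return a \code{flux_series} data.frame.
#' @export
read_fluxnet_csv <- function(path, site_id = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(TIMESTAMP_START = "character",
                                 TIMESTAMP_END = "character"))
  need <- c("TIMESTAMP_START", "TIMESTAMP_END", "NEE_VUT_REF", "SW_IN_F",
            "SW_OUT", "TA_F")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  desent <- function(x) { x[!is.na(x) & x == FLUXNET_SENTINEL] <- NA; x }
  series <- data.frame(
    timestamp = as.POSIXct(raw$TIMESTAMP_START, format = "%Y%m%d%H%M",
                           tz = "UTC"),
    sw_in = desent(raw$SW_IN_F),
    sw_out = desent(raw$SW_OUT),
    nee = desent(raw$NEE_VUT_REF),
    gpp = if ("GPP" %in% names(raw)) desent(raw$GPP) else NA_real_,
    reco = if ("RECO" %in% names(raw)) desent(raw$RECO) else NA_real_,
    tair = desent(raw$TA_F),
    precip = if ("P" %in% names(raw)) desent(raw$P) else NA_real_)
  if (anyNA(series$timestamp)) stop("malformed TIMESTAMP_START values")
  if (nrow(series) > 1) {
    dt <- diff(as.numeric(series$timestamp))
    if (any(dt != 1800))
      stop("timestamps are not a uniform half-hourly grid")
  }
  if (any(series$sw_in < 0, na.rm = TRUE) ||
      any(series$sw_out < 0, na.rm = TRUE))
    stop("negative shortwave radiation values")
  attr(series, "site_id") <- site_id
  class(series) <- c("flux_series", "data.frame")
  series
}

#' Write and read the site-metadata table
#'
#' Plain CSV with one row per site; NA fields written empty.
#'
#' @param meta a \code{site_meta} data.frame.
#' @param path file path.
#' @return \code{write_site_metadata}: the path invisibly;
#'   \code{read_site_metadata}: a \code{site_meta} data.frame.
#' @export
write_site_metadata <- function(meta, path) {
  write.csv(as.data.frame(meta), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_metadata
#' @export
read_site_metadata <- function(path) {
  meta <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "igbp", "mat", "map", "mean_sw_in", "snow_days")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(meta$igbp), IGBP_CLASSES)
  if (length(bad))
    stop("unknown IGBP classes: ", paste(bad, collapse = ", "))
  class(meta) <- c("site_meta", "data.frame")
  meta
}
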