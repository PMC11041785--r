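# Independent exhaustive reference for the paired-site scenarios: plain
# double loops, no shared code with the package implementation.

oracle_partners <- function(i, meta, mat_abs = 1.5, rel = 0.2) {
  out <- character(0)
  for (j in seq_len(nrow(meta))) {
    if (j == i) next
    if (abs(meta$mat[j] - meta$mat[i]) > mat_abs) next
    ok <- TRUE
    for (v in c("mean_sw_in", "map", "snow_days")) {
      fi <- meta[[v]][i]; fj <- meta[[v]][j]
      if (fi == 0) {
        if (fj != 0) { ok <- FALSE; break }
      } else if (abs(fj - fi) / abs(fi) > rel) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, meta$site_id[j])
  }
  sort(out)
}

oracle_assign <- function(annual, meta, mat_abs = 1.5, rel = 0.2) {
  o <- order(annual$site_id)
  annual <- annual[o, , drop = FALSE]
  meta <- meta[match(annual$site_id, meta$site_id), , drop = FALSE]
  a_rng <- range(annual$albedo); n_rng <- range(annual$nep)
  rows <- list()
  for (i in seq_len(nrow(annual))) {
    partners <- oracle_partners(i, meta, mat_abs, rel)
    has <- length(partners) > 0
    best <- function(crit) {
      # largest criterion value; first (smallest) id wins ties
      bi <- NULL; bv <- -Inf
      for (pid in partners) {
        v <- crit(match(pid, annual$site_id))
        if (v > bv) { bv <- v; bi <- pid }
      }
      list(id = bi, value = bv)
    }
    if (!has) {
      for (sc in c("SC1", "SC2", "SC3", "SC4"))
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = annual$site_id[i], scenario = sc,
          nep_partner = NA_character_, albedo_partner = NA_character_,
          delta_nep = NA_real_, delta_albedo = NA_real_,
          has_partners = FALSE, stringsAsFactors = FALSE)
      next
    }
    b1 <- best(function(j) annual$nep[j])
    p1 <- if (b1$value > annual$nep[i]) b1$id else NA_character_
    b2 <- best(function(j) annual$albedo[j])
    p2 <- if (b2$value > annual$albedo[i]) b2$id else NA_character_
    b3 <- best(function(j)
      ((annual$albedo[j] - annual$albedo[i]) / diff(a_rng) +
         (annual$nep[j] - annual$nep[i]) / diff(n_rng)) / sqrt(2))
    p3 <- b3$id
    d <- function(pid, col) {
      if (is.na(pid)) 0
      else annual[[col]][match(pid, annual$site_id)] - annual[[col]][i]
    }
    add <- function(sc, pn, pa)
      rows[[length(rows) + 1L]] <<- data.frame(
        site_id = annual$site_id[i], scenario = sc, nep_partner = pn,
        albedo_partner = pa, delta_nep = d(pn, "nep"),
        delta_albedo = d(pa, "albedo"), has_partners = TRUE,
        stringsAsFactors = FALSE)
    add("SC1", p1, p1)
    add("SC2", p2, p2)
    add("SC3", p3, p3)
    add("SC4", p1, p2)
  }
  do.call(rbind, rows)
}

# Minimal hand-built half-hourly series: `alpha_by_day` true albedo per day,
# daytime block of constant SW_IN, optional temperature.
make_series <- function(alpha_by_day, sw_day = 500, tair = 10,
                        day_hours = 8:15, year = 2019) {
  n_days <- length(alpha_by_day)
  ts0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  n <- n_days * 48L
  timestamp <- ts0 + (seq_len(n) - 1L) * 1800
  hour <- rep(0:47, n_days) / 2
  sw_in <- ifelse(hour %in% day_hours, sw_day, 0)
  alpha <- rep(alpha_by_day, each = 48L)
  s <- data.frame(timestamp = timestamp, sw_in = sw_in,
                  sw_out = alpha * sw_in, nee = 0, gpp = 0, reco = 0,
                  tair = rep_len(tair, n), precip = 0)
  class(s) <- c("flux_series", "data.frame")
  s
}
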