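test_that("stable windows split at albedo change points", {
  s <- make_series(c(rep(0.2, 5), rep(0.4, 5)))
  w <- detect_stable_windows(s)
  expect_equal(nrow(w), 2)
  truth_change <- s$timestamp[5 * 48 + 1]
  expect_lte(abs(as.numeric(w$start[2]) - as.numeric(truth_change)), 1800)
  expect_equal(w$albedo, c(0.2, 0.4), tolerance = 1e-12)
  # windows partition the timeline
  expect_equal(w$start_row[1], 1L)
  expect_equal(w$end_row[2], nrow(s))
  expect_equal(w$start_row[2], w$end_row[1] + 1L)
})

test_that("constant albedo yields a single window; all-night series none", {
  s <- make_series(rep(0.25, 7))
  w <- detect_stable_windows(s)
  expect_equal(nrow(w), 1)
  expect_equal(w$albedo, 0.25, tolerance = 1e-12)
  expect_equal(w$n_records, nrow(s))

  night <- make_series(rep(0.25, 3))
  night$sw_in[] <- 0; night$sw_out[] <- 0
  expect_warning(w0 <- detect_stable_windows(night), "no daytime")
  expect_equal(nrow(w0), 0)
  expect_error(detect_stable_windows(transform(night, sw_in = NA)),
               "gap-filled")
})

test_that("an intra-day albedo jump is located to the half-hour", {
  s <- make_series(rep(0.2, 6))
  jump <- 3 * 48 + 25   # noon of day 4
  s$sw_out[jump:nrow(s)] <- 0.45 * s$sw_in[jump:nrow(s)]
  w <- detect_stable_windows(s)
  expect_equal(nrow(w), 2)
  expect_equal(w$start_row[2], jump)
})

test_that("imputation is exact for forced cases and identity without gaps", {
  s <- make_series(rep(0.25, 4))
  w <- detect_stable_windows(s)
  s2 <- impute_swout(s, w)
  expect_equal(s2$sw_out, s$sw_out)
  expect_false(any(s2$swout_imputed))

  gap <- which(s$sw_in == 500)[10]
  s$sw_in[gap] <- 400
  s$sw_out[gap] <- NA
  w <- detect_stable_windows(s)
  s3 <- impute_swout(s, w)
  expect_equal(s3$sw_out[gap], 100)        # 0.25 x 400
  expect_true(s3$swout_imputed[gap])

  # coverage violation: windows that stop short of the end
  w_cut <- w[1, , drop = FALSE]
  w_cut$end_row <- gap - 5L
  expect_error(impute_swout(s, w_cut), "cover")
})

test_that("imputation leaves annual albedo unbiased under 30% gaps", {
  errs <- vapply(1:5, function(seed) {
    p <- generator_params(seed = seed, gap_fraction = 0.3)
    meta <- generate_site_metadata(p)
    g <- generate_halfhourly(meta[1, ], 2015, p)
    pr <- process_site(g$series)
    aggregate_albedo(pr$series) - g$truth$albedo
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.003)
})

test_that("snow classification follows the albedo/temperature thresholds", {
  w <- data.frame(albedo = c(0.45, 0.45, 0.20, 0.30, NA),
                  t_min = c(-3, 10, -5, 0.5, -3))
  expect_equal(classify_snow(w), c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("condition assignment: snow wins, NEP = 0 is dormant", {
  w <- data.frame(albedo = 0.4, t_min = -1)
  expect_equal(classify_condition(w[c(1, 1, 1), ],
                                  snow = c(TRUE, FALSE, FALSE),
                                  nep = c(50, 0, 1)),
               c("snow", "dormant", "active"))
})

test_that("interval albedo is the ratio of sums, never the mean of ratios", {
  s <- make_series(rep(0.2, 1))
  rows <- which(s$sw_in > 0)[1:10]
  expect_equal(aggregate_albedo(s, rows), 0.2)

  s2 <- s
  r2 <- rows[1:2]
  s2$sw_in[r2] <- c(800, 200)
  s2$sw_out[r2] <- c(80, 40)
  expect_equal(aggregate_albedo(s2, r2), 0.12)   # mean of ratios: 0.15

  s3 <- s
  s3$sw_in[] <- 0
  expect_error(aggregate_albedo(s3), "undefined")

  # flux-weighted value is bracketed by instantaneous daytime ratios
  p <- generator_params(seed = 12, gap_fraction = 0)
  meta <- generate_site_metadata(p)
  g <- generate_halfhourly(meta[5, ], 2015, p)
  day <- g$series$sw_in >= 20
  ratios <- g$series$sw_out[day] / g$series$sw_in[day]
  a <- aggregate_albedo(g$series, day)
  expect_gte(a, min(ratios)); expect_lte(a, max(ratios))
})

test_that("NEP totals convert units correctly and demand gap-filled NEE", {
  s <- make_series(rep(0.2, 30))
  expect_equal(aggregate_nep(s), 0)
  s$nee[] <- -1
  expect_equal(aggregate_nep(s), 2.592e6 * 12.011e-6)  # 31.13 gC m-2
  s$nee[] <- 2
  expect_lt(aggregate_nep(s), 0)
  s$nee[5] <- NA
  expect_error(aggregate_nep(s), "missing")
})

test_that("monthly NEP totals of a complete year sum to the annual total", {
  p <- generator_params(seed = 13, gap_fraction = 0)
  meta <- generate_site_metadata(p)
  g <- generate_halfhourly(meta[7, ], 2015, p)
  mon <- as.integer(format(g$series$timestamp, "%m", tz = "UTC"))
  monthly <- vapply(1:12, function(m) aggregate_nep(g$series, mon == m),
                    numeric(1))
  expect_equal(sum(monthly), aggregate_nep(g$series), tolerance = 1e-6)
})

test_that("E_GPP follows the 0.469 J/umol energy intensity and is scale-invariant", {
  s <- make_series(rep(0.2, 2))
  expect_equal(compute_egpp(s), 0)
  day <- s$sw_in > 0
  # make SW_net average 200 over daytime and gpp 5 umol m-2 s-1
  s$sw_in[day] <- 250; s$sw_out[day] <- 50
  s$gpp[day] <- 5
  expect_equal(compute_egpp(s, day), 5 * 0.469 / 200, tolerance = 1e-12)
  s2 <- s
  s2$gpp <- s$gpp * 2; s2$sw_in <- s$sw_in * 2; s2$sw_out <- s$sw_out * 2
  expect_equal(compute_egpp(s2, day), compute_egpp(s, day))
  s$sw_out[day] <- 260
  expect_error(compute_egpp(s, day), "SW_net")
})

test_that("full-year screening keeps only complete gap-filled years", {
  p <- generator_params(seed = 14, gap_fraction = 0.1)
  meta <- generate_site_metadata(p)
  y1 <- process_site(generate_halfhourly(meta[1, ], 2015, p)$series)$series
  y2 <- process_site(generate_halfhourly(meta[1, ], 2016, p)$series)$series
  p_gappy <- generator_params(seed = 14, gap_fraction = 0.1,
                              gap_fraction_nee = 0.05)
  y3 <- process_site(generate_halfhourly(meta[1, ], 2017,
                                         p_gappy)$series)$series
  ann <- screen_full_years(list(y1, y2, y3), meta$site_id[1])
  expect_equal(ann$complete, c(TRUE, TRUE, FALSE))
  expect_equal(sum(!is.na(ann$nep)), 2)
  expect_warning(screen_full_years(list(y3), meta$site_id[1]),
                 "no complete")
})

test_that("missing MAT/MAP metadata falls back to series means", {
  p <- generator_params(n_sites = 3, n_clusters = 1, seed = 4,
                        gap_fraction = 0)
  meta <- generate_site_metadata(p)
  g <- generate_halfhourly(meta[1, ], 2015, p)
  meta$mat[1] <- NA; meta$map[1] <- NA
  filled <- fill_missing_meta(meta, setNames(list(list(g$series)),
                                             meta$site_id[1]))
  expect_equal(filled$mat[1], mean(g$series$tair))
  expect_equal(filled$map[1], sum(g$series$precip))
})

test_that("fAPAR aggregation drops QC failures and interpolates interior gaps", {
  dates <- seq(as.Date("2020-01-02"), as.Date("2020-06-28"), by = 4)
  f <- data.frame(date = dates, fapar = 0.5, qc = 0)
  m <- aggregate_fapar(f)
  expect_true(all(m$fapar == 0.5))

  f2 <- f
  f2$fapar <- rep(c(0.4, 0.4, 0.6, 0.6), length.out = nrow(f2))
  f2$fapar[format(f2$date, "%m") == "03"] <- NA
  f2$fapar[format(f2$date, "%m") %in% c("01", "02")] <- 0.4
  f2$fapar[format(f2$date, "%m") %in% c("04", "05", "06")] <- 0.6
  f2$qc[format(f2$date, "%m") == "03"] <- 1
  m2 <- aggregate_fapar(f2)
  expect_equal(m2$fapar[m2$month == 3], 0.5)   # interpolated between .4/.6

  # QC-failing records are excluded from monthly means
  f3 <- f
  f3$fapar[1:3] <- 5; f3$qc[1:3] <- 2
  m3 <- aggregate_fapar(f3)
  expect_equal(m3$fapar[m3$month == 1], 0.5)

  f4 <- f; f4$qc <- 1
  expect_error(aggregate_fapar(f4), "quality")
})

test_that("process_site output windows partition the record and label conditions", {
  p <- generator_params(seed = 15, gap_fraction = 0.1)
  meta <- generate_site_metadata(p)
  site <- meta[which(meta$snow_days > 0)[1], ]
  g <- generate_halfhourly(site, 2015, p)
  pr <- process_site(g$series)
  w <- pr$windows
  expect_equal(w$start_row[1], 1L)
  expect_equal(w$end_row[nrow(w)], nrow(g$series))
  if (nrow(w) > 1)
    expect_true(all(w$start_row[-1] == w$end_row[-nrow(w)] + 1L))
  expect_true(all(w$condition %in% c("active", "dormant", "snow")))
  expect_true(any(w$condition == "snow"))
  expect_false(anyNA(pr$series$sw_out))
})
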