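test_that("the assumption ensemble is the full 16-member factorial", {
  m <- ensemble_members()
  expect_equal(nrow(m), 16)
  expect_equal(nrow(unique(m)), 16)
  expect_setequal(unique(m$transition_years), c(0, 30))
  expect_setequal(unique(m$c_max), c(50000, 100000))
  expect_setequal(unique(m$harvest_level), c("low", "high"))
  expect_setequal(unique(m$kernel_set), c("weak", "strong"))
})

test_that("harvest rates follow the class-specific bounds", {
  expect_equal(harvest_rate("CRO", "low", 500), 247)
  expect_equal(harvest_rate("CRO", "high", 500), 335)
  expect_equal(harvest_rate("GRA", "low", 500), 0)
  expect_equal(harvest_rate("GRA", "high", 500), 500)
  expect_equal(harvest_rate("GRA", "high", -50), 0)
  expect_equal(harvest_rate("ENF", "low", 500), 0)
  expect_equal(harvest_rate("ENF", "high", 500), 61)
  expect_equal(harvest_rate("WET", "high", 500), 61)
})

test_that("carbon perturbation accumulates, saturates and conserves mass", {
  k <- forcing_constants()
  m0 <- list(transition_years = 0, c_max = 1e5, harvest_level = "low")
  # no change, same class: identically zero
  p0 <- carbon_perturbation(200, 0, "ENF", m0, k)
  expect_true(all(p0$perturbation == 0))
  # step change +100, no harvest, far from caps: 1000 gC by year 10
  p1 <- carbon_perturbation(200, 100, "ENF", m0, k)
  expect_equal(cumsum(p1$perturbation)[10], 1000)
  # saturation: cap 500 above the initial stock, neutral counterfactual
  m_cap <- list(transition_years = 0, c_max = k$c_init + 500,
                harvest_level = "low")
  p2 <- carbon_perturbation(0, 100, "ENF", m_cap, k)
  cum <- cumsum(p2$perturbation)
  expect_equal(cum[5], 500)
  expect_true(all(cum[5:100] == 500))
  expect_true(all(p2$factual$stock <= k$c_init + 500))
  expect_error(carbon_perturbation(0, 10, "ENF",
                                   list(transition_years = 0, c_max = 1000,
                                        harvest_level = "low"), k),
               "c_max")
})

test_that("transition ramps delay the perturbation without changing its target", {
  k <- forcing_constants()
  m30 <- list(transition_years = 30, c_max = 1e5, harvest_level = "low")
  m0 <- list(transition_years = 0, c_max = 1e5, harvest_level = "low")
  pa <- carbon_perturbation(100, 120, "DBF", m0, k)
  pb <- carbon_perturbation(100, 120, "DBF", m30, k)
  expect_equal(pb$perturbation[1], 120 / 30)
  expect_lt(pb$perturbation[1], pa$perturbation[1])
  expect_equal(pb$perturbation[50], pa$perturbation[50])  # ramp finished
})

test_that("rf_co2 reproduces closed forms and is monotone", {
  k <- forcing_constants()
  expect_equal(rf_co2(0, k), 0)
  # forced doubling: uptake chosen so the mixing ratio gain is +420 ppm
  cum_double <- -420 * k$ppm_to_mass /
    (k$land_fraction_changed * k$land_area * k$airborne_fraction)
  expect_lt(abs(rf_co2(cum_double, k) - 5.35 * log(2)), 1e-6)
  expect_equal(5.35 * log(2), 3.709, tolerance = 1e-3)
  # worked chain: 1000 gC m-2 on 1% of land
  expect_equal(rf_co2(1000, k), -3.93e-3, tolerance = 0.01)
  u <- seq(0, 5e4, length.out = 40)
  expect_true(all(diff(rf_co2(u, k)) < 0))
  expect_error(rf_co2(-cum_double, k), "unphysical")
})

test_that("albedo effect applies kernels monthly and scales to the globe", {
  k <- forcing_constants()
  expect_equal(albedo_effect(rep(0, 12), rep(-150, 12), k), 0)
  got <- albedo_effect(rep(0.05, 12), rep(-0.89 * 200, 12), k)
  expect_equal(got, -0.89 * 200 * 0.05 * 0.01 * 1.489e14 / 5.101e14)
  expect_equal(got, -0.026, tolerance = 1e-2)
  expect_lt(albedo_effect(rep(0.05, 12), -0.9 * c(rep(100, 6), rep(300, 6)),
                          k), 0)
  expect_warning(albedo_effect(rep(0.01, 12), rep(1, 12), k), "sign")
})

test_that("synthetic kernels scale SW_IN by the literature factor bounds", {
  expect_equal(synthetic_kernels(100, "strong"), -103)
  expect_equal(synthetic_kernels(100, "weak"), -81)
  sw <- matrix(runif(24, 0, 300), 2)
  expect_equal(synthetic_kernels(sw, "weak") / synthetic_kernels(sw, "strong"),
               matrix(0.81 / 1.03, 2, 12), tolerance = 1e-12)
  expect_equal(synthetic_kernels(0, "strong"), 0)
})

test_that("trajectories are zero for zero assignments and ordered by transition", {
  annual <- data.frame(site_id = c("A", "B"), albedo = c(0.2, 0.25),
                       nep = c(100, 120), stringsAsFactors = FALSE)
  meta <- data.frame(site_id = c("A", "B"), igbp = "ENF",
                     stringsAsFactors = FALSE)
  monthly <- data.frame(site_id = rep(c("A", "B"), each = 12),
                        month = rep(1:12, 2), albedo = 0.2, sw_in = 150)
  asn <- data.frame(site_id = rep(c("A", "B"), each = 4),
                    scenario = rep(c("SC1", "SC2", "SC3", "SC4"), 2),
                    delta_nep = 0, delta_albedo = 0, has_partners = TRUE,
                    stringsAsFactors = FALSE)
  asn[paste0("dalb_m", 1:12)] <- 0
  tr <- build_trajectories(asn, annual, meta, monthly, years = 20)
  expect_true(all(tr$trajectories$delta_r == 0))
  expect_true(all(is.na(sign_crossing(rep(0, 20)))))

  asn2 <- asn
  asn2$delta_nep <- 150
  asn2[paste0("dalb_m", 1:12)] <- -0.05
  tr2 <- build_trajectories(asn2, annual, meta, monthly, years = 20)
  t2 <- tr2$trajectories
  y1 <- t2[t2$year == 1 & t2$scenario == "SC1", ]
  expect_gt(abs(y1$delta_r[y1$member == "t00_c050k_hlow_kstrong"]),
            abs(y1$delta_r[y1$member == "t30_c050k_hlow_kstrong"]))
  # ensemble envelope brackets the mean
  s <- tr2$summary
  expect_true(all(s$min <= s$mean + 1e-12 & s$mean <= s$max + 1e-12))
})

test_that("pure-albedo and pure-NEP scenarios both cool", {
  annual <- data.frame(site_id = "A", albedo = 0.2, nep = 100,
                       stringsAsFactors = FALSE)
  meta <- data.frame(site_id = "A", igbp = "ENF", stringsAsFactors = FALSE)
  monthly <- data.frame(site_id = "A", month = 1:12, albedo = 0.2,
                        sw_in = 150)
  base <- data.frame(site_id = "A", scenario = "SC1", delta_nep = 0,
                     delta_albedo = 0, has_partners = TRUE,
                     stringsAsFactors = FALSE)
  alb <- base; alb[paste0("dalb_m", 1:12)] <- 0.05
  tr_a <- build_trajectories(alb, annual, meta, monthly, years = 50)
  expect_true(all(tr_a$trajectories$delta_r <= 0))
  nep <- base; nep$delta_nep <- 200; nep[paste0("dalb_m", 1:12)] <- 0
  tr_n <- build_trajectories(nep, annual, meta, monthly, years = 50)
  expect_true(all(tr_n$trajectories$delta_r <= 0))
  # monotone non-increasing before any cap binds
  for (mem in unique(tr_n$trajectories$member)) {
    d <- tr_n$trajectories[tr_n$trajectories$member == mem, ]
    stocks_ok <- max(forcing_constants()$c_init + 200 * 50, 0) < 50000
    if (stocks_ok) expect_true(all(diff(d$delta_r[order(d$year)]) <= 1e-15))
  }
})

test_that("sign_crossing finds the first reversal", {
  expect_true(is.na(sign_crossing(c(-1, -2, -3))))
  expect_equal(sign_crossing(c(1, 0.5, -0.2, -1)), 3L)
  expect_true(is.na(sign_crossing(numeric(0))))
})
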