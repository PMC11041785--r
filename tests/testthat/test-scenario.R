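test_that("climate partner matching applies the stated tolerances", {
  mk <- function(id, mat, map, sw, snow)
    data.frame(site_id = id, mat = mat, map = map, mean_sw_in = sw,
               snow_days = snow, stringsAsFactors = FALSE)
  focal <- mk("F", 10, 800, 150, 0)
  pool <- rbind(mk("P1", 10, 1000, 150, 0),   # 200/800 = 25% > 20%
                mk("P2", 10, 800, 150, 0),    # identical
                mk("P3", 11.4, 900, 160, 0),  # all inside tolerances
                mk("P4", 11.6, 800, 150, 0),  # MAT off by 1.6 > 1.5
                mk("P5", 10, 800, 150, 5))    # snow 0 vs 5
  expect_equal(find_climate_partners(focal, pool), c("P2", "P3"))
  snowy <- mk("F", 0, 800, 150, 50)
  pool2 <- rbind(mk("Q1", 0, 800, 150, 58),   # 8/50 = 16%
                 mk("Q2", 0, 800, 150, 62),   # 12/50 = 24%
                 mk("Q3", 0, 800, 150, 0))    # positive vs zero
  expect_equal(find_climate_partners(snowy, pool2), "Q1")
  expect_error(match_tolerances(mat_abs = 0), "positive")
})

test_that("balanced score reproduces the closed-form cases", {
  a_rng <- c(0.05, 0.45); n_rng <- c(-100, 800)
  expect_equal(balanced_score(0.2, 300, 0.2, 300, a_rng, n_rng), 0)
  expect_equal(balanced_score(0.05, -100, 0.45, 800, a_rng, n_rng),
               sqrt(2))
  x <- balanced_score(0.15, 100, 0.20, 50, a_rng, n_rng)
  expected <- (0.05 / 0.40 + (-50) / 900) / sqrt(2)
  expect_lt(abs(x - expected), 1e-12)
  expect_equal(x, 0.0491, tolerance = 1e-3)
  expect_error(balanced_score(0.1, 1, 0.2, 2, c(0.2, 0.2), n_rng),
               "degenerate")
})

test_that("scenario assignment matches the exhaustive reference on a network", {
  net <- simulate_network_annual(generator_params(seed = 17))
  asn <- assign_scenarios(net$annual, net$meta)
  ref <- oracle_assign(net$annual, net$meta)
  cols <- c("site_id", "scenario", "nep_partner", "albedo_partner",
            "delta_nep", "delta_albedo", "has_partners")
  got <- asn[cols]
  rownames(got) <- rownames(ref) <- NULL
  expect_identical(got$nep_partner, ref$nep_partner)
  expect_identical(got$albedo_partner, ref$albedo_partner)
  expect_equal(got$delta_nep, ref$delta_nep)
  expect_equal(got$delta_albedo, ref$delta_albedo)
  expect_identical(got$has_partners, ref$has_partners)
})

test_that("assignments are invariant to input row order", {
  net <- simulate_network_annual(generator_params(n_sites = 20,
                                                  n_clusters = 3, seed = 19))
  asn1 <- assign_scenarios(net$annual, net$meta, monthly = net$monthly)
  set.seed(1)
  perm <- sample(nrow(net$annual))
  asn2 <- assign_scenarios(net$annual[perm, ], net$meta[rev(perm), ],
                           monthly = net$monthly)
  rownames(asn1) <- rownames(asn2) <- NULL
  expect_equal(asn1, asn2)
})

test_that("a site already at the optimum keeps zero deltas but stays in the average", {
  annual <- data.frame(site_id = c("A", "B", "C"),
                       albedo = c(0.10, 0.20, 0.30),
                       nep = c(500, 300, 100), stringsAsFactors = FALSE)
  meta <- data.frame(site_id = c("A", "B", "C"), mat = 10, map = 800,
                     mean_sw_in = 150, snow_days = 0,
                     stringsAsFactors = FALSE)
  asn <- assign_scenarios(annual, meta)
  a_sc1 <- asn[asn$site_id == "A" & asn$scenario == "SC1", ]
  expect_true(is.na(a_sc1$nep_partner))
  expect_equal(a_sc1$delta_nep, 0)
  expect_equal(a_sc1$delta_albedo, 0)
  expect_true(a_sc1$has_partners)
  s <- scenario_summary(asn)
  expect_equal(s$n_with_partners, rep(3L, 4))
  # SC1 mean over all three sites, including A's zero contribution
  expect_equal(s$mean_delta_nep[s$scenario == "SC1"],
               mean(c(0, 200, 400)))

  # SC4 composes SC1's NEP delta with SC2's albedo delta componentwise
  for (sid in annual$site_id) {
    s1 <- asn[asn$site_id == sid & asn$scenario == "SC1", ]
    s2 <- asn[asn$site_id == sid & asn$scenario == "SC2", ]
    s4 <- asn[asn$site_id == sid & asn$scenario == "SC4", ]
    expect_equal(s4$delta_nep, s1$delta_nep)
    expect_equal(s4$delta_albedo, s2$delta_albedo)
  }
})

test_that("componentwise dominance of SC2 albedo and SC1 NEP deltas", {
  net <- simulate_network_annual(generator_params(seed = 23))
  asn <- assign_scenarios(net$annual, net$meta)
  w <- asn[asn$has_partners, ]
  for (sid in unique(w$site_id)) {
    rows <- w[w$site_id == sid, ]
    expect_equal(max(rows$delta_albedo),
                 rows$delta_albedo[rows$scenario == "SC2"])
    expect_equal(max(rows$delta_nep),
                 rows$delta_nep[rows$scenario == "SC1"])
  }
})

test_that("SC3 can be forced to require improvement", {
  # two sites, mutual partners, where every move is a strict trade-off loss
  annual <- data.frame(site_id = c("A", "B"),
                       albedo = c(0.30, 0.10), nep = c(100, 90),
                       stringsAsFactors = FALSE)
  meta <- data.frame(site_id = c("A", "B"), mat = 10, map = 800,
                     mean_sw_in = 150, snow_days = 0,
                     stringsAsFactors = FALSE)
  free <- assign_scenarios(annual, meta)
  a3 <- free[free$site_id == "A" & free$scenario == "SC3", ]
  expect_equal(a3$nep_partner, "B")   # accepts the least-bad trade-off
  strict <- assign_scenarios(annual, meta, sc3_require_improvement = TRUE)
  a3s <- strict[strict$site_id == "A" & strict$scenario == "SC3", ]
  expect_true(is.na(a3s$nep_partner))
  expect_equal(a3s$delta_nep, 0)
})

test_that("empty input raises an error", {
  expect_error(assign_scenarios(data.frame(), data.frame()), "empty")
})
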