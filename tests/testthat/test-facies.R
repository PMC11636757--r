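test_that("Chadha coordinates reproduce hand computations and end-member waters", {
  mean_wet <- data.frame(Ca = 82.78, Mg = 37.15, Na = 32.41, K = 1.09,
                         HCO3 = 235, Cl = 29.89, SO4 = 32.67)
  cc <- chadha_coordinates(mean_wet)
  expect_equal(cc$x, 66.67, tolerance = 1e-3)
  expect_equal(cc$y, 43.32, tolerance = 1e-3)
  expect_equal(cc$zone, 5L)
  expect_identical(cc$water_type, "Ca-Mg-HCO3")

  nacl <- chadha_coordinates(data.frame(Na = 23, Cl = 35.4527 * 23 /
                                          22.98977))
  expect_equal(nacl$x, -100)
  expect_equal(nacl$y, -100)
  expect_equal(nacl$zone, 7L)

  cahco3 <- chadha_coordinates(data.frame(Ca = 40.078, HCO3 = 122.032))
  expect_equal(cahco3$x, 100)
  expect_equal(cahco3$y, 100)
  expect_equal(cahco3$zone, 5L)

  expect_error(chadha_coordinates(data.frame(Ca = 0, Cl = 10)),
               "zero cation")
})

test_that("Chadha axes are invariant to uniform ion-group scaling and quadrants are exhaustive", {
  set.seed(11)
  for (i in 1:30) {
    s <- data.frame(Ca = runif(1, 1, 200), Mg = runif(1, 1, 100),
                    Na = runif(1, 1, 100), K = runif(1, 0, 5),
                    HCO3 = runif(1, 10, 400), Cl = runif(1, 1, 100),
                    SO4 = runif(1, 1, 150), NO3 = runif(1, 0, 60))
    cc <- chadha_coordinates(s)
    scaled <- s
    scaled[c("Ca", "Mg", "Na", "K")] <-
      scaled[c("Ca", "Mg", "Na", "K")] * 3.7
    scaled[c("HCO3", "Cl", "SO4", "NO3")] <-
      scaled[c("HCO3", "Cl", "SO4", "NO3")] * 0.21
    cc2 <- chadha_coordinates(scaled)
    expect_equal(cc$x, cc2$x, tolerance = 1e-10)
    expect_equal(cc$y, cc2$y, tolerance = 1e-10)
    expect_true(cc$zone %in% 5:8)
    expect_true(cc$x >= -100 && cc$x <= 100)
    expect_true(cc$y >= -100 && cc$y <= 100)
    # field flags are exactly the sign pattern of (x, y)
    expect_identical(cc$alkaline_earth_dominant, cc$x >= 0)
    expect_identical(cc$weak_acid_dominant, cc$y >= 0)
    want_zone <- if (cc$x >= 0) {
      if (cc$y >= 0) 5L else 6L
    } else if (cc$y >= 0) 8L else 7L
    expect_identical(cc$zone, want_zone)
  }
})

test_that("TDS-TH classes follow the configured thresholds with upper-class ties", {
  expect_identical(tds_th_class(174.28, 300, th_only = TRUE),
                   "soft-brackish")
  expect_identical(tds_th_class(240.17, 300, th_only = TRUE),
                   "hard-brackish")
  expect_identical(tds_th_class(180, 1000), "hard-brackish")  # ties up
  expect_identical(tds_th_class(179.9, 999.9), "soft-fresh")
})

test_that("ratio panel computes molar and equivalent ratios with safe zeroes", {
  equimolar <- data.frame(Na = 22.98977, Cl = 35.4527, Ca = 40.078,
                          HCO3 = 122.032, SO4 = 96.06)
  rp <- ratio_panel(equimolar)
  expect_equal(rp$Na_Cl, 1, tolerance = 1e-12)
  expect_equal(rp$Ca_HCO3, 0.5, tolerance = 1e-12)
  mean_wet <- data.frame(Ca = 82.78, Mg = 37.15, Na = 32.41, K = 1.09,
                         HCO3 = 235, Cl = 29.89, SO4 = 32.67)
  nacl <- ratio_panel(mean_wet)$Na_Cl
  expect_equal(nacl, (32.41 / 22.98977) / (29.89 / 35.4527),
               tolerance = 1e-12)
  expect_gt(nacl, 0.41); expect_lt(nacl, 5.78)
  # zero denominator gives NA with a reason, never Inf
  z <- ratio_panel(data.frame(Na = 10, Cl = 0))
  expect_true(is.na(z$Na_Cl))
  expect_true("Na_Cl" %in% names(attr(z, "zero_denominator")))
})

test_that("source labels are the documented deterministic rules", {
  panel <- data.frame(Na_Cl = c(5.78, 0.41, 1, NA),
                      CaMg_HCO3SO4 = c(1.5, 0.8, 1.02, 1.5),
                      Ca_HCO3 = c(0.375, 0.6, 0.2, 0.3))
  labs <- source_labels(panel)
  expect_true("silicate-weathering/ion-exchange" %in% labs[[1]])
  expect_true("carbonate-dissolution-dominant" %in% labs[[1]])
  expect_true("carbonic-acid-calcite-dissolution" %in% labs[[1]])
  expect_true("anthropogenic/reverse-exchange" %in% labs[[2]])
  expect_true("silicate-weathering-influence" %in% labs[[2]])
  expect_true("carbonate+evaporite-mixing" %in% labs[[3]])
  # an NA ratio contributes no label for that axis
  expect_false(any(grepl("exchange", labs[[4]])))
  # purity: same panel, same labels
  expect_identical(labs, source_labels(panel))
})

test_that("end-member assignment picks the nearest composition in log space", {
  carb <- data.frame(Ca_Na = 45, Mg_Na = 9, HCO3_Na = 110)
  sil <- data.frame(Ca_Na = 0.4, Mg_Na = 0.3, HCO3_Na = 2.2)
  expect_identical(end_member_assignment(carb), "carbonate")
  expect_identical(end_member_assignment(sil), "silicate")
})

test_that("seasonal correlations agree with the two-pass Pearson formula", {
  # exact linearity
  d <- data.frame(season = "wet", NO3 = 2 * (1:5) + 1, Cl = 1:5,
                  TDS = 5:1)
  sc <- season_correlations(d)
  expect_equal(sc$r_NO3_Cl, 1)
  expect_equal(sc$r_NO3_TDS, -1)
  # constant vector gives NA
  dc <- data.frame(season = "dry", NO3 = rep(3, 5), Cl = 1:5)
  expect_true(is.na(season_correlations(dc)$r_NO3_Cl))
  # oracle equivalence on random vectors
  set.seed(99)
  for (i in 1:20) {
    dd <- data.frame(season = "dry", NO3 = runif(27, 10, 60),
                     Cl = runif(27, 10, 60), TDS = runif(27, 150, 450))
    sc <- season_correlations(dd)
    expect_equal(sc$r_NO3_Cl, oracle_pearson(dd$NO3, dd$Cl),
                 tolerance = 1e-12)
    expect_equal(sc$r_NO3_TDS, oracle_pearson(dd$NO3, dd$TDS),
                 tolerance = 1e-12)
  }
})
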