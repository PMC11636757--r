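test_that("mg/L to meq/L conversion matches hand values and is linear", {
  expect_equal(mg_to_meq(40.078, "Ca"), 2)           # 1 mmol divalent
  expect_equal(mg_to_meq(0, "SO4"), 0)
  expect_equal(mg_to_meq(235, "HCO3"), 235 / 61.016, tolerance = 1e-12)
  expect_equal(round(mg_to_meq(235, "HCO3"), 3), 3.851)
  expect_error(mg_to_meq(10, "Fe"), "unknown ion")
  expect_error(mg_to_meq(-1, "Ca"), ">= 0")
  # linearity over every registered ion
  for (ion in c("Ca", "Mg", "Na", "K", "HCO3", "CO3", "Cl", "SO4",
                "NO3")) {
    a <- 13.7; b <- 201.3
    expect_equal(mg_to_meq(a + b, ion),
                 mg_to_meq(a, ion) + mg_to_meq(b, ion),
                 tolerance = 1e-12)
  }
})

test_that("total hardness follows the CaCO3-equivalent formula and is monotone", {
  expect_equal(total_hardness(0, 0), 0)
  expect_equal(total_hardness(100, 0), 249.7)
  expect_equal(round(total_hardness(82.78, 37.15), 1), 359.6)
  set.seed(42)
  ca <- runif(20, 0, 200); mg <- runif(20, 0, 100)
  expect_true(all(total_hardness(ca + 1, mg) > total_hardness(ca, mg)))
  expect_true(all(total_hardness(ca, mg + 1) > total_hardness(ca, mg)))
})

test_that("charge balance error is zero for balanced water and bounded", {
  expect_equal(charge_balance_error(balanced_sample()), 0,
               tolerance = 1e-12)
  # cations-only water balances at +100%
  expect_equal(
    suppressWarnings(charge_balance_error(data.frame(Ca = 50))), 100)
  expect_error(charge_balance_error(data.frame(Ca = 0, Cl = 0)),
               "all-zero")
  # spreadsheet-style oracle on the wet-season mean composition
  comp <- data.frame(Ca = 82.78, Mg = 37.15, Na = 32.41, K = 1.09,
                     HCO3 = 235, Cl = 29.89, SO4 = 32.67, NO3 = 35.70)
  cat_meq <- 82.78 * 2 / 40.078 + 37.15 * 2 / 24.305 +
    32.41 / 22.98977 + 1.09 / 39.0983
  an_meq <- 235 / 61.016 + 29.89 / 35.4527 + 32.67 * 2 / 96.06 +
    35.70 / 62.0049
  # the table of means is not itself a balanced analysis, so the QC
  # warning is expected here
  expect_warning(got <- charge_balance_error(comp), "CBE")
  expect_equal(got, 100 * (cat_meq - an_meq) / (cat_meq + an_meq),
               tolerance = 1e-12)
  # CBE stays in [-100, 100] for random compositions
  set.seed(7)
  for (i in 1:25) {
    s <- data.frame(Ca = runif(1, 0, 300), Na = runif(1, 0, 100),
                    HCO3 = runif(1, 0, 400), Cl = runif(1, 0, 100))
    cbe <- suppressWarnings(charge_balance_error(s))
    expect_true(cbe >= -100 && cbe <= 100)
  }
})

test_that("guideline screening flags strict exceedances only", {
  std <- who_standards()
  d <- data.frame(well_id = "w", season = "wet", pH = 7.4, NO3 = 61)
  expect_identical(screen_samples(d, std)$flags[[1]], "NO3")
  # values exactly at the limit pass (inclusive limits)
  at_limit <- data.frame(pH = 8.5, NO3 = 50, TH = 500, Ca = 200)
  expect_length(screen_samples(at_limit, std)$flags[[1]], 0)
  # raising any single parameter by epsilon adds exactly that one
  for (p in c("NO3", "TH", "Ca")) {
    bumped <- at_limit
    bumped[[p]] <- bumped[[p]] + 1e-9
    expect_identical(screen_samples(bumped, std)$flags[[1]], p)
  }
  # pH outside the band counts as exceedance
  expect_identical(screen_samples(data.frame(pH = 8.6), std)$flags[[1]],
                   "pH")
  # missing values are reported as not screened, never passed
  scr <- screen_samples(data.frame(pH = 7.0), std,
                        parameters = c("pH", "NO3"))
  expect_identical(scr$not_screened[[1]], "NO3")
})

test_that("seasonal exceedance fractions use half-up two-decimal rounding", {
  d <- data.frame(season = rep("wet", 27),
                  NO3 = c(rep(61, 7), rep(20, 20)))
  scr <- screen_samples(d, who_standards())
  row <- scr$season_summary[scr$season_summary$parameter == "NO3", ]
  expect_equal(row$pct_exceeding, 25.93)
  expect_equal(row$pct_within, 74.07)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})

test_that("standards files round-trip and validate", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("# test standards", "NO3 = 45", "pH_min = 6.0",
               "pH_max = 9.0"), path)
  std <- read_standards(path)
  expect_equal(std$limits[["NO3"]], 45)
  expect_equal(std$ph_band, c(6.0, 9.0))
  expect_error(who_standards(limits = c(NO3 = -1)), "positive")
  expect_error(who_standards(ph_band = c(9, 6)), "lower < upper")
})

test_that("sample validation computes TH and rejects bad input", {
  tab <- data.frame(well_id = "w", season = "wet", Ca = 100, Mg = 10)
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  got <- read_samples(path)
  expect_equal(got$TH, total_hardness(100, 10))
  expect_equal(got$CO3, 0)
  bad <- tab; bad$season <- "monsoon"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_samples(path), "season")
  bad2 <- tab; bad2$Ca <- -5
  write.csv(bad2, path, row.names = FALSE)
  expect_error(read_samples(path), "negative")
})
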