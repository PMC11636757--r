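test_that("min-max normalisation maps columns to [0,1] and flags degeneracy", {
  expect_error(ewqi_normalize(matrix(1, 1, 2)), "at least 2")
  nrm <- ewqi_normalize(cbind(a = c(1, 2, 3), b = c(4, 4, 4)))
  expect_equal(nrm$Y[, "a"], c(0, 0.5, 1))
  expect_equal(nrm$Y[, "b"], c(0, 0, 0))
  expect_identical(unname(nrm$degenerate), c(FALSE, TRUE))
  expect_equal(ewqi_normalize(cbind(c(14, 61)))$Y[, 1], c(0, 1))
  expect_error(ewqi_normalize(cbind(c(1, NA))), "non-finite")
})

test_that("entropy weights: degenerate columns get zero weight, weights sum to 1", {
  one <- entropy_weights(cbind(c(0, 0.5, 1)))
  expect_equal(unname(one$weights), 1)
  # uniform proportions give maximal entropy, zero weight
  two <- entropy_weights(cbind(u = c(0.4, 0.4, 0.4), v = c(0, 0.5, 1)))
  expect_equal(unname(two$entropy["u"]), 1)
  expect_equal(unname(two$weights["u"]), 0)
  expect_equal(sum(two$weights), 1, tolerance = 1e-12)
  expect_error(entropy_weights(cbind(c(1, 1, 1))), "degenerate")
})

test_that("EWQI pipeline equals the brute-force oracle on 100 random matrices", {
  set.seed(123)
  for (rep in 1:100) {
    m <- sample(3:10, 1); n <- sample(2:6, 1)
    X <- matrix(runif(m * n, 1, 100), m, n)
    nrm <- ewqi_normalize(X)
    ew <- entropy_weights(nrm$Y)
    orc <- oracle_ewqi(X)
    expect_equal(unname(ew$entropy), orc$entropy, tolerance = 1e-9)
    expect_equal(unname(ew$weights), orc$weights, tolerance = 1e-9)
    # full scores against the oracle with unit standards
    S <- runif(n, 10, 200)
    q <- sweep(X, 2, S, "/") * 100
    expect_equal(unname(ewqi_score(ew$weights, q)),
                 oracle_ewqi(X, S)$score, tolerance = 1e-9)
  }
})

test_that("quality ratings follow the standard ratio and the pH band rule", {
  std <- who_standards()
  expect_equal(quality_rating(50, "NO3", std), 100)
  expect_equal(quality_rating(61, "NO3", std), 122)
  expect_equal(quality_rating(8.5, "pH", std), 100)
  expect_equal(quality_rating(7.0, "pH", std), 0)
  expect_equal(quality_rating(6.5, "pH", std), 100)
  expect_equal(quality_rating(7.75, "pH", std), 50)
  expect_true(all(quality_rating(seq(0, 14, by = 0.5), "pH", std) >= 0))
  expect_error(quality_rating(5, "unobtainium", std), "no standard")
})

test_that("weighted score reduces to known cases", {
  expect_equal(ewqi_score(c(0.3, 0.7), c(100, 100)), 100)
  expect_equal(ewqi_score(1, 37), 37)
  expect_equal(ewqi_score(c(0.25, 0.75), rbind(c(40, 80), c(0, 100))),
               c(70, 75))
  expect_error(ewqi_score(c(0.5, 0.5), c(1, 2, 3)), "mismatch")
})

test_that("rank classification uses left-closed 25/50/100/150 bands", {
  expect_identical(as.character(classify_ewqi(c(83.27, 95.68))),
                   c("III", "III"))
  expect_identical(as.character(classify_ewqi(c(120.30, 130.65))),
                   c("IV", "IV"))
  expect_identical(as.character(classify_ewqi(c(0, 24.99, 25, 50, 100,
                                                150, 400))),
                   c("I", "I", "II", "III", "IV", "V", "V"))
  expect_identical(attr(classify_ewqi(120.3), "labels"), "poor")
})

test_that("ewqi() fit is permutation invariant and deterministic for duplicates", {
  set.seed(5)
  d <- data.frame(well_id = paste0("w", 1:6),
                  pH = runif(6, 7, 8), TH = runif(6, 200, 600),
                  BOD = runif(6, 5, 9), COD = runif(6, 11, 20),
                  Ca = runif(6, 20, 200), NO3 = runif(6, 14, 61))
  fit <- ewqi(d)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(fit$weights >= 0))
  # permuting samples permutes scores identically
  perm <- sample(6)
  fit_p <- ewqi(d[perm, ])
  expect_equal(fit_p$score, fit$score[perm], tolerance = 1e-12)
  # permuting parameter order leaves scores unchanged
  fit_q <- ewqi(d, parameters = rev(c("pH", "TH", "BOD", "COD", "Ca",
                                      "NO3")))
  expect_equal(fit_q$score, fit$score, tolerance = 1e-12)
  # appending a duplicate sample gives it an identical score
  d2 <- rbind(d, d[3, ])
  fit_d <- ewqi(d2)
  expect_equal(fit_d$score[7], fit_d$score[3], tolerance = 1e-12)
})

test_that("samples at their standards score 100 for any admissible weights", {
  # every rated parameter at its limit (pH at 8.5) rates 100, so the
  # weighted sum is 100 whatever the weights
  set.seed(31)
  std <- who_standards()
  params <- c("pH", "TH", "BOD", "COD", "Ca", "NO3")
  q <- vapply(params, function(p) {
    v <- if (p == "pH") 8.5 else std$limits[[p]]
    quality_rating(v, p, std)
  }, numeric(1))
  expect_equal(unname(q), rep(100, length(params)))
  for (i in 1:10) {
    w <- runif(length(params)); w <- w / sum(w)
    expect_equal(ewqi_score(w, q), 100, tolerance = 1e-12)
  }
  # a fully constant matrix carries no entropy information at all
  d <- data.frame(pH = 8.5, TH = 500, BOD = 5, COD = 20, Ca = 200,
                  NO3 = 50)[rep(1, 4), ]
  expect_error(ewqi(d), "degenerate")
  # with an informative parameter alongside, the at-standard samples
  # still score exactly 100 on the at-standard parameters
  d$NO3 <- c(20, 30, 40, 50)
  fit <- ewqi(d)
  expect_equal(unname(fit$q[, "TH"]), rep(100, 4))
  expect_equal(fit$score, 100 * fit$weights[["NO3"]] *
                 d$NO3 / 50 + 100 * (1 - fit$weights[["NO3"]]),
               tolerance = 1e-9)
})

test_that("score is monotone in any one concentration under fixed weights", {
  set.seed(9)
  d <- data.frame(pH = runif(5, 7, 8), TH = runif(5, 200, 600),
                  BOD = runif(5, 5, 9), COD = runif(5, 11, 20),
                  Ca = runif(5, 20, 200), NO3 = runif(5, 14, 61))
  fit <- ewqi(d)
  for (p in c("TH", "BOD", "COD", "Ca", "NO3")) {
    bumped <- d
    bumped[[p]][2] <- bumped[[p]][2] * 1.25
    pred0 <- predict(fit, d)$score
    pred1 <- predict(fit, bumped)$score
    expect_gte(pred1[2], pred0[2])
    expect_equal(pred1[-2], pred0[-2], tolerance = 1e-12)
  }
})

test_that("fit methods: coef, fitted, predict round-trip, summary and plot", {
  f <- fixture_small()
  fit <- ewqi(f$samples, parameters = f$parameters)
  expect_s3_class(fit, "ewqi")
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-12)
  expect_equal(fitted(fit), fit$score)
  # predicting the training samples reproduces the fitted scores
  pr <- predict(fit, f$samples)
  expect_equal(pr$score, fit$score, tolerance = 1e-12)
  expect_output(print(fit), "Entropy-weighted")
  expect_output(print(summary(fit)), "Rank counts")
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
})

test_that("fixture EWQI matches the frozen independent oracle file", {
  f <- fixture_small()
  expect_false(is.null(f$oracle))
  fit <- ewqi(f$samples, parameters = f$parameters)
  orc <- f$oracle
  expect_equal(fit$score, orc$value[orc$kind == "score"],
               tolerance = 1e-9)
  expect_equal(unname(fit$weights), orc$value[orc$kind == "weight"],
               tolerance = 1e-9)
  expect_equal(unname(fit$entropy), orc$value[orc$kind == "entropy"],
               tolerance = 1e-9)
})
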