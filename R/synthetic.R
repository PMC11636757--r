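#' Marginal specification for a generated parameter
#'
#' The generator emulates published per-season summary statistics: for
#' each parameter only the minimum, maximum and mean are specified, and
#' draws come from a Beta distribution rescaled to `[min, max]` whose
#' mean matches the target.
#'
#' @param parameter Parameter name.
#' @param season `"wet"` or `"dry"`.
#' @param min,max,mean Summary statistics (min <= mean <= max).
#' @return A one-row data frame (class `marginal_spec` rows are plain).
#' @export
marginal_spec <- function(parameter, season, min, max, mean) {
  if (min > max || mean < min || mean > max) {
    stop("need min <= mean <= max for ", parameter, " (", season, ")")
  }
  data.frame(parameter = parameter, season = season,
             min = min, max = max, mean = mean,
             stringsAsFactors = FALSE)
}

#' Default per-season marginal specifications
#'
#' Published two-season summary statistics (min/max/mean) for a
#' 27-well drinking-water network: pH, EC (uS/cm), TDS, TH, BOD, COD
#' and the major ions (mg/L). The Na and K assignments resolve an
#' ambiguity in the source summary narrative: Na spans 9-68 mg/L in
#' both seasons (means 32.41 wet, 33.41 dry) and K spans 0.30-1.90
#' (mean 1.09, wet) and 0.30-3.06 (mean 1.27, dry).
#'
#' @return Data frame of [marginal_spec()] rows.
#' @export
default_marginals <- function() {
  rbind(
    marginal_spec("pH",   "wet", 7.10, 8.00, 7.53),
    marginal_spec("pH",   "dry", 7.10, 7.90, 7.38),
    marginal_spec("EC",   "wet", 366, 917, 533.81),
    marginal_spec("EC",   "dry", 346, 882, 524.96),
    marginal_spec("TDS",  "wet", 183, 459, 267.19),
    marginal_spec("TDS",  "dry", 173, 441, 262.67),
    marginal_spec("TH",   "wet", 240.17, 882.87, 359.29),
    marginal_spec("TH",   "dry", 174.282, 497.48, 320.05),
    marginal_spec("BOD",  "wet", 5.20, 8.30, 7.04),
    marginal_spec("BOD",  "dry", 6.00, 9.10, 7.80),
    marginal_spec("COD",  "wet", 11.10, 15.90, 13.21),
    marginal_spec("COD",  "dry", 12.30, 20.70, 16.17),
    marginal_spec("Ca",   "wet", 11, 222, 82.78),
    marginal_spec("Ca",   "dry", 27, 145, 82.37),
    marginal_spec("Mg",   "wet", 22, 104, 37.15),
    marginal_spec("Mg",   "dry", 15, 41, 27.85),
    marginal_spec("Na",   "wet", 9, 68, 32.41),
    marginal_spec("Na",   "dry", 9, 68, 33.41),
    marginal_spec("K",    "wet", 0.30, 1.90, 1.09),
    marginal_spec("K",    "dry", 0.30, 3.06, 1.27),
    marginal_spec("HCO3", "wet", 134, 361, 235.00),
    marginal_spec("HCO3", "dry", 95, 328, 197.00),
    marginal_spec("SO4",  "wet", 5, 91, 32.67),
    marginal_spec("SO4",  "dry", 6, 132, 35.04),
    marginal_spec("Cl",   "wet", 10, 65, 29.89),
    marginal_spec("Cl",   "dry", 12, 58, 28.11),
    marginal_spec("NO3",  "wet", 14, 61, 35.70),
    marginal_spec("NO3",  "dry", 12, 60, 29.00)
  )
}

#' Fit a bounded sampler to a marginal specification
#'
#' Scaled Beta on `[min, max]` with mean fraction
#' `m = (mean - min)/(max - min)`, shape `(c m, c (1 - m))` for
#' concentration `c`. Degenerate specs (`min == max`) give the
#' constant.
#'
#' @param spec One row of [default_marginals()] (or [marginal_spec()]).
#' @param concentration Beta concentration `c` (> 0), default 4; larger
#'   values concentrate mass around the mean.
#' @return List with `q` (quantile function on `[0, 1]`), `r` (random
#'   sampler `function(n)`), and the spec fields.
#' @export
fit_marginal <- function(spec, concentration = 4) {
  lo <- spec$min; hi <- spec$max; mu <- spec$mean
  if (lo == hi) {
    return(list(q = function(u) rep(lo, length(u)),
                r = function(n) rep(lo, n),
                min = lo, max = hi, mean = mu))
  }
  m <- (mu - lo) / (hi - lo)
  if (m <= 0 || m >= 1) stop("mean must lie strictly inside (min, max)")
  a <- concentration * m
  b <- concentration * (1 - m)
  qfun <- function(u) lo + (hi - lo) * stats::qbeta(u, a, b)
  list(q = qfun,
       r = function(n) qfun(stats::runif(n)),
       min = lo, max = hi, mean = mu, shape1 = a, shape2 = b)
}

# Power-correct a uniform vector so the transformed sample mean hits
# the target exactly: values = qfun(u^gamma), gamma solved by uniroot.
# The transform is monotone in u (rank preserving) and keeps [min,max].
.mean_correct <- function(u, qfun, target) {
  f <- function(lg) mean(qfun(u^exp(lg))) - target
  lo <- -8; hi <- 8
  if (f(lo) < 0) return(qfun(u^exp(lo)))
  if (f(hi) > 0) return(qfun(u^exp(hi)))
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  qfun(u^exp(root))
}

# Deterministic k-value segment on [lo, hi]: Beta quantiles at the
# plotting positions (i - 0.5)/k, power-adjusted so the segment mean is
# exactly target_mean.
.segment_values <- function(k, lo, hi, target_mean, concentration = 4) {
  if (k == 0) return(numeric(0))
  if (k == 1) return(target_mean)
  if (target_mean <= lo || target_mean >= hi) {
    stop("infeasible segment mean ", target_mean, " for [", lo, ", ",
         hi, "]")
  }
  w <- (seq_len(k) - 0.5) / k
  m <- (target_mean - lo) / (hi - lo)
  a <- concentration * m
  b <- concentration * (1 - m)
  qfun <- function(u) lo + (hi - lo) * stats::qbeta(u, a, b)
  .mean_correct(w, qfun, target_mean)
}

# Two-segment deterministic multiset: n values in [lo, hi] with exactly
# n_upper strictly above `threshold`, overall mean exactly `target`.
# The upper segment sits at the middle of (threshold, hi]; the lower
# segment mean absorbs the remainder.
.split_values <- function(n, n_upper, threshold, lo, hi, target,
                          concentration = 4) {
  if (n_upper > n) stop("more exceedance roles than wells")
  upper <- .segment_values(n_upper, threshold, hi,
                           (threshold + hi) / 2, concentration)
  lower_target <- (n * target - sum(upper)) / (n - n_upper)
  lower <- .segment_values(n - n_upper, lo, threshold, lower_target,
                           concentration)
  c(lower, upper)   # ascending across segments
}

# Pearson correlation induced by a Gaussian copula with parameter rho
# between two margins given by quantile functions, via two-dimensional
# Gauss-Hermite quadrature; then the rho achieving a target Pearson r.
.copula_pearson <- function(rho, qf1, qf2, nodes = 24) {
  gh <- pracma::gaussHermite(nodes)
  z <- sqrt(2) * gh$x
  wt <- gh$w / sqrt(pi)
  v1 <- qf1(stats::pnorm(z))
  m1 <- sum(wt * v1); s1 <- sqrt(sum(wt * (v1 - m1)^2))
  v2 <- qf2(stats::pnorm(z))
  m2 <- sum(wt * v2); s2 <- sqrt(sum(wt * (v2 - m2)^2))
  zmix <- outer(z, z, function(z1, z2) rho * z1 + sqrt(1 - rho^2) * z2)
  e12 <- sum(outer(wt * v1, wt) * qf2(stats::pnorm(zmix)))
  (e12 - m1 * m2) / (s1 * s2)
}

.calibrate_copula_rho <- function(target_r, qf1, qf2, nodes = 24) {
  if (abs(target_r) < 1e-12) return(0)
  f <- function(rho) .copula_pearson(rho, qf1, qf2, nodes) - target_r
  stats::uniroot(f, c(-0.995, 0.995), tol = 1e-8)$root
}

.calib_cache <- new.env(parent = emptyenv())

#' Generator configuration
#'
#' Defines the study conditions the synthetic network emulates: 27
#' wells sampled in a wet and a dry season, published per-season
#' min/max/mean marginals, target NO3-Cl Pearson correlations of 0.16
#' (wet) and 0.64 (dry) plus NO3-TDS correlations, and the printed
#' well roles: seven named wells above 50 mg/L NO3 per season, three
#' named wells above the 500 mg/L TH limit in the wet season, and
#' Ba-37 holding the dry-season TH minimum (the single soft sample).
#' Unprinted well names are synthetic placeholders (`Sy-*`).
#'
#' @param n_wells Number of wells (default 27).
#' @param seasons Seasons to generate.
#' @param marginals Marginal table, see [default_marginals()].
#' @param correlations Named list per season with `NO3_Cl` and
#'   `NO3_TDS` target Pearson correlations in (-1, 1).
#' @param concentration Beta concentration for all marginals.
#' @param bbox Coordinate bounding box `c(xmin, xmax, ymin, ymax)`.
#' @param wells Well names (length `n_wells`).
#' @param no3_exceed Named list per season of wells with NO3 above
#'   `no3_threshold`.
#' @param th_exceed_wet Wells above `th_limit` TH in the wet season.
#' @param soft_well_dry Well holding the dry TH minimum.
#' @param ewqi_subset Default well subset for the six-parameter EWQI
#'   run.
#' @param no3_threshold,th_limit NO3 and TH screening limits used by
#'   the role constraints.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(
    n_wells = 27,
    seasons = c("wet", "dry"),
    marginals = default_marginals(),
    correlations = list(wet = c(NO3_Cl = 0.16, NO3_TDS = 0.30),
                        dry = c(NO3_Cl = 0.64, NO3_TDS = 0.60)),
    concentration = 4,
    bbox = c(0, 10, 0, 10),
    wells = NULL,
    no3_exceed = list(
      wet = c("Ka-15", "Sa-10", "Na-16", "Ku-11", "Gl-3", "As-2",
              "Is-1"),
      dry = c("Ka-15", "Tu-4", "Na-16", "Ku-11", "Gl-3", "As-2",
              "Is-1")),
    th_exceed_wet = c("Sa-10", "Gl-3", "As-2"),
    soft_well_dry = "Ba-37",
    ewqi_subset = c("Bn-19", "Ka-15", "Na-16", "Sa-10", "Ku-11",
                    "Gl-3", "As-2", "Is-1"),
    no3_threshold = 50,
    th_limit = 500) {
  if (is.null(wells)) {
    named <- c("Ka-15", "Sa-10", "Na-16", "Ku-11", "Gl-3", "As-2",
               "Is-1", "Tu-4", "Bn-19", "Ba-37")
    extra <- sprintf("Sy-%02d", seq_len(max(0, n_wells - length(named))))
    wells <- c(named, extra)[seq_len(n_wells)]
  }
  if (length(wells) != n_wells) stop("need ", n_wells, " well names")
  for (s in seasons) {
    if (length(no3_exceed[[s]]) > n_wells) {
      stop("more NO3 exceedance roles than wells in season ", s)
    }
    if (!all(no3_exceed[[s]] %in% wells)) {
      stop("unknown well in NO3 exceedance roles")
    }
  }
  r <- unlist(correlations)
  if (any(r <= -1 | r >= 1)) stop("correlations must lie in (-1, 1)")
  structure(list(
    n_wells = n_wells, seasons = seasons, marginals = marginals,
    correlations = correlations, concentration = concentration,
    bbox = bbox, wells = wells, no3_exceed = no3_exceed,
    th_exceed_wet = th_exceed_wet, soft_well_dry = soft_well_dry,
    ewqi_subset = ewqi_subset, no3_threshold = no3_threshold,
    th_limit = th_limit), class = "generator_config")
}

# Role-constrained deterministic value multiset for one season.
.role_multiset <- function(param, config, spec) {
  n <- config$n_wells
  if (param == "NO3") {
    k <- length(config$no3_exceed[[spec$season]])
    return(.split_values(n, k, config$no3_threshold, spec$min,
                         spec$max, spec$mean, config$concentration))
  }
  if (param == "TH" && spec$season == "wet" &&
      length(config$th_exceed_wet)) {
    return(.split_values(n, length(config$th_exceed_wet),
                         config$th_limit, spec$min, spec$max,
                         spec$mean, config$concentration))
  }
  if (param == "TH" && spec$season == "dry" &&
      !is.null(config$soft_well_dry)) {
    # the named soft well sits exactly at the printed minimum; all
    # other wells are hard (TH >= 180)
    rest_target <- (n * spec$mean - spec$min) / (n - 1)
    rest <- .segment_values(n - 1, max(180, spec$min), spec$max,
                            rest_target, config$concentration)
    return(c(spec$min, rest))
  }
  NULL
}

#' Generate a synthetic per-well, two-season dataset
#'
#' Draws each season independently from a Gaussian copula over the
#' parameters: NO3-Cl and NO3-TDS carry the configured Pearson
#' correlations (the copula parameter is calibrated to the target
#' product-moment correlation by Gauss-Hermite quadrature against the
#' actual marginal quantile functions), all other parameters are
#' independent. Unconstrained parameters are Beta draws on the printed
#' `[min, max]` with a rank-preserving power correction making the
#' per-season sample mean exactly the printed mean. Role-constrained
#' parameters (NO3, TH) use a deterministic two-segment quantile
#' construction so exceedance counts and means are exact, with the
#' copula ranks deciding which well receives which value; named
#' exceedance wells receive the above-limit values. Coordinates are
#' fixed per well across seasons, with the high-NO3 ("urban") wells
#' clustered in the north-west corner of the bounding box.
#'
#' @param config A [generator_config()].
#' @param seed Integer RNG seed; fixed seed gives bit-identical output.
#' @return Data frame with one row per well x season, schema matching
#'   [read_samples()].
#' @examples
#' d <- generate_groundwater(seed = 1)
#' table(d$season)
#' @export
generate_groundwater <- function(config = generator_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_wells
  urban <- unique(unlist(config$no3_exceed))
  bb <- config$bbox
  w_x <- bb[2] - bb[1]; w_y <- bb[4] - bb[3]
  # coordinates per well, urban wells in the NW corner
  xs <- stats::runif(n, bb[1], bb[2])
  ys <- stats::runif(n, bb[3], bb[4])
  iu <- which(config$wells %in% urban)
  xs[iu] <- stats::runif(length(iu), bb[1], bb[1] + 0.3 * w_x)
  ys[iu] <- stats::runif(length(iu), bb[4] - 0.3 * w_y, bb[4])
  coords <- data.frame(well_id = config$wells, x = xs, y = ys,
                       depth_m = round(stats::runif(n, 30, 150), 1),
                       lulc_tag = ifelse(config$wells %in% urban,
                                         "urban", "periurban"),
                       stringsAsFactors = FALSE)

  out <- do.call(rbind, lapply(config$seasons, function(season) {
    specs <- config$marginals[config$marginals$season == season, ]
    params <- specs$parameter
    fits <- lapply(seq_len(nrow(specs)), function(i) {
      fit_marginal(specs[i, ], config$concentration)
    })
    names(fits) <- params

    # copula draw: NO3 drives Cl and TDS
    corr <- config$correlations[[season]]
    z_no3 <- stats::rnorm(n)
    z_rest <- matrix(stats::rnorm(n * (length(params) - 1)), n)
    colnames(z_rest) <- setdiff(params, "NO3")
    u <- matrix(NA_real_, n, length(params),
                dimnames = list(NULL, params))
    u[, "NO3"] <- stats::pnorm(z_no3)
    for (pp in colnames(z_rest)) u[, pp] <- stats::pnorm(z_rest[, pp])
    no3_spec <- specs[specs$parameter == "NO3", ]
    no3_vals <- sort(.role_multiset("NO3", config, no3_spec))
    qf_no3 <- stats::approxfun((seq_len(n) - 0.5) / n, no3_vals,
                               rule = 2)
    for (pp in c("Cl", "TDS")) {
      tgt <- corr[[paste0("NO3_", pp)]]
      if (is.null(tgt) || is.na(tgt)) next
      key <- paste(season, pp, tgt, sep = "|")
      rho <- .calib_cache[[key]]
      if (is.null(rho)) {
        rho <- .calibrate_copula_rho(tgt, qf_no3, fits[[pp]]$q)
        assign(key, rho, envir = .calib_cache)
      }
      u[, pp] <- stats::pnorm(rho * z_no3 +
                                sqrt(1 - rho^2) * z_rest[, pp])
    }

    vals <- matrix(NA_real_, n, length(params),
                   dimnames = list(NULL, params))
    for (i in seq_along(params)) {
      pp <- params[i]
      spec <- specs[i, ]
      mset <- .role_multiset(pp, config, spec)
      if (is.null(mset)) {
        vals[, pp] <- .mean_correct(u[, pp], fits[[pp]]$q, spec$mean)
      } else {
        # rank assignment: the row with the r-th smallest copula
        # uniform receives the r-th smallest value
        vals[, pp] <- sort(mset)[rank(u[, pp], ties.method = "first")]
      }
    }

    d <- as.data.frame(vals)
    d$season <- season

    # label assignment: named NO3-exceedance wells take the values
    # above the limit (largest first), remaining labels in list order
    exceed_names <- config$no3_exceed[[season]]
    over <- which(d$NO3 > config$no3_threshold)
    stopifnot(length(over) == length(exceed_names))
    labels <- character(n)
    labels[over[order(-d$NO3[over])]] <- exceed_names
    labels[labels == ""] <- setdiff(config$wells, exceed_names)
    d$well_id <- labels

    # TH is independent of the copula block, so its values may be
    # permuted across rows to honour the TH roles
    if (season == "wet" && length(config$th_exceed_wet)) {
      d$TH <- .assign_extremes(d$TH, d$well_id, config$th_exceed_wet,
                               decreasing = TRUE)
    }
    if (season == "dry" && !is.null(config$soft_well_dry)) {
      d$TH <- .assign_extremes(d$TH, d$well_id, config$soft_well_dry,
                               decreasing = FALSE)
    }
    d$CO3 <- 0
    merge(coords, d, by = "well_id", sort = FALSE)
  }))
  rownames(out) <- NULL
  ord <- c("well_id", "season", "x", "y", "depth_m", "lulc_tag", "pH",
           "EC", "TDS", "TH", "BOD", "COD", "Ca", "Mg", "Na", "K",
           "HCO3", "CO3", "Cl", "SO4", "NO3")
  out <- out[order(match(out$season, config$seasons),
                   match(out$well_id, config$wells)),
             intersect(ord, names(out))]
  rownames(out) <- NULL
  .validate_samples(out)
}

# Permute values so the named wells hold the most extreme ones
# (largest if decreasing, smallest otherwise); the remaining wells keep
# the remaining values in their previous relative order.
.assign_extremes <- function(values, well_id, names_extreme,
                             decreasing) {
  k <- length(names_extreme)
  ord <- order(values, decreasing = decreasing)
  extreme_vals <- values[ord[seq_len(k)]]
  rest_vals <- values[ord[-seq_len(k)]]
  out <- numeric(length(values))
  idx_extreme <- match(names_extreme, well_id)
  out[idx_extreme] <- extreme_vals
  idx_rest <- setdiff(seq_along(values), idx_extreme)
  # keep the remaining wells' rank order stable
  prev_rank <- rank(values[idx_rest], ties.method = "first")
  out[idx_rest] <- sort(rest_vals)[prev_rank]
  out
}

#' Small deterministic fixture with frozen oracle results
#'
#' A five-well, single-season toy table with a consistent ion balance
#' (|CBE| < 10%), covering the EWQI parameter set `pH, TH, Ca, NO3`
#' (plus BOD/COD and full ions so every pipeline stage runs). Well
#' F-01 has NO3 = 32 mg/L so an effective ingestion rate of 0.05
#' L/(kg day) with RfD 1.6 gives HI = 1 exactly. The accompanying
#' oracle file (entropy, weights and EWQI scores for the four-parameter
#' run) was computed once with an independent step-by-step
#' implementation and is shipped as plain CSV.
#'
#' @return List with `samples` (data frame), `parameters` (the oracle
#'   EWQI parameter set) and `oracle` (data frame with columns `kind`,
#'   `name`, `value`).
#' @export
fixture_small <- function() {
  samples <- data.frame(
    well_id = sprintf("F-%02d", 1:5),
    season = "wet",
    x = c(1, 2, 3, 4, 5), y = c(5, 3, 1, 4, 2),
    pH = c(7.2, 7.5, 7.8, 7.0, 6.8),
    EC = c(500, 366, 918, 600, 760),
    TDS = c(250, 183, 459, 300, 380),
    BOD = c(6, 5, 9, 7, 8),
    COD = c(12, 11, 18, 14, 16),
    Ca = c(80, 40, 120, 60, 100),
    Mg = c(30, 20, 50, 25, 40),
    Na = c(30, 15, 50, 25, 40),
    K = c(1.0, 0.5, 2.0, 1.0, 1.5),
    HCO3 = c(305, 183, 466, 216, 423),
    CO3 = 0,
    Cl = c(40, 20, 65, 35, 45),
    SO4 = c(55, 25, 90, 40, 70),
    NO3 = c(32, 14, 61, 50, 25),
    stringsAsFactors = FALSE)
  samples$TH <- total_hardness(samples$Ca, samples$Mg)
  oracle_path <- system.file("extdata", "fixture_small_oracle.csv",
                             package = "gwquality")
  oracle <- if (nzchar(oracle_path)) {
    utils::read.csv(oracle_path, stringsAsFactors = FALSE)
  } else NULL
  list(samples = .validate_samples(samples),
       parameters = c("pH", "TH", "Ca", "NO3"),
       oracle = oracle)
}
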