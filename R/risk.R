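#' Receptor-group exposure profile
#'
#' Exposure to a waterborne contaminant through drinking is summarised
#' by the effective ingestion rate `k = IRW * EF * ED / (BW * AT)` in
#' L/(kg day): chronic daily intake is `CDI = Cw * k`. A profile can be
#' specified either by the full USEPA quintuple (water intake rate IRW
#' in L/day, exposure frequency EF in days/year, exposure duration ED
#' in years, body weight BW in kg, averaging time AT in days) or
#' directly by `k` when only the product is known.
#'
#' @param group Receptor label, conventionally one of `"adults"`,
#'   `"children"`, `"infants"` (free text allowed).
#' @param k Effective ingestion rate, L/(kg day). Ignored when the full
#'   quintuple is supplied.
#' @param IRW,EF,ED,BW,AT Optional full exposure quintuple (all > 0);
#'   when all five are given they define `k`.
#' @return Object of class `exposure_profile`.
#' @examples
#' exposure_profile("adults", IRW = 2.5, EF = 365, ED = 30, BW = 65.7,
#'                  AT = 10950)
#' @export
exposure_profile <- function(group, k = NULL, IRW = NULL, EF = NULL,
                             ED = NULL, BW = NULL, AT = NULL) {
  quint <- list(IRW = IRW, EF = EF, ED = ED, BW = BW, AT = AT)
  have <- !vapply(quint, is.null, TRUE)
  if (all(have)) {
    vals <- unlist(quint)
    if (any(vals <= 0)) stop("all exposure parameters must be positive")
    k <- unname(vals["IRW"] * vals["EF"] * vals["ED"] /
                  (vals["BW"] * vals["AT"]))
  } else if (any(have)) {
    stop("supply either all of IRW, EF, ED, BW, AT or none")
  }
  if (is.null(k) || k <= 0) stop("effective ingestion rate k must be > 0")
  structure(list(group = group, k = k, quintuple = quint[have]),
            class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat("Exposure profile '", x$group, "': k = ",
      format(x$k, digits = 6), " L/(kg day)\n", sep = "")
  if (length(x$quintuple)) {
    cat("  from:", paste(names(x$quintuple), unlist(x$quintuple),
                         sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Calibrate an effective ingestion rate from a hazard-index anchor
#'
#' Because the hazard index is linear in concentration
#' (`HI = k * Cw / RfD` for a single contaminant), a known HI at a
#' known concentration pins down the receptor's effective ingestion
#' rate: `k = HI_ref * RfD / Cw_ref`. A profile built from this `k`
#' reproduces the anchor exactly and predicts the HI at any other
#' concentration.
#'
#' @param HI_ref Anchor hazard index (> 0).
#' @param Cw_ref Anchor concentration, mg/L (> 0).
#' @param RfD Reference dose, mg/(kg day); default nitrate 1.6.
#' @return Effective ingestion rate `k`, L/(kg day).
#' @examples
#' calibrate_effective_rate(1.45, 61)   # adult rate from a wet-season
#'                                      # maximum
#' @export
calibrate_effective_rate <- function(HI_ref, Cw_ref, RfD = 1.6) {
  if (any(HI_ref <= 0) || any(Cw_ref <= 0) || RfD <= 0) {
    stop("HI_ref, Cw_ref and RfD must be positive")
  }
  HI_ref * RfD / Cw_ref
}

#' Default receptor profiles for nitrate in drinking water
#'
#' Adults, children and infants with effective ingestion rates
#' calibrated so that a 61 mg/L nitrate exposure yields hazard indices
#' of 1.45, 1.80 and 1.91 respectively (RfD 1.6 mg/kg/day); infant and
#' child rates exceed the adult rate, reproducing the usual
#' infants > children > adults risk ordering.
#'
#' @return Named list of [exposure_profile()] objects.
#' @export
default_profiles <- function() {
  anchors <- c(adults = 1.45, children = 1.80, infants = 1.91)
  lapply(stats::setNames(names(anchors), names(anchors)), function(g) {
    exposure_profile(g, k = calibrate_effective_rate(anchors[[g]], 61))
  })
}

#' Chronic daily intake through drinking water
#'
#' `CDI = Cw * k`, mg per kg body weight per day; strictly linear in
#' the concentration.
#'
#' @param Cw Contaminant concentration in water, mg/L (>= 0,
#'   vectorised).
#' @param profile An [exposure_profile()].
#' @return CDI in mg/(kg day).
#' @export
cdi <- function(Cw, profile) {
  if (any(Cw < 0)) stop("Cw must be >= 0")
  stopifnot(inherits(profile, "exposure_profile"))
  Cw * profile$k
}

#' Hazard-index risk categories
#'
#' Left-closed bands: negligible (HI < 0.1), low (0.1 <= HI < 1),
#' medium (1 <= HI < 4), high (HI >= 4).
#'
#' @param HI Hazard index values (>= 0).
#' @param breaks Band boundaries, strictly increasing (default
#'   `c(0.1, 1, 4)`).
#' @return Ordered factor `negligible < low < medium < high`.
#' @examples
#' hi_category(c(0.09, 0.1, 1, 4))
#' @export
hi_category <- function(HI, breaks = c(0.1, 1, 4)) {
  lv <- c("negligible", "low", "medium", "high")
  factor(lv[findInterval(HI, breaks) + 1L], levels = lv, ordered = TRUE)
}

#' Non-carcinogenic hazard from drinking-water ingestion
#'
#' Computes the chronic daily intake, hazard quotient `HQ = CDI / RfD`
#' and hazard index for one contaminant in one or more samples. With a
#' single contaminant `HI = HQ`; [hazard_index()] sums quotients over
#' several contaminants.
#'
#' @param Cw Concentration(s), mg/L.
#' @param profile An [exposure_profile()].
#' @param RfD Reference dose, mg/(kg day); default nitrate 1.6.
#' @param well_id,season Optional identifiers carried into the result.
#' @return Data frame of class `risk_result` with columns `well_id`,
#'   `season`, `group`, `CDI`, `HQ`, `HI`, `category`.
#' @examples
#' hazard(61, default_profiles()$adults)
#' @export
hazard <- function(Cw, profile, RfD = 1.6, well_id = NULL,
                   season = NULL) {
  if (RfD <= 0) stop("RfD must be positive")
  CDI <- cdi(Cw, profile)
  HQ <- CDI / RfD
  out <- data.frame(
    well_id = if (is.null(well_id)) as.character(seq_along(Cw))
              else well_id,
    season = if (is.null(season)) NA_character_ else season,
    group = profile$group, CDI = CDI, HQ = HQ, HI = HQ,
    category = as.character(hi_category(HQ)),
    stringsAsFactors = FALSE)
  class(out) <- c("risk_result", "data.frame")
  out
}

#' Hazard index over several contaminants
#'
#' `HI = sum_c HQ_c` for one receptor; each contaminant contributes
#' `Cw_c * k / RfD_c`.
#'
#' @param Cw Named list or vector of concentrations per contaminant
#'   (mg/L), or a matrix (samples x contaminants).
#' @param profile An [exposure_profile()].
#' @param RfD Reference doses, recycled against the contaminants.
#' @return Numeric HI per sample.
#' @export
hazard_index <- function(Cw, profile, RfD) {
  Cw <- if (is.matrix(Cw)) Cw else matrix(unlist(Cw), nrow = 1)
  RfD <- rep_len(RfD, ncol(Cw))
  if (any(RfD <= 0)) stop("RfD must be positive")
  hq <- sweep(Cw * profile$k, 2L, RfD, "/")
  rowSums(hq)
}

#' Population summary of hazard results
#'
#' Per season and receptor group: min/mean/max HI, the fraction of
#' wells with HI above a threshold (default the HI = 1 benchmark), and
#' the ordering of groups by mean HI.
#'
#' @param results A `risk_result` data frame (rows for every
#'   well x season x group combination), e.g. rbind-ed [hazard()]
#'   outputs.
#' @param threshold Exceedance benchmark (default 1).
#' @return List with `summary` (data frame) and `ordering` (named list
#'   per season: groups sorted by decreasing mean HI).
#' @export
population_summary <- function(results, threshold = 1.0) {
  stopifnot(nrow(results) >= 1)
  key <- interaction(results$season, results$group, drop = TRUE)
  summ <- do.call(rbind, lapply(split(results, key), function(d) {
    data.frame(season = d$season[1], group = d$group[1], n = nrow(d),
               HI_min = min(d$HI), HI_mean = mean(d$HI),
               HI_max = max(d$HI),
               pct_exceeding = round_half_up(
                 100 * mean(d$HI > threshold), 2),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  ordering <- lapply(split(summ, summ$season), function(s) {
    s$group[order(-s$HI_mean)]
  })
  list(summary = summ, ordering = ordering)
}
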