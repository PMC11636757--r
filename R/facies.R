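#' Chadha rectangle coordinates and hydrochemical facies
#'
#' Places each sample on the Chadha diagram: the x axis is the
#' milliequivalent-percentage difference between alkaline earths
#' (Ca + Mg) and alkalis (Na + K) over the cation sum, the y axis the
#' difference between weak-acid anions (CO3 + HCO3) and strong-acid
#' anions (Cl + SO4) over the anion sum. Quadrants map to the classical
#' water types: (+,+) zone 5 Ca-Mg-HCO3 (temporary hardness), (+,-)
#' zone 6 Ca-Mg-Cl (reverse ion exchange, permanent hardness), (-,-)
#' zone 7 Na-Cl, (-,+) zone 8 Na-HCO3. Values exactly on an axis are
#' assigned to the positive side. The four half-plane fields (1:
#' alkaline earths dominant, 2: alkalis dominant, 3: weak acids
#' dominant, 4: strong acids dominant) are exposed as logical flags;
#' samples whose anion difference is within `equiline_band` meq-% of
#' zero are additionally flagged `near_axis` (visual "zone 1"-style
#' groupings in published diagrams correspond to this band).
#'
#' @param samples Data frame with `Ca`, `Mg`, `Na`, `K`, `HCO3`, `Cl`,
#'   `SO4` (mg/L); `CO3` optional.
#' @param equiline_band Half-width (meq-%) of the near-axis band
#'   (default 5).
#' @return Data frame with columns `x`, `y`, `zone` (5-8),
#'   `water_type`, the field flags `alkaline_earth_dominant`,
#'   `alkali_dominant`, `weak_acid_dominant`, `strong_acid_dominant`
#'   and `near_axis`.
#' @examples
#' chadha_coordinates(data.frame(Ca = 82.78, Mg = 37.15, Na = 32.41,
#'                               K = 1.09, HCO3 = 235, Cl = 29.89,
#'                               SO4 = 32.67))
#' @export
chadha_coordinates <- function(samples, equiline_band = 5) {
  samples <- .validate_samples(samples)
  meq <- function(col) {
    if (col %in% names(samples)) mg_to_meq(samples[[col]], col)
    else numeric(nrow(samples))
  }
  ca <- meq("Ca"); mg <- meq("Mg"); na <- meq("Na"); k <- meq("K")
  hco3 <- meq("HCO3"); co3 <- meq("CO3"); cl <- meq("Cl"); so4 <- meq("SO4")
  cat_sum <- ca + mg + na + k
  an_sum  <- hco3 + co3 + cl + so4 + meq("NO3")
  if (any(cat_sum == 0) || any(an_sum == 0)) {
    stop("Chadha coordinates undefined: zero cation or anion meq sum")
  }
  x <- 100 * ((ca + mg) - (na + k)) / cat_sum
  y <- 100 * ((co3 + hco3) - (cl + so4)) / an_sum
  # axis ties go to the positive side
  zone <- ifelse(x >= 0,
                 ifelse(y >= 0, 5L, 6L),
                 ifelse(y >= 0, 8L, 7L))
  types <- c(`5` = "Ca-Mg-HCO3", `6` = "Ca-Mg-Cl",
             `7` = "Na-Cl", `8` = "Na-HCO3")
  data.frame(
    x = x, y = y, zone = zone,
    water_type = unname(types[as.character(zone)]),
    alkaline_earth_dominant = x >= 0,
    alkali_dominant = x < 0,
    weak_acid_dominant = y >= 0,
    strong_acid_dominant = y < 0,
    near_axis = abs(y) < equiline_band,
    stringsAsFactors = FALSE
  )
}

#' TDS-TH water class
#'
#' Quadrant classification of waters by total hardness (soft vs hard)
#' and total dissolved solids (fresh vs brackish). Boundary values go
#' to the upper class. With `th_only = TRUE` the salinity split is
#' ignored and every sample is labelled brackish — some published TDS-TH
#' diagrams label low-TDS waters brackish, inconsistent with the
#' conventional 1000 mg/L fresh boundary, and this mode reproduces such
#' labels through the hardness split alone.
#'
#' @param th Total hardness, mg/L as CaCO3.
#' @param tds Total dissolved solids, mg/L.
#' @param th_threshold Soft/hard boundary (default 180).
#' @param tds_threshold Fresh/brackish boundary (default 1000).
#' @param th_only Collapse the salinity axis to "brackish"?
#' @return Character vector in `{soft-fresh, hard-fresh, soft-brackish,
#'   hard-brackish}`.
#' @examples
#' tds_th_class(174.28, 300, th_only = TRUE)  # soft-brackish
#' @export
tds_th_class <- function(th, tds, th_threshold = 180,
                         tds_threshold = 1000, th_only = FALSE) {
  hard <- th >= th_threshold
  brackish <- if (th_only) rep(TRUE, length(th)) else tds >= tds_threshold
  paste0(ifelse(hard, "hard", "soft"), "-",
         ifelse(brackish, "brackish", "fresh"))
}

#' Ionic molar-ratio panel
#'
#' Computes the molar ratios used for source attribution (Na/Cl,
#' Ca/SO4, Ca/HCO3, Mg/Na, Ca/Na, HCO3/Na, NO3/Na, Cl/Na, SO4/Na) plus
#' the equivalent-sum ratio (Ca+Mg)/(HCO3+SO4). Ratios with a zero
#' denominator are returned as `NA` and listed in the `zero_denominator`
#' attribute rather than as infinities.
#'
#' @param samples Data frame with ion columns in mg/L.
#' @return Data frame of ratios, one row per sample, with attribute
#'   `zero_denominator` (named list of affected row indices).
#' @examples
#' ratio_panel(data.frame(Na = 22.98977, Cl = 35.4527, Ca = 40.078,
#'                        HCO3 = 122.032, Mg = 0, K = 0, SO4 = 96.06,
#'                        NO3 = 0))
#' @export
ratio_panel <- function(samples) {
  samples <- .validate_samples(samples)
  mol <- function(col) {
    if (col %in% names(samples)) {
      samples[[col]] / ion_spec(col)$molar_mass
    } else numeric(nrow(samples))
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  na <- mol("Na"); cl <- mol("Cl"); ca <- mol("Ca"); mg <- mol("Mg")
  hco3 <- mol("HCO3"); so4 <- mol("SO4"); no3 <- mol("NO3")
  meq <- function(col) if (col %in% names(samples))
    mg_to_meq(samples[[col]], col) else numeric(nrow(samples))
  out <- data.frame(
    Na_Cl    = safe_div(na, cl),
    Ca_SO4   = safe_div(ca, so4),
    Ca_HCO3  = safe_div(ca, hco3),
    Mg_Na    = safe_div(mg, na),
    Ca_Na    = safe_div(ca, na),
    HCO3_Na  = safe_div(hco3, na),
    NO3_Na   = safe_div(no3, na),
    Cl_Na    = safe_div(cl, na),
    SO4_Na   = safe_div(so4, na),
    CaMg_HCO3SO4 = safe_div(meq("Ca") + meq("Mg"),
                            meq("HCO3") + meq("SO4"))
  )
  zero <- lapply(out, function(v) which(is.na(v)))
  attr(out, "zero_denominator") <- zero[lengths(zero) > 0]
  out
}

#' Qualitative source labels from the ratio panel
#'
#' Deterministic rules of thumb used in groundwater provenance work:
#' Na/Cl above 1 points to silicate weathering / cation exchange as the
#' sodium source, below 1 to anthropogenic input or reverse exchange;
#' the equivalent ratio (Ca+Mg)/(HCO3+SO4) above 1 marks carbonate
#' dissolution dominance, below 1 silicate weathering influence, and
#' within `mixing_band` of 1 mixed carbonate/evaporite dissolution;
#' Ca/HCO3 between 1:4 and 1:2 (molar) is the carbonic-acid calcite
#' dissolution band. Missing (NA) ratios yield no label for that axis.
#'
#' @param panel Output of [ratio_panel()].
#' @param mixing_band Relative half-width of the equiline band
#'   (default 0.05, i.e. within 5% of 1).
#' @return List (one element per sample) of character label vectors.
#' @export
source_labels <- function(panel, mixing_band = 0.05) {
  lapply(seq_len(nrow(panel)), function(i) {
    lab <- character(0)
    nacl <- panel$Na_Cl[i]
    if (!is.na(nacl)) {
      lab <- c(lab, if (nacl > 1) "silicate-weathering/ion-exchange"
                    else if (nacl < 1) "anthropogenic/reverse-exchange")
    }
    eq <- panel$CaMg_HCO3SO4[i]
    if (!is.na(eq)) {
      lab <- c(lab, if (abs(eq - 1) <= mixing_band)
                      "carbonate+evaporite-mixing"
                    else if (eq > 1) "carbonate-dissolution-dominant"
                    else "silicate-weathering-influence")
    }
    cahco3 <- panel$Ca_HCO3[i]
    if (!is.na(cahco3) && cahco3 >= 0.25 && cahco3 <= 0.5) {
      lab <- c(lab, "carbonic-acid-calcite-dissolution")
    }
    lab
  })
}

# Gaillardet-style global end-member compositions on the Na-normalised
# axes (molar Ca/Na, Mg/Na, HCO3/Na). Reconstructed defaults, not
# site-specific ground truth; override freely.
.default_end_members <- data.frame(
  member  = c("carbonate", "silicate", "evaporite"),
  Ca_Na   = c(50, 0.35, 0.17),
  Mg_Na   = c(10, 0.24, 0.02),
  HCO3_Na = c(120, 2, 0.3),
  stringsAsFactors = FALSE
)

#' Assign samples to weathering end members
#'
#' Nearest end member in log10 space of the Na-normalised molar ratios
#' (Ca/Na, Mg/Na, HCO3/Na). Default end-member coordinates follow the
#' global riverine carbonate/silicate/evaporite values; they are
#' configurable because basin-specific boxes are rarely published.
#'
#' @param panel Output of [ratio_panel()].
#' @param end_members Data frame with columns `member`, `Ca_Na`,
#'   `Mg_Na`, `HCO3_Na`.
#' @return Character vector of end-member names (`NA` where any ratio
#'   is undefined).
#' @export
end_member_assignment <- function(panel,
                                  end_members = .default_end_members) {
  feat <- log10(as.matrix(panel[, c("Ca_Na", "Mg_Na", "HCO3_Na")]))
  ref <- log10(as.matrix(end_members[, c("Ca_Na", "Mg_Na", "HCO3_Na")]))
  apply(feat, 1L, function(f) {
    if (anyNA(f) || any(!is.finite(f))) return(NA_character_)
    d2 <- rowSums((ref - matrix(f, nrow(ref), 3, byrow = TRUE))^2)
    end_members$member[which.min(d2)]
  })
}

#' Per-season nitrate correlations
#'
#' Pearson correlation of NO3 with Cl and with TDS within each season;
#' an elevated NO3-Cl association is the classic fingerprint of
#' wastewater/agricultural co-input. Zero-variance vectors give `NA`.
#'
#' @param samples Data frame with `season`, `NO3`, `Cl` and optionally
#'   `TDS`.
#' @return Data frame with columns `season`, `n`, `r_NO3_Cl`,
#'   `r_NO3_TDS`.
#' @export
season_correlations <- function(samples) {
  samples <- .validate_samples(samples)
  safe_cor <- function(a, b) {
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  out <- do.call(rbind, lapply(split(samples, samples$season), function(d) {
    data.frame(
      season = d$season[1], n = nrow(d),
      r_NO3_Cl = safe_cor(d$NO3, d$Cl),
      r_NO3_TDS = if ("TDS" %in% names(d)) safe_cor(d$NO3, d$TDS)
                  else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Plot the Chadha rectangle
#'
#' Base-graphics rendering of [chadha_coordinates()] output with the
#' quadrant partition and zone numbers.
#'
#' @param coords Output of [chadha_coordinates()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `coords`.
#' @export
plot_chadha <- function(coords, ...) {
  graphics::plot(coords$x, coords$y, xlim = c(-100, 100),
                 ylim = c(-100, 100),
                 xlab = "(Ca+Mg) - (Na+K), meq-% of cations",
                 ylab = "(CO3+HCO3) - (Cl+SO4), meq-% of anions",
                 pch = 19, ...)
  graphics::abline(h = 0, v = 0, lty = 2)
  graphics::text(c(50, 50, -50, -50), c(50, -50, -50, 50),
                 labels = c("5: Ca-Mg-HCO3", "6: Ca-Mg-Cl",
                            "7: Na-Cl", "8: Na-HCO3"), col = "grey40")
  invisible(coords)
}
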