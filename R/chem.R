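#' @keywords internal
"_PACKAGE"

# Major-ion registry: IUPAC standard atomic weights (g/mol) and absolute
# valence (equivalents per mole). HCO3/CO3 masses are formula masses.
.ion_registry <- data.frame(
  ion        = c("Ca", "Mg", "Na", "K", "HCO3", "CO3", "Cl", "SO4", "NO3"),
  molar_mass = c(40.078, 24.305, 22.98977, 39.0983,
                 61.016, 60.008, 35.4527, 96.06, 62.0049),
  valence    = c(2L, 2L, 1L, 1L, 1L, 2L, 1L, 2L, 1L),
  stringsAsFactors = FALSE
)

.cation_names <- c("Ca", "Mg", "Na", "K")
.anion_names  <- c("HCO3", "CO3", "Cl", "SO4", "NO3")

#' Ion specification lookup
#'
#' Returns the molar mass and absolute valence for a registered major ion.
#'
#' @param ion Ion name, one of `"Ca"`, `"Mg"`, `"Na"`, `"K"`, `"HCO3"`,
#'   `"CO3"`, `"Cl"`, `"SO4"`, `"NO3"`.
#' @return A one-row data frame with columns `ion`, `molar_mass` (g/mol)
#'   and `valence` (equivalents/mol).
#' @examples
#' ion_spec("Ca")
#' @export
ion_spec <- function(ion) {
  i <- match(ion, .ion_registry$ion)
  if (anyNA(i)) {
    stop("unknown ion(s): ", paste(ion[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  .ion_registry[i, , drop = FALSE]
}

#' Convert a mass concentration to milliequivalents per litre
#'
#' meq/L = mg/L x valence / molar mass. All facies and ratio diagnostics
#' in this package work on the equivalent scale.
#'
#' @param conc Concentration in mg/L (vectorised, must be >= 0).
#' @param ion Ion name (recycled against `conc`), see [ion_spec()].
#' @return Concentration in meq/L.
#' @examples
#' mg_to_meq(40.078, "Ca")   # one mmol of a divalent ion -> 2 meq/L
#' mg_to_meq(235, "HCO3")
#' @export
mg_to_meq <- function(conc, ion) {
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  spec <- ion_spec(ion)
  conc * spec$valence / spec$molar_mass
}

#' Total hardness from calcium and magnesium
#'
#' Standard hydrochemical identity `TH = 2.497 Ca + 4.115 Mg`, expressed
#' as mg/L CaCO3 equivalent.
#'
#' @param ca,mg Calcium and magnesium concentrations in mg/L (>= 0).
#' @return Total hardness in mg/L as CaCO3.
#' @examples
#' total_hardness(82.78, 37.15)
#' @export
total_hardness <- function(ca, mg) {
  if (any(ca < 0, na.rm = TRUE) || any(mg < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0")
  }
  2.497 * ca + 4.115 * mg
}

#' Charge balance error of water analyses
#'
#' CBE (%) = 100 (sum cations - sum anions) / (sum cations + sum anions),
#' on the meq/L scale. Analyses with |CBE| > 10 are flagged with a
#' warning (conventional laboratory acceptance band) but still returned.
#'
#' @param samples Data frame with ion columns in mg/L (any of `Ca`, `Mg`,
#'   `Na`, `K`, `HCO3`, `CO3`, `Cl`, `SO4`, `NO3`; missing columns count
#'   as zero).
#' @param warn Emit a warning for analyses with |CBE| > 10? Default `TRUE`.
#' @return Numeric vector of CBE percentages, one per row.
#' @examples
#' charge_balance_error(data.frame(Na = 22.98977, Cl = 35.4527))
#' @export
charge_balance_error <- function(samples, warn = TRUE) {
  samples <- as.data.frame(samples)
  meq_sum <- function(ions) {
    tot <- numeric(nrow(samples))
    for (ion in ions) {
      if (ion %in% names(samples)) {
        v <- samples[[ion]]
        v[is.na(v)] <- 0
        tot <- tot + mg_to_meq(v, ion)
      }
    }
    tot
  }
  cat_meq <- meq_sum(.cation_names)
  an_meq  <- meq_sum(.anion_names)
  if (any(cat_meq + an_meq == 0)) {
    stop("charge balance undefined: all-zero ion vector in at least one row")
  }
  cbe <- 100 * (cat_meq - an_meq) / (cat_meq + an_meq)
  if (warn && any(abs(cbe) > 10)) {
    warning(sum(abs(cbe) > 10),
            " analysis/analyses with |CBE| > 10% (poor ionic balance)")
  }
  cbe
}

#' WHO-based drinking water standards table
#'
#' Permissible limits used for guideline screening and for the EWQI
#' quality ratings. pH is screened against a band rather than a single
#' limit. Defaults follow the WHO drinking-water guidelines as applied
#' to this parameter set; any limit can be overridden.
#'
#' @param limits Named numeric vector of permissible limits (units match
#'   the measured parameter: mg/L except EC in uS/cm). Positive values
#'   only.
#' @param ph_band Length-2 numeric, the acceptable pH interval
#'   (lower < upper).
#' @return An object of class `standards_table`.
#' @examples
#' std <- who_standards()
#' std$limits[["NO3"]]
#' @export
who_standards <- function(limits = NULL, ph_band = c(6.5, 8.5)) {
  default <- c(EC = 1500, TDS = 1000, TH = 500, BOD = 5, COD = 20,
               Ca = 200, Mg = 50, Na = 200, K = 12,
               Cl = 250, SO4 = 250, NO3 = 50)
  if (!is.null(limits)) default[names(limits)] <- limits
  if (any(default <= 0)) stop("all permissible limits must be positive")
  if (length(ph_band) != 2 || ph_band[1] >= ph_band[2]) {
    stop("ph_band must be (lower, upper) with lower < upper")
  }
  structure(list(limits = default, ph_band = ph_band),
            class = "standards_table")
}

#' Read a standards table from a key-value file
#'
#' Plain-text file with one `parameter = limit` pair per line; `#` starts
#' a comment. The keys `pH_min`/`pH_max` set the pH band.
#'
#' @param path File path.
#' @return A [who_standards()] object.
#' @export
read_standards <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed standards line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 1L)
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  if (anyNA(vals)) stop("non-numeric limit in standards file")
  band <- c(6.5, 8.5)
  if ("pH_min" %in% keys) band[1] <- vals[keys == "pH_min"]
  if ("pH_max" %in% keys) band[2] <- vals[keys == "pH_max"]
  keep <- !(keys %in% c("pH_min", "pH_max"))
  lim <- vals[keep]
  names(lim) <- keys[keep]
  who_standards(limits = lim, ph_band = band)
}

#' @export
print.standards_table <- function(x, ...) {
  cat("Drinking-water standards (", length(x$limits), " parameters)\n",
      sep = "")
  cat("  pH band: ", x$ph_band[1], "-", x$ph_band[2], "\n", sep = "")
  print(x$limits)
  invisible(x)
}

# Validate and normalise a samples table: season enum, non-negative
# concentrations, pH range, TH completed from Ca/Mg where absent,
# CO3 defaulting to 0.
.validate_samples <- function(samples) {
  samples <- as.data.frame(samples)
  if (!"CO3" %in% names(samples)) samples$CO3 <- 0
  samples$CO3[is.na(samples$CO3)] <- 0
  if ("season" %in% names(samples)) {
    bad <- !samples$season %in% c("wet", "dry")
    if (any(bad)) stop("season must be 'wet' or 'dry'")
  }
  if ("pH" %in% names(samples) &&
      any(samples$pH < 0 | samples$pH > 14, na.rm = TRUE)) {
    stop("pH outside [0, 14]")
  }
  conc_cols <- intersect(c("EC", "TDS", "TH", "BOD", "COD",
                           .cation_names, .anion_names), names(samples))
  for (cc in conc_cols) {
    if (any(samples[[cc]] < 0, na.rm = TRUE)) {
      stop("negative concentration in column ", cc)
    }
  }
  if (all(c("Ca", "Mg") %in% names(samples))) {
    th <- total_hardness(samples$Ca, samples$Mg)
    if (!"TH" %in% names(samples)) {
      samples$TH <- th
    } else {
      miss <- is.na(samples$TH)
      samples$TH[miss] <- th[miss]
    }
  }
  samples
}

#' Read a per-well samples table
#'
#' One row per well-season; expected columns are `well_id`, `season`
#' (`"wet"`/`"dry"`), planar coordinates `x`, `y`, optional `depth_m`,
#' `pH`, `EC` (uS/cm), `TDS`, `TH`, `BOD`, `COD` and the major ions
#' `Ca`, `Mg`, `Na`, `K`, `HCO3`, `CO3`, `Cl`, `SO4`, `NO3` (mg/L).
#' Missing `TH` is completed from Ca and Mg; missing `CO3` defaults to 0.
#'
#' @param path CSV file path.
#' @return Validated data frame of samples.
#' @export
read_samples <- function(path) {
  .validate_samples(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Screen samples against drinking-water standards
#'
#' Flags, per sample, every parameter strictly above its permissible
#' limit (a value exactly at the limit passes); pH outside the standards
#' band counts as an exceedance. Parameters without a measured value are
#' reported as not screened, never silently passed. Per-season
#' within-limit and exceedance fractions are tabulated per parameter.
#'
#' @param samples Data frame of samples (see [read_samples()]).
#' @param standards A [who_standards()] object.
#' @param parameters Parameters to screen; default all limits present in
#'   both the standards and the data, plus pH if present.
#' @return An object of class `gw_screening`: list with `flags` (per
#'   sample, character vector of exceeded parameters), `not_screened`,
#'   `table` (logical sample x parameter exceedance matrix) and
#'   `season_summary` (per season/parameter counts and percentages,
#'   rounded half-up to 2 decimals).
#' @examples
#' d <- data.frame(well_id = "w1", season = "wet", pH = 7.4, NO3 = 61)
#' screen_samples(d)$flags
#' @export
screen_samples <- function(samples, standards = who_standards(),
                           parameters = NULL) {
  samples <- .validate_samples(samples)
  all_params <- c(names(standards$limits), "pH")
  if (is.null(parameters)) {
    parameters <- intersect(all_params, names(samples))
  } else {
    unknown <- setdiff(setdiff(parameters, "pH"), names(standards$limits))
    if (length(unknown)) {
      stop("no standard registered for: ", paste(unknown, collapse = ", "))
    }
  }
  m <- nrow(samples)
  exceed <- matrix(NA, m, length(parameters),
                   dimnames = list(NULL, parameters))
  for (p in parameters) {
    v <- if (p %in% names(samples)) samples[[p]] else rep(NA_real_, m)
    exceed[, p] <- if (p == "pH") {
      v < standards$ph_band[1] | v > standards$ph_band[2]
    } else {
      v > standards$limits[[p]]   # strict: value at the limit passes
    }
  }
  flags <- lapply(seq_len(m), function(i) {
    r <- exceed[i, ]
    names(r)[!is.na(r) & r]
  })
  not_screened <- lapply(seq_len(m), function(i) {
    names(exceed[i, ])[is.na(exceed[i, ])]
  })
  season <- if ("season" %in% names(samples)) samples$season
            else rep("all", m)
  summ <- do.call(rbind, lapply(split(seq_len(m), season), function(idx) {
    do.call(rbind, lapply(parameters, function(p) {
      e <- exceed[idx, p]
      n_ok <- sum(!is.na(e))
      data.frame(season = season[idx[1]], parameter = p,
                 n = n_ok, n_exceeding = sum(e, na.rm = TRUE),
                 pct_exceeding = if (n_ok)
                   round_half_up(100 * sum(e, na.rm = TRUE) / n_ok, 2)
                   else NA_real_,
                 pct_within = if (n_ok)
                   round_half_up(100 * sum(!e, na.rm = TRUE) / n_ok, 2)
                   else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  structure(list(flags = flags, not_screened = not_screened,
                 table = exceed, season_summary = summ,
                 samples = samples, standards = standards),
            class = "gw_screening")
}

#' @export
print.gw_screening <- function(x, ...) {
  n_flag <- sum(lengths(x$flags) > 0)
  cat("Guideline screening of ", nrow(x$table), " samples: ",
      n_flag, " with at least one exceedance\n", sep = "")
  print(x$season_summary[x$season_summary$n_exceeding > 0, ])
  invisible(x)
}

#' Round half away from zero
#'
#' Percentage reports use commercial (half-up) rounding rather than
#' banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
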