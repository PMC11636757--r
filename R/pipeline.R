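# 32-bit FNV-1a hash of a character scalar, as 8 hex digits; used to
# stamp artifacts with the configuration they came from. The modular
# multiply by the FNV prime is split into 16-bit halves so every
# intermediate stays exactly representable in a double.
.fnv1a <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(txt))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %%
      4294967296
  }
  hex <- "0123456789abcdef"
  out <- character(8)
  for (i in 8:1) {
    out[i] <- substr(hex, h %% 16 + 1, h %% 16 + 1)
    h <- (h - h %% 16) / 16
  }
  paste(out, collapse = "")
}

.config_hash <- function(config) {
  .fnv1a(paste(utils::capture.output(utils::str(config)),
               collapse = "\n"))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

.stamp <- function(meta, out_dir, stage) {
  .write_json(meta, file.path(out_dir, paste0(stage, "_meta.json")))
}

#' Run the full groundwater assessment pipeline
#'
#' Orchestrates all stages on one samples table: guideline screening,
#' facies and ratio diagnostics, per-season EWQI on the configured
#' well subset, nitrate health risk for the three receptor groups, IDW
#' rasters of NO3 / EWQI / HI, and an aggregated report. Every
#' artifact directory gains JSON metadata embedding the seed and a
#' hash of the configuration.
#'
#' @param out_dir Output directory (created if absent).
#' @param samples Data frame of samples; by default generated
#'   synthetically from `config` and `seed`.
#' @param config A [generator_config()] (also supplies the EWQI well
#'   subset).
#' @param seed RNG seed used when `samples` is generated.
#' @param standards A [who_standards()] table.
#' @param profiles Receptor profiles, default [default_profiles()].
#' @param ewqi_params EWQI parameter set.
#' @param cellsize IDW raster cell size (coordinate units).
#' @param idw_power IDW distance-decay power.
#' @return Invisibly, a list with the stage results (`samples`,
#'   `screening`, `facies`, `ewqi` (per season), `risk`, `summary`).
#' @export
run_pipeline <- function(out_dir, samples = NULL,
                         config = generator_config(), seed = 1,
                         standards = who_standards(),
                         profiles = default_profiles(),
                         ewqi_params = c("pH", "TH", "BOD", "COD",
                                         "Ca", "NO3"),
                         cellsize = 0.5, idw_power = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = seed, config_hash = .config_hash(config))

  if (is.null(samples)) {
    samples <- generate_groundwater(config, seed = seed)
  } else {
    samples <- .validate_samples(samples)
  }
  utils::write.csv(samples, file.path(out_dir, "samples.csv"),
                   row.names = FALSE)
  .stamp(c(meta, list(stage = "simulate", rows = nrow(samples))),
         out_dir, "simulate")

  scr <- screen_samples(samples, standards)
  flag_df <- data.frame(
    well_id = samples$well_id, season = samples$season,
    exceeding = vapply(scr$flags, paste, "", collapse = ";"),
    not_screened = vapply(scr$not_screened, paste, "", collapse = ";"),
    CBE_pct = round_half_up(charge_balance_error(samples, warn = FALSE),
                            2),
    stringsAsFactors = FALSE)
  utils::write.csv(flag_df, file.path(out_dir, "screening.csv"),
                   row.names = FALSE)
  .write_json(list(meta = meta, season_summary = scr$season_summary),
              file.path(out_dir, "screening.json"))

  cc <- chadha_coordinates(samples)
  rp <- ratio_panel(samples)
  fac <- cbind(samples[, c("well_id", "season")], cc, rp)
  fac$tds_th_class <- tds_th_class(samples$TH, samples$TDS,
                                   th_only = TRUE)
  fac$end_member <- end_member_assignment(rp)
  fac$source_labels <- vapply(source_labels(rp), paste, "",
                              collapse = ";")
  utils::write.csv(fac, file.path(out_dir, "facies.csv"),
                   row.names = FALSE)

  seasons <- unique(samples$season)
  subset_ids <- intersect(config$ewqi_subset, samples$well_id)
  ewqi_fits <- lapply(stats::setNames(seasons, seasons), function(s) {
    d <- samples[samples$season == s &
                   samples$well_id %in% subset_ids, ]
    ewqi(d, parameters = ewqi_params, standards = standards)
  })
  ewqi_df <- do.call(rbind, lapply(seasons, function(s) {
    f <- ewqi_fits[[s]]
    data.frame(well_id = f$wells, season = s,
               EWQI = round_half_up(f$score, 2),
               rank = as.character(f$rank), class = f$label,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(ewqi_df, file.path(out_dir, "ewqi.csv"),
                   row.names = FALSE)
  .write_json(list(meta = meta, runs = lapply(ewqi_fits, function(f) {
    list(parameters = f$parameters, entropy = as.list(f$entropy),
         weights = as.list(f$weights))
  })), file.path(out_dir, "ewqi.json"))

  risk <- do.call(rbind, lapply(profiles, function(pr) {
    hazard(samples$NO3, pr, well_id = samples$well_id,
           season = samples$season)
  }))
  risk$CDI <- round(risk$CDI, 4)
  risk$HQ <- round_half_up(risk$HQ, 2)
  risk$HI <- round_half_up(risk$HI, 2)
  utils::write.csv(risk, file.path(out_dir, "risk.csv"),
                   row.names = FALSE)
  unrounded <- do.call(rbind, lapply(profiles, function(pr) {
    hazard(samples$NO3, pr, well_id = samples$well_id,
           season = samples$season)
  }))
  psum <- population_summary(unrounded)
  .write_json(list(meta = meta, summary = psum$summary,
                   ordering = psum$ordering),
              file.path(out_dir, "risk.json"))

  bb <- config$bbox
  for (s in seasons) {
    d <- samples[samples$season == s, ]
    g_no3 <- rasterize_idw(d$x, d$y, d$NO3, bb, cellsize, idw_power)
    write_esri_ascii(g_no3, file.path(out_dir,
                                      paste0("no3_", s, ".asc")))
    write_esri_ascii(
      classify_grid(g_no3, standards$limits[["NO3"]]),
      file.path(out_dir, paste0("no3_class_", s, ".asc")))
    hi_ad <- hazard(d$NO3, profiles$adults)$HI
    g_hi <- rasterize_idw(d$x, d$y, hi_ad, bb, cellsize, idw_power)
    write_esri_ascii(g_hi, file.path(out_dir,
                                     paste0("hi_adults_", s, ".asc")))
    f <- ewqi_fits[[s]]
    ds <- d[d$well_id %in% f$wells, ]
    sc <- f$score[match(ds$well_id, f$wells)]
    g_ew <- rasterize_idw(ds$x, ds$y, sc, bb, cellsize, idw_power)
    write_esri_ascii(g_ew, file.path(out_dir,
                                     paste0("ewqi_", s, ".asc")))
    write_class_csv(classify_grid(g_ew, f$thresholds),
                    file.path(out_dir, paste0("ewqi_class_", s,
                                              ".csv")))
  }

  report <- .build_report(samples, scr, ewqi_df, psum, meta)
  writeLines(report$md, file.path(out_dir, "report.md"))
  .write_json(report$json, file.path(out_dir, "report.json"))

  invisible(list(samples = samples, screening = scr, facies = fac,
                 ewqi = ewqi_fits, risk = unrounded, summary = psum,
                 meta = meta))
}

# Aggregate stage outputs into a markdown + JSON report: per-season
# statistics table, EWQI table, risk table.
.build_report <- function(samples, scr, ewqi_df, psum, meta) {
  params <- intersect(c("pH", "EC", "TDS", "TH", "BOD", "COD", "Ca",
                        "Mg", "Na", "K", "HCO3", "Cl", "SO4", "NO3"),
                      names(samples))
  stats_tab <- do.call(rbind, lapply(split(samples, samples$season),
                                     function(d) {
    do.call(rbind, lapply(params, function(p) {
      v <- d[[p]]
      data.frame(season = d$season[1], parameter = p,
                 min = round(min(v), 3), mean = round(mean(v), 3),
                 max = round(max(v), 3), stringsAsFactors = FALSE)
    }))
  }))
  rownames(stats_tab) <- NULL
  md <- c(
    paste0("# Groundwater assessment report (seed ", meta$seed,
           ", config ", meta$config_hash, ")"),
    "", "## Per-season summary statistics", "",
    .md_table(stats_tab),
    "", "## EWQI", "", .md_table(ewqi_df),
    "", "## Nitrate health risk", "", .md_table(psum$summary))
  list(md = md,
       json = list(meta = meta, statistics = stats_tab,
                   ewqi = ewqi_df, risk = psum$summary,
                   risk_ordering = psum$ordering))
}

.md_table <- function(df) {
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1L, function(r) {
    paste("|", paste(r, collapse = " | "), "|")
  })
  c(hdr, sep, rows)
}
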