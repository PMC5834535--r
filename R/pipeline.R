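# Config-driven orchestration: synthetic or CSV inputs -> community series ->
# coherence/phase per variable pair -> band phase statistics -> ENSO events ->
# anomaly series -> monthly LAI, with a reproducibility manifest.

#' Pipeline configuration
#'
#' @param input_dir directory of input CSVs (`climate.csv`, `oni.csv`,
#'   `seed_traps.csv`, `leaf_traps.csv`, `species_meta.csv`, optionally
#'   `gap_fractions.csv`, `lifespans.csv`; the dialects of
#'   [write_synth_fixtures()]); `NULL` to generate synthetic inputs in memory.
#' @param synth a [synth_config()] used when `input_dir` is `NULL`.
#' @param pairs two-column matrix/list of series pairs (phenology first, so
#'   positive phase = phenology lags); default: seed and leaf fall against
#'   deficit, radiation and VPD, plus leaf against seed.
#' @param seasonal_band,enso_band period bands in weeks; defaults ~12 months
#'   and 2-7 years.
#' @param coh_min coherence threshold for phase selection (default 0.5).
#' @param alpha significance level (default 0.05).
#' @param n_surrogates Monte-Carlo surrogate pairs; 0 skips significance.
#' @param voices wavelet scales per octave.
#' @param seed_min_censuses,leaf_min_censuses inclusion thresholds (strict >).
#' @param running_mean_weeks anomaly smoothing window (default 13, ~3 months).
#' @param rng_seed integer seed for all stochastic steps.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            synth = synth_config(),
                            pairs = NULL,
                            seasonal_band = c(0.8, 1.25) * 365.25 / 7,
                            enso_band = c(2, 7) * 365.25 / 7,
                            coh_min = 0.5,
                            alpha = 0.05,
                            n_surrogates = 0,
                            voices = 12,
                            seed_min_censuses = 10,
                            leaf_min_censuses = 3,
                            running_mean_weeks = 13,
                            rng_seed = 1L) {
  if (!(alpha > 0 && alpha <= 1)) abort("`alpha` must be in (0, 1]")
  if (is.null(pairs)) {
    pairs <- rbind(
      c("seed", "deficit"), c("seed", "radiation"), c("seed", "vpd"),
      c("leaf", "deficit"), c("leaf", "radiation"), c("leaf", "vpd"),
      c("leaf", "seed")
    )
  }
  structure(
    list(input_dir = input_dir, synth = synth, pairs = pairs,
         seasonal_band = seasonal_band, enso_band = enso_band,
         coh_min = coh_min, alpha = alpha, n_surrogates = n_surrogates,
         voices = voices, seed_min_censuses = seed_min_censuses,
         leaf_min_censuses = leaf_min_censuses,
         running_mean_weeks = running_mean_weeks, rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

read_pipeline_inputs <- function(dir) {
  rd <- function(f, required = TRUE) {
    path <- file.path(dir, f)
    if (!file.exists(path)) {
      if (required) abort(sprintf("missing input file: %s", path))
      return(NULL)
    }
    readr::read_csv(path, show_col_types = FALSE)
  }
  list(climate = rd("climate.csv"), oni = rd("oni.csv"),
       seed_traps = rd("seed_traps.csv"), leaf_traps = rd("leaf_traps.csv"),
       species_meta = rd("species_meta.csv"),
       gap_fractions = rd("gap_fractions.csv", required = FALSE),
       lifespans = rd("lifespans.csv", required = FALSE))
}

#' Build the analysis-ready weekly table from raw inputs
#'
#' Seed equivalents, species filtering (strict census thresholds plus the
#' metadata exclusion list), community averaging of z-scored species series,
#' soil water deficit from soil water content, and weekly VPD; community
#' series with missing weeks are linearly imputed for the wavelet step.
#'
#' @param inputs list with `climate`, `seed_traps`, `leaf_traps`,
#'   `species_meta` (see [read_pipeline_inputs()] / [synth_phenology()]).
#' @param cfg a [pipeline_config()].
#' @return tibble with columns `date`, `seed`, `leaf`, `deficit`, `radiation`,
#'   `vpd`, `streamflow`.
#' @export
prepare_analysis_table <- function(inputs, cfg = pipeline_config()) {
  excl <- inputs$species_meta$species[isTRUE_vec(inputs$species_meta$exclude)]
  seeds <- seed_equivalents(inputs$seed_traps, species_meta = inputs$species_meta) |>
    filter_species(min_censuses = cfg$seed_min_censuses, exclude = excl,
                   record_cols = "seeds")
  seed_comm <- community_series(seeds, value = "seeds")
  leaves <- filter_species(inputs$leaf_traps, min_censuses = cfg$leaf_min_censuses,
                           exclude = excl, record_cols = "dry_mass")
  leaf_comm <- community_series(leaves, value = "dry_mass")
  deficit <- soil_water_deficit(
    select(inputs$climate, "date", "swc"),
    weekly_dates = inputs$climate$date
  )
  out <- tibble(
    date = inputs$climate$date,
    radiation = inputs$climate$radiation,
    vpd = vpd_from_weekly(inputs$climate$temperature, inputs$climate$rh),
    streamflow = inputs$climate$streamflow
  ) |>
    left_join(tibble(date = deficit$date, deficit = deficit$value), by = "date") |>
    left_join(tibble(date = seed_comm$date, seed = seed_comm$value), by = "date") |>
    left_join(tibble(date = leaf_comm$date, leaf = leaf_comm$value), by = "date")
  for (v in c("seed", "leaf", "deficit", "radiation", "vpd", "streamflow")) {
    if (anyNA(out[[v]])) out[[v]] <- impute_missing(out, v)[[v]]
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE

#' Run the full phenology-climate wavelet pipeline
#'
#' Executes the end-to-end analysis on synthetic or CSV inputs and writes the
#' artifact directory: the analysis-ready community/climate table, per-pair
#' coherence and phase grids (tidy CSV), band-restricted phase samples,
#' circular summaries and histograms for the seasonal and ENSO bands, the ENSO
#' event table, seasonally detrended 3-month running-mean anomalies, monthly
#' LAI (when gap fractions are available), and a `manifest.json` recording the
#' config hash, seed and package version. Failure of one pair is logged and
#' the remaining pairs proceed.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory results (`table`, `coherence`
#'   per pair, `phases`, `phase_summary`, `enso_events`, `lai_monthly`,
#'   `manifest`, `failures`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("phenowave_run_")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- if (is.null(cfg$input_dir)) {
    cl <- synth_climate(cfg$synth)
    ph <- synth_phenology(cl, cfg$synth)
    lt <- synth_lai_trajectory(cl)
    monthly <- lt[!duplicated(lubridate::floor_date(lt$date, "month")), ]
    list(climate = cl$climate, oni = cl$oni, seed_traps = ph$seed_traps,
         leaf_traps = ph$leaf_traps, species_meta = ph$species_meta,
         gap_fractions = synth_gap_fractions(monthly, rng_seed = cfg$synth$rng_seed),
         lifespans = synth_lifespans(rng_seed = cfg$synth$rng_seed))
  } else {
    read_pipeline_inputs(cfg$input_dir)
  }
  tab <- prepare_analysis_table(inputs, cfg)
  readr::write_csv(tab, file.path(out_dir, "analysis_table.csv"))

  sg <- scale_grid(n = nrow(tab), dt = 1, voices = cfg$voices)
  bands <- list(seasonal = cfg$seasonal_band, enso = cfg$enso_band)
  results <- list(); phases <- list(); summaries <- list(); failures <- character()
  for (i in seq_len(nrow(cfg$pairs))) {
    xn <- cfg$pairs[i, 1]; yn <- cfg$pairs[i, 2]
    key <- paste0(xn, "_", yn)
    res <- tryCatch({
      co <- wavelet_coherence(tab, x = !!xn, y = !!yn, dt = 1, scale_spec = sg)
      if (cfg$n_surrogates > 0) {
        co <- coherence_significance(tab, x = !!xn, y = !!yn, dt = 1,
                                     scale_spec = sg, alpha = cfg$alpha,
                                     n_surrogates = cfg$n_surrogates,
                                     rng_seed = cfg$rng_seed + i, object = co)
      }
      co
    }, error = function(e) {
      warn(sprintf("pair %s failed: %s", key, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { failures <- c(failures, key); next }
    results[[key]] <- res
    readr::write_csv(tidy(res), file.path(out_dir, sprintf("coherence_%s.csv", key)))
    for (b in names(bands)) {
      ps <- suppressWarnings(
        band_select(res, bands[[b]][1], bands[[b]][2], coh_min = cfg$coh_min)
      )
      phases[[paste(key, b, sep = "_")]] <- ps
      readr::write_csv(ps, file.path(out_dir, sprintf("phase_%s_%s.csv", key, b)))
      if (nrow(ps) > 0) {
        cs <- circular_mean_sd(ps)
        lag_wk <- mean(angle_to_lag(ps$angle_deg, ps$period))
        summaries[[paste(key, b, sep = "_")]] <- mutate(
          cs, pair = key, band = b, mean_lag_weeks = lag_wk,
          .before = 1
        )
      }
    }
  }
  phase_summary <- bind_rows(summaries)
  readr::write_csv(phase_summary, file.path(out_dir, "phase_summary.csv"))

  enso_events <- identify_enso_events(inputs$oni)
  readr::write_csv(enso_events, file.path(out_dir, "enso_events.csv"))

  anoms <- purrr::map(c("seed", "leaf", "deficit", "radiation", "vpd"), function(v) {
    a <- seasonal_detrend(tab, value = v)
    tibble(date = a$date, variable = v, anomaly = a$value,
           anomaly_3mo = running_mean(a$value, cfg$running_mean_weeks))
  }) |> bind_rows()
  readr::write_csv(anoms, file.path(out_dir, "anomalies.csv"))

  lai_monthly <- NULL
  if (!is.null(inputs$gap_fractions)) {
    lai_monthly <- inputs$gap_fractions |>
      lai_from_gap_fraction() |>
      aggregate_lai()
    readr::write_csv(lai_monthly, file.path(out_dir, "lai_monthly.csv"))
  }
  if (!is.null(inputs$lifespans)) {
    readr::write_csv(lifespan_histogram(inputs$lifespans, group = "stratum"),
                     file.path(out_dir, "lifespan_histogram.csv"))
  }

  manifest <- list(
    package = "phenowave",
    version = as.character(utils::packageVersion("phenowave")),
    config_hash = rlang::hash(cfg),
    rng_seed = cfg$rng_seed,
    n_weeks = nrow(tab),
    pairs_done = names(results),
    pairs_failed = failures,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- list(table = tab, coherence = results, phases = phases,
              phase_summary = phase_summary, enso_events = enso_events,
              lai_monthly = lai_monthly, manifest = manifest,
              failures = failures, out_dir = out_dir)
  if (length(failures) > 0) {
    warn(sprintf("pipeline finished with %d failed pair(s)", length(failures)))
  }
  invisible(out)
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are a validation error before any computation; the `synth`
#' block is passed to [synth_config()].
#'
#' @param path YAML file.
#' @return [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$synth)) {
    known_s <- names(formals(synth_config))
    unknown_s <- setdiff(names(raw$synth), known_s)
    if (length(unknown_s) > 0) {
      abort(sprintf("unknown synth config key(s): %s", paste(unknown_s, collapse = ", ")))
    }
    sl <- raw$synth
    for (nm in c("seasonal_amplitudes", "enso_amplitudes", "leaf_lead_weeks",
                 "seed_lag_weeks", "noise_ar1", "noise_sd")) {
      if (!is.null(sl[[nm]])) sl[[nm]] <- unlist(sl[[nm]])
    }
    raw$synth <- do.call(synth_config, sl)
  }
  if (!is.null(raw$pairs)) raw$pairs <- do.call(rbind, raw$pairs)
  do.call(pipeline_config, raw)
}
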