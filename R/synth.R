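# Synthetic fixtures with known injected structure: ~30 years of weekly
# climate with an annual cycle plus a shared narrowband interannual (ENSO)
# mode, species-level phenology with configurable band-specific leads/lags
# relative to soil water deficit, a monthly ONI-like index, gap fractions from
# a known LAI trajectory, and leaf life spans. Every injected parameter is
# returned as ground truth so downstream estimates can be checked against it.

WEEKS_PER_YEAR <- 365.25 / 7

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the structure of a three-decade weekly record from a
#' seasonally dry tropical forest: a dominant annual cycle in every climate
#' variable, a shared 2-7-year narrowband ENSO mode (strongest in soil water
#' deficit, weakest in radiation), red (AR(1)) noise that is smoother in soil
#' moisture than in radiation, and community phenology in which leaf fall
#' leads soil water deficit and seed fall lags it, with separate seasonal-band
#' and ENSO-band lags.
#'
#' @param n_years length of the record (>= 8, so the 2-7-yr band lies inside
#'   the cone of influence for part of the record); default 30.
#' @param dt_weeks sampling interval, weeks (fixed at 1).
#' @param start_date first week.
#' @param seasonal_amplitudes,enso_amplitudes named per-variable amplitudes
#'   (standardised units) of the annual sinusoid and of the shared ENSO mode.
#' @param enso_period_years central period of the interannual mode, in (2, 7).
#' @param enso_bandwidth relative bandwidth of the narrowband mode (the mode
#'   is a sum of three sinusoids at periods `P0*(1-bw), P0, P0*(1+bw)`).
#' @param leaf_lead_weeks named vector `c(seasonal=, enso=)`: injected lead of
#'   leaf fall over soil water deficit, per band, in weeks.
#' @param seed_lag_weeks named vector `c(seasonal=, enso=)`: injected lag of
#'   seed fall behind soil water deficit, per band, in weeks.
#' @param n_species_seed,n_species_leaf species counts.
#' @param noise_ar1 named lag-1 autocorrelations of the red-noise components
#'   (`radiation`, `temperature`, `rh`, `deficit`, `streamflow`, `species`),
#'   each in `[0, 1)`.
#' @param noise_sd named standard deviations of the same noise components;
#'   `species` is the per-species latent noise.
#' @param rare_fraction fraction of species generated with fewer nonzero
#'   censuses than the community inclusion thresholds (exercises filtering).
#' @param seed_link `"log"` (Poisson counts around `exp(latent)`) or
#'   `"identity"` (counts around the latent itself).
#' @param sampling `"poisson"` for count sampling of seed traps, `"none"` for
#'   the noise-free deterministic limit.
#' @param rng_seed integer; per-component streams are derived from it so one
#'   module's fixtures are stable under changes to another's draw count.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_years = 30,
                         dt_weeks = 1,
                         start_date = as.Date("1987-01-05"),
                         seasonal_amplitudes = c(radiation = 1, temperature = 1,
                                                 rh = 1, deficit = 1, streamflow = 1),
                         enso_amplitudes = c(radiation = 0.25, temperature = 0.45,
                                             rh = 0.5, deficit = 0.8, streamflow = 0.6),
                         enso_period_years = 4,
                         enso_bandwidth = 0.15,
                         leaf_lead_weeks = c(seasonal = 6, enso = 17.4),
                         seed_lag_weeks = c(seasonal = 4, enso = 21.7),
                         n_species_seed = 60,
                         n_species_leaf = 80,
                         noise_ar1 = c(radiation = 0.3, temperature = 0.5, rh = 0.4,
                                       deficit = 0.85, streamflow = 0.7, species = 0.3),
                         noise_sd = c(radiation = 0.6, temperature = 0.35, rh = 0.45,
                                      deficit = 0.18, streamflow = 0.45, species = 0.6),
                         rare_fraction = 0.15,
                         seed_link = c("log", "identity"),
                         sampling = c("poisson", "none"),
                         rng_seed = 1L) {
  cfg <- list(
    n_years = n_years, dt_weeks = dt_weeks, start_date = as.Date(start_date),
    seasonal_amplitudes = seasonal_amplitudes, enso_amplitudes = enso_amplitudes,
    enso_period_years = enso_period_years, enso_bandwidth = enso_bandwidth,
    leaf_lead_weeks = leaf_lead_weeks, seed_lag_weeks = seed_lag_weeks,
    n_species_seed = n_species_seed, n_species_leaf = n_species_leaf,
    noise_ar1 = noise_ar1, noise_sd = noise_sd, rare_fraction = rare_fraction,
    seed_link = match.arg(seed_link), sampling = match.arg(sampling),
    rng_seed = as.integer(rng_seed)
  )
  fail <- function(field, why) abort(sprintf("invalid synth_config field `%s`: %s", field, why))
  if (!is.numeric(n_years) || n_years < 8) fail("n_years", "must be >= 8")
  if (dt_weeks != 1) fail("dt_weeks", "only weekly sampling (1) is supported")
  if (any(noise_ar1 < 0 | noise_ar1 >= 1)) fail("noise_ar1", "must be in [0, 1)")
  if (!(enso_period_years > 2 && enso_period_years < 7)) {
    fail("enso_period_years", "must lie in (2, 7)")
  }
  if (any(seasonal_amplitudes < 0)) fail("seasonal_amplitudes", "must be >= 0")
  if (any(enso_amplitudes < 0)) fail("enso_amplitudes", "must be >= 0")
  if (any(noise_sd < 0)) fail("noise_sd", "must be >= 0")
  if (!(enso_bandwidth >= 0 && enso_bandwidth < 0.5)) fail("enso_bandwidth", "must be in [0, 0.5)")
  if (rare_fraction < 0 || rare_fraction >= 1) fail("rare_fraction", "must be in [0, 1)")
  if (2 * enso_period_years > n_years) {
    fail("n_years", "record shorter than two ENSO periods")
  }
  structure(cfg, class = "synth_config")
}

# Evaluate the annual component at weeks t (0-based), optionally advanced by
# `shift` weeks (positive shift = the signal peaks earlier, i.e. leads).
seasonal_component <- function(t, shift = 0, peak_week = 10) {
  cos(2 * pi * (t + shift - peak_week) / WEEKS_PER_YEAR)
}

# The narrowband ENSO mode: sum of three sinusoids with seeded phases.
enso_mode_params <- function(cfg) {
  p0 <- cfg$enso_period_years * WEEKS_PER_YEAR
  periods <- p0 * c(1 - cfg$enso_bandwidth, 1, 1 + cfg$enso_bandwidth)
  set.seed(cfg$rng_seed + 11L)
  phases <- runif(3, 0, 2 * pi)
  list(periods = periods, amps = c(0.35, 0.5, 0.35), phases = phases)
}

enso_component <- function(t, mp, shift = 0) {
  out <- 0
  for (i in seq_along(mp$periods)) {
    out <- out + mp$amps[i] * cos(2 * pi * (t + shift) / mp$periods[i] + mp$phases[i])
  }
  out
}

# Independent brute-force run enumeration (kept separate from
# identify_enso_events so ground truth does not depend on the code under test).
enumerate_runs <- function(x, threshold, min_len) {
  out <- list()
  i <- 1L; n <- length(x)
  while (i <= n) {
    s <- if (x[i] > threshold) 1L else if (x[i] < -threshold) -1L else 0L
    j <- i
    while (j < n && (if (s > 0) x[j + 1] > threshold
                     else if (s < 0) x[j + 1] < -threshold else FALSE)) j <- j + 1L
    if (s != 0L && (j - i + 1L) >= min_len) {
      out[[length(out) + 1L]] <- list(start = i, end = j, sign = s)
    }
    i <- j + 1L
  }
  out
}

#' Generate synthetic weekly climate and a monthly ONI-like index
#'
#' Each climate variable is a seasonal sinusoid plus the shared narrowband
#' ENSO mode (scaled and signed per variable: dry-season-like variables peak
#' together, relative humidity and streamflow are inverted) plus AR(1) noise.
#' Soil moisture carries higher lag-1 autocorrelation and lower noise than
#' radiation, mirroring the buffered soil-water spectrum of real records. The
#' ONI series is the shared mode sampled monthly plus small observation noise.
#'
#' @param cfg a [synth_config()].
#' @return list with `climate` (wide weekly tibble: `date`, `radiation`,
#'   `temperature`, `rh`, `swc`, `streamflow`), `oni` (monthly tibble `date`,
#'   `oni`), `ground_truth` (injected parameters, noise-free components, true
#'   phase angles per band, ENSO event windows).
#' @export
synth_climate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- round(cfg$n_years * WEEKS_PER_YEAR)
  t <- seq_len(n) - 1
  dates <- cfg$start_date + 7 * t
  mp <- enso_mode_params(cfg)
  seas <- seasonal_component(t)
  enso <- enso_component(t, mp)

  sgn <- c(radiation = 1, temperature = 1, rh = -1, deficit = 1, streamflow = -1)
  base <- c(radiation = 180, temperature = 26, rh = 85, deficit = 0, streamflow = 60)
  unit <- c(radiation = 25, temperature = 1.5, rh = 6, deficit = 1, streamflow = 15)

  set.seed(cfg$rng_seed + 101L)
  mk_noise <- function(v) {
    if (cfg$noise_sd[[v]] == 0) return(numeric(n))
    as.vector(ar1_surrogates(n, 1L, cfg$noise_ar1[[v]], cfg$noise_sd[[v]]))
  }
  latent <- function(v) {
    sgn[[v]] * (cfg$seasonal_amplitudes[[v]] * seas + cfg$enso_amplitudes[[v]] * enso) +
      mk_noise(v)
  }
  deficit_latent <- latent("deficit")
  climate <- tibble(
    date = dates,
    radiation = base[["radiation"]] + unit[["radiation"]] * latent("radiation"),
    temperature = base[["temperature"]] + unit[["temperature"]] * latent("temperature"),
    rh = pmin(100, pmax(20, base[["rh"]] + unit[["rh"]] * latent("rh"))),
    swc = 0.45 - 0.10 * deficit_latent, # deficit is an affine decreasing map of swc
    streamflow = pmax(0, base[["streamflow"]] + unit[["streamflow"]] * latent("streamflow"))
  )

  month_starts <- seq(lubridate::floor_date(dates[1], "month"),
                      lubridate::floor_date(dates[n], "month"), by = "month")
  tm <- as.numeric(month_starts - dates[1]) / 7
  oni_true <- enso_component(tm, mp) / sd(enso_component(t, mp)) * 0.7
  oni <- oni_true + rnorm(length(tm), 0, 0.05)

  runs <- enumerate_runs(oni_true, 0.5, 5L)
  events <- tibble(
    start = as.Date(vapply(runs, function(r) as.character(month_starts[r$start]), "")),
    end = as.Date(vapply(runs, function(r) as.character(month_starts[r$end]), "")),
    sign = vapply(runs, function(r) if (r$sign > 0) "warm" else "cold", "")
  )

  py <- WEEKS_PER_YEAR
  pe <- cfg$enso_period_years * WEEKS_PER_YEAR
  ground_truth <- list(
    mode_params = mp,
    seasonal_component = seas,
    enso_component = enso,
    deficit_latent = deficit_latent,
    oni_true = tibble(date = month_starts, oni = oni_true),
    enso_events = events,
    # positive angle = phenology lags deficit (package-wide convention)
    true_angle_seasonal = c(leaf = -360 * cfg$leaf_lead_weeks[["seasonal"]] / py,
                            seed = 360 * cfg$seed_lag_weeks[["seasonal"]] / py),
    true_angle_enso = c(leaf = -360 * cfg$leaf_lead_weeks[["enso"]] / pe,
                        seed = 360 * cfg$seed_lag_weeks[["enso"]] / pe),
    true_lag_weeks_seasonal = c(leaf = -cfg$leaf_lead_weeks[["seasonal"]],
                                seed = cfg$seed_lag_weeks[["seasonal"]]),
    true_lag_weeks_enso = c(leaf = -cfg$leaf_lead_weeks[["enso"]],
                            seed = cfg$seed_lag_weeks[["enso"]])
  )
  list(climate = climate, oni = tibble(date = month_starts, oni = oni),
       ground_truth = ground_truth, config = cfg)
}

#' Generate synthetic seed-trap and leaf-litter censuses
#'
#' Community latent signals are the soil-water-deficit signal with each
#' frequency band shifted by its injected lead or lag: the seasonal component
#' is advanced by `leaf_lead_weeks["seasonal"]` (delayed by
#' `seed_lag_weeks["seasonal"]`) and the ENSO component by the corresponding
#' `enso` entries - an exact band-specific fractional delay, realisable here
#' because both components are sums of sinusoids. Species series are the
#' latent signal times a species loading plus AR(1) species noise; seed counts
#' are Poisson around the exponentiated (or identity-linked) latent, leaf dry
#' mass is Gamma around a softplus-transformed latent (strictly positive). A
#' configurable fraction of species is generated with too few nonzero censuses
#' to pass the community inclusion thresholds, and one seed species is flagged
#' on the exclusion list.
#'
#' @param climate output of [synth_climate()] (same config).
#' @param cfg the same [synth_config()].
#' @return list with `seed_traps` (long tibble: `species`, `date`,
#'   `mature_seeds`, `mature_fruits`, `immature`, `damaged`), `leaf_traps`
#'   (`species`, `date`, `dry_mass`), `species_meta` (`species`, `group`,
#'   `dispersal_mode`, `leaf_habit`, `seeds_per_fruit`, `exclude`), and
#'   `ground_truth` (community latents and injected lags).
#' @export
synth_phenology <- function(climate, cfg = climate$config) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- nrow(climate$climate)
  if (n != round(cfg$n_years * WEEKS_PER_YEAR)) {
    abort("dimension error: climate time axis does not match the configuration")
  }
  t <- seq_len(n) - 1
  mp <- climate$ground_truth$mode_params
  a_s <- cfg$seasonal_amplitudes[["deficit"]]
  a_e <- cfg$enso_amplitudes[["deficit"]]

  latent_for <- function(shift_seasonal, shift_enso) {
    z <- a_s * seasonal_component(t, shift = shift_seasonal) +
      a_e * enso_component(t, mp, shift = shift_enso)
    (z - mean(z)) / sd(z)
  }
  leaf_latent <- latent_for(cfg$leaf_lead_weeks[["seasonal"]], cfg$leaf_lead_weeks[["enso"]])
  seed_latent <- latent_for(-cfg$seed_lag_weeks[["seasonal"]], -cfg$seed_lag_weeks[["enso"]])

  set.seed(cfg$rng_seed + 202L)
  species_table <- function(prefix, n_sp, latent, type) {
    if (n_sp == 0L) return(list(table = tibble(), meta = tibble()))
    ids <- sprintf("%s_%03d", prefix, seq_len(n_sp))
    n_rare <- floor(cfg$rare_fraction * n_sp)
    rare <- seq_len(n_sp) %in% sample.int(n_sp, n_rare)
    loading <- runif(n_sp, 0.4, 0.8)
    noise_sd <- cfg$noise_sd[["species"]]
    rows <- purrr::map(seq_len(n_sp), function(i) {
      eps <- if (noise_sd > 0) {
        as.vector(ar1_surrogates(n, 1L, cfg$noise_ar1[["species"]], noise_sd))
      } else numeric(n)
      z <- loading[i] * latent + eps
      if (type == "seed") {
        lam <- if (cfg$seed_link == "log") exp(log(8) + z) else pmax(0, z)
        if (rare[i]) {
          wk <- sample.int(n, sample(1:8, 1))
          cnt <- integer(n); cnt[wk] <- 1L
          seeds <- cnt; fruits <- integer(n)
        } else if (cfg$sampling == "poisson") {
          total <- rpois(n, lam)
          fruits <- rbinom(n, total, 0.3)
          seeds <- total - fruits
        } else {
          seeds <- lam; fruits <- numeric(n)
        }
        imm <- if (cfg$sampling == "poisson") rpois(n, 0.2) else numeric(n)
        tibble(species = ids[i], date = climate$climate$date,
               mature_seeds = seeds, mature_fruits = fruits,
               immature = imm, damaged = if (cfg$sampling == "poisson") rpois(n, 0.1) else numeric(n))
      } else {
        mu <- log1p(exp(1.2 * z + 0.5)) # softplus keeps the mean positive
        if (rare[i]) {
          wk <- sample.int(n, sample(1:3, 1))
          mass <- numeric(n); mass[wk] <- runif(length(wk), 0.1, 1)
        } else if (cfg$sampling == "poisson") {
          shape <- 4
          mass <- rgamma(n, shape = shape, scale = mu / shape)
        } else {
          mass <- mu
        }
        tibble(species = ids[i], date = climate$climate$date, dry_mass = mass)
      }
    })
    meta <- tibble(
      species = ids, group = type,
      dispersal_mode = sample(c("abiotic", "biotic"), n_sp, TRUE, prob = c(0.3, 0.7)),
      leaf_habit = sample(c("evergreen", "deciduous"), n_sp, TRUE, prob = c(0.8, 0.2)),
      seeds_per_fruit = if (type == "seed") pmax(1, round(exp(runif(n_sp, 0, 3.5)))) else NA_real_,
      exclude = FALSE
    )
    list(table = bind_rows(rows), meta = meta)
  }

  seed <- species_table("seed_sp", cfg$n_species_seed, seed_latent, "seed")
  leaf <- species_table("leaf_sp", cfg$n_species_leaf, leaf_latent, "leaf")
  if (nrow(seed$meta) > 0) seed$meta$exclude[1] <- TRUE # the named exclusion-list species
  seed$table <- left_join(seed$table,
                          select(seed$meta, "species", "seeds_per_fruit"),
                          by = "species")

  gt <- climate$ground_truth
  gt$leaf_latent <- leaf_latent
  gt$seed_latent <- seed_latent
  list(seed_traps = seed$table, leaf_traps = leaf$table,
       species_meta = bind_rows(seed$meta, leaf$meta),
       ground_truth = gt, config = cfg)
}

#' A smooth "true" LAI trajectory for forward simulation
#'
#' Mean canopy LAI with a seasonal dip (leaf fall at the wet-to-dry
#' transition) and a smaller ENSO-band modulation, built from the noise-free
#' climate components so its phases are known.
#'
#' @param climate output of [synth_climate()].
#' @param mean_lai,seasonal_amp,enso_amp trajectory parameters.
#' @return [weekly_series()] tibble of true LAI (dimensionless, >= 0).
#' @export
synth_lai_trajectory <- function(climate, mean_lai = 5.5, seasonal_amp = 0.75,
                                 enso_amp = 0.3) {
  gt <- climate$ground_truth
  lai <- mean_lai - seasonal_amp * gt$seasonal_component - enso_amp * gt$enso_component
  weekly_series(climate$climate$date, pmax(0, lai), name = "true_lai")
}

#' Forward-simulate gap fractions from a true LAI trajectory
#'
#' Inverse of the LAI estimator: at the zenith (`theta = 0`),
#' `P = exp(-LAI * omega * g / cos(theta))`, jittered per location on the log
#' scale with standard deviation `noise_sd` and capped at 1. At
#' `noise_sd = 0` the inversion in [lai_from_gap_fraction()] recovers the
#' trajectory to machine precision.
#'
#' @param true_lai data frame with `date` and `value` (LAI >= 0), typically
#'   monthly-subsampled from [synth_lai_trajectory()].
#' @param n_locations number of photo locations per date (default 188).
#' @param params [lai_params()].
#' @param noise_sd log-scale jitter SD.
#' @param rng_seed integer seed.
#' @return tibble: `location`, `date`, `theta_deg`, `gap_fraction`.
#' @export
synth_gap_fractions <- function(true_lai, n_locations = 188,
                                params = lai_params(), noise_sd = 0.1,
                                rng_seed = 1L) {
  if (any(true_lai$value < 0, na.rm = TRUE)) abort("true LAI must be >= 0")
  set.seed(rng_seed + 303L)
  grid <- tidyr::expand_grid(
    location = sprintf("loc_%03d", seq_len(n_locations)),
    date = true_lai$date
  ) |>
    left_join(select(true_lai, "date", "value"), by = "date")
  logp <- -grid$value * params$omega * params$g +
    (if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0)
  tibble(location = grid$location, date = grid$date, theta_deg = 0,
         gap_fraction = pmin(1, exp(logp)))
}

#' Generate species median leaf life spans
#'
#' Right-skewed (log-normal) positive life spans whose mode falls in the
#' configured interval (default 6-12 months) for canopy species, with longer
#' understory life spans, across two sites.
#'
#' @param n_species species count.
#' @param mode_months interval (months) containing the canopy mode.
#' @param rng_seed integer seed.
#' @return tibble: `species`, `site`, `stratum`, `lifespan_months`.
#' @export
synth_lifespans <- function(n_species = 120, mode_months = c(6, 12),
                            rng_seed = 1L) {
  if (any(mode_months <= 0) || mode_months[1] >= mode_months[2]) {
    abort("`mode_months` must be a positive increasing interval")
  }
  if (n_species == 0L) {
    return(tibble(species = character(), site = character(),
                  stratum = character(), lifespan_months = numeric()))
  }
  set.seed(rng_seed + 404L)
  sdlog <- 0.45
  mode_mid <- mean(mode_months)
  mu <- log(mode_mid) + sdlog^2 # log-normal mode = exp(mu - sd^2)
  stratum <- sample(c("canopy", "understory"), n_species, TRUE, prob = c(0.7, 0.3))
  shiftm <- ifelse(stratum == "understory", log(2.5), 0)
  tibble(
    species = sprintf("ls_sp_%03d", seq_len(n_species)),
    site = sample(c("wet_site", "dry_site"), n_species, TRUE),
    stratum = stratum,
    lifespan_months = stats::rlnorm(n_species, mu + shiftm, sdlog)
  )
}

#' Write a complete synthetic fixture directory
#'
#' Emits the CSV dialects the preparation functions read (long trap CSVs, wide
#' weekly climate CSV, monthly ONI CSV, gap-fraction CSV, life-span CSV,
#' species metadata) plus `ground_truth.json` with the injected parameters.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [synth_config()].
#' @return invisibly, the list of written paths.
#' @export
write_synth_fixtures <- function(dir, cfg = synth_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl <- synth_climate(cfg)
  ph <- synth_phenology(cl, cfg)
  lai_true <- synth_lai_trajectory(cl)
  monthly <- lai_true[!duplicated(lubridate::floor_date(lai_true$date, "month")), ]
  gf <- synth_gap_fractions(monthly, rng_seed = cfg$rng_seed)
  ls <- synth_lifespans(rng_seed = cfg$rng_seed)
  p <- function(f) file.path(dir, f)
  readr::write_csv(cl$climate, p("climate.csv"))
  readr::write_csv(cl$oni, p("oni.csv"))
  readr::write_csv(ph$seed_traps, p("seed_traps.csv"))
  readr::write_csv(ph$leaf_traps, p("leaf_traps.csv"))
  readr::write_csv(ph$species_meta, p("species_meta.csv"))
  readr::write_csv(gf, p("gap_fractions.csv"))
  readr::write_csv(ls, p("lifespans.csv"))
  gt <- ph$ground_truth
  jsonlite::write_json(
    list(
      rng_seed = cfg$rng_seed,
      leaf_lead_weeks = as.list(cfg$leaf_lead_weeks),
      seed_lag_weeks = as.list(cfg$seed_lag_weeks),
      enso_period_years = cfg$enso_period_years,
      true_angle_seasonal = as.list(gt$true_angle_seasonal),
      true_angle_enso = as.list(gt$true_angle_enso),
      enso_events = gt$enso_events
    ),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list.files(dir, full.names = TRUE))
}
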