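test_that("synth config validation names the offending field", {
  expect_error(synth_config(n_years = 5), "n_years")
  expect_error(synth_config(noise_ar1 = c(radiation = 1.2, temperature = 0.5,
                                          rh = 0.4, deficit = 0.8,
                                          streamflow = 0.7, species = 0.3)),
               "noise_ar1")
  expect_error(synth_config(enso_period_years = 9), "enso_period_years")
  expect_error(synth_config(seasonal_amplitudes = c(radiation = -1, temperature = 1,
                                                    rh = 1, deficit = 1, streamflow = 1)),
               "seasonal_amplitudes")
})

test_that("same seed gives identical fixtures, different seeds differ", {
  cfg <- small_synth()
  a <- synth_climate(cfg); b <- synth_climate(cfg)
  expect_identical(a$climate, b$climate)
  expect_identical(a$oni, b$oni)
  pa <- synth_phenology(a, cfg); pb <- synth_phenology(b, cfg)
  expect_identical(pa$seed_traps, pb$seed_traps)
  expect_identical(pa$leaf_traps, pb$leaf_traps)
  c2 <- synth_climate(small_synth(rng_seed = 8))
  expect_false(identical(a$climate$radiation, c2$climate$radiation))
})

test_that("noise-free config is a deterministic sinusoid mixture with true ONI events", {
  cfg <- small_synth(noise_sd = c(radiation = 0, temperature = 0, rh = 0,
                                  deficit = 0, streamflow = 0, species = 0))
  cl <- synth_climate(cfg)
  # exactly reproducible and smooth: second differences of the deterministic
  # seasonal+ENSO mixture are tiny relative to the signal
  expect_lt(sd(diff(cl$climate$radiation, differences = 2)), 0.02 * sd(cl$climate$radiation))
  # the noise-free monthly ONI crosses 0.5 only inside ground-truth warm windows
  gt <- cl$ground_truth
  warm_months <- gt$oni_true$oni > 0.5
  inside_warm <- rep(FALSE, nrow(gt$oni_true))
  ev <- gt$enso_events[gt$enso_events$sign == "warm", ]
  for (k in seq_len(nrow(ev))) {
    inside_warm <- inside_warm |
      (gt$oni_true$date >= ev$start[k] & gt$oni_true$date <= ev$end[k])
  }
  # every warm-event month qualifies; crossings outside events are only the
  # short (<5 month) runs that fail the duration rule
  expect_true(all(gt$oni_true$oni[inside_warm] > 0.5))
  stray <- which(warm_months & !inside_warm)
  if (length(stray) > 0) {
    runs <- rle(warm_months)
    qualifying <- rep(runs$lengths >= 5 & runs$values, runs$lengths)
    expect_true(all(!qualifying[stray]))
  }
})

test_that("with no seasonal/ENSO signal the series is AR(1) noise (recursion oracle)", {
  cfg <- synth_config(
    n_years = 30,
    seasonal_amplitudes = c(radiation = 0, temperature = 0, rh = 0,
                            deficit = 0, streamflow = 0),
    enso_amplitudes = c(radiation = 0, temperature = 0, rh = 0,
                        deficit = 0, streamflow = 0),
    rng_seed = 3
  )
  cl <- synth_climate(cfg)
  r <- cl$climate$radiation
  r1_hat <- cor(r[-1], r[-length(r)])
  expect_lt(abs(r1_hat - cfg$noise_ar1[["radiation"]]), 0.05)
  # oracle: an AR(1) recursion with the same parameters has matching moments
  set.seed(99)
  o <- as.vector(phenowave:::ar1_surrogates(length(r), 1, cfg$noise_ar1[["radiation"]],
                                            cfg$noise_sd[["radiation"]]))
  expect_lt(abs(sd(r) - sd(o) * 25) / (sd(o) * 25), 0.15) # radiation unit = 25
})

test_that("the ENSO mode is narrowband: >99% of variance in the 2-7 yr band", {
  cl <- synth_climate(synth_config())
  e <- cl$ground_truth$enso_component
  n <- length(e)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)) # Hann taper controls leakage
  pg <- Mod(fft((e - mean(e)) * w))^2
  pg <- pg[2:(n %/% 2)]
  period_weeks <- n / (1:(n %/% 2 - 1))
  inband <- period_weeks >= 2 * 365.25 / 7 & period_weeks <= 7 * 365.25 / 7
  expect_gt(sum(pg[inband]) / sum(pg), 0.99)
})

test_that("injected seasonal lead shows up in the community latent cross-correlation", {
  cfg <- small_synth(
    noise_sd = c(radiation = 0, temperature = 0, rh = 0, deficit = 0,
                 streamflow = 0, species = 0),
    leaf_lead_weeks = c(seasonal = 6, enso = 6),
    rare_fraction = 0
  )
  cl <- synth_climate(cfg)
  ph <- synth_phenology(cl, cfg)
  deficit <- -cl$climate$swc # increasing in deficit
  # direct cross-correlation oracle: leaf latent peaks 6 weeks before deficit
  cc <- ccf(ph$ground_truth$leaf_latent, deficit, lag.max = 15, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], -6)
})

test_that("single-species identity link with no sampling reproduces the latent", {
  cfg <- small_synth(n_species_seed = 1, n_species_leaf = 1,
                     seed_link = "identity", sampling = "none",
                     rare_fraction = 0,
                     noise_sd = c(radiation = 0, temperature = 0, rh = 0,
                                  deficit = 0, streamflow = 0, species = 0))
  cl <- synth_climate(cfg)
  ph <- synth_phenology(cl, cfg)
  lat <- ph$ground_truth$seed_latent
  v <- ph$seed_traps$mature_seeds
  # the trap series is the (loading-scaled, floored) latent: perfectly
  # correlated wherever the latent is positive
  pos <- lat > 0
  expect_gt(sum(pos), 100)
  expect_equal(cor(v[pos], lat[pos]), 1, tolerance = 1e-10)
  expect_true(all(v[!pos] == 0))
})

test_that("seed counts are non-negative integers and some species are rare", {
  cfg <- small_synth()
  ph <- synth_phenology(synth_climate(cfg), cfg)
  expect_true(all(ph$seed_traps$mature_seeds >= 0))
  expect_true(all(ph$seed_traps$mature_fruits >= 0))
  expect_true(all(ph$seed_traps$mature_seeds == round(ph$seed_traps$mature_seeds)))
  nz <- ph$seed_traps |>
    dplyr::group_by(species) |>
    dplyr::summarise(n = sum(mature_seeds + mature_fruits > 0))
  expect_equal(sum(nz$n <= 9), floor(0.15 * cfg$n_species_seed))
  expect_equal(sum(ph$species_meta$exclude), 1)
})

test_that("phenology requires matching time axes", {
  cfg <- small_synth()
  cl <- synth_climate(cfg)
  cl$climate <- cl$climate[1:100, ]
  expect_error(synth_phenology(cl, small_synth(n_years = 20)), ".")
})

test_that("gap-fraction forward model matches the closed form and round-trips", {
  lt <- weekly_series(monday, c(0, 1, 2.5, 6))
  gf <- synth_gap_fractions(lt, n_locations = 3, noise_sd = 0)
  # LAI = 0 -> P = 1 exactly
  expect_equal(gf$gap_fraction[gf$date == monday], rep(1, 3))
  # closed form: LAI = 0.45/(0.9*0.5) = 1 -> P = exp(-0.45)
  lt2 <- weekly_series(monday, 0.45 / (0.9 * 0.5))
  gf2 <- synth_gap_fractions(lt2, n_locations = 1, noise_sd = 0)
  expect_equal(gf2$gap_fraction, exp(-0.45), tolerance = 1e-12)
  expect_equal(gf2$gap_fraction, 0.6376, tolerance = 1e-4)
  # round trip at zero noise recovers LAI to machine precision
  est <- lai_from_gap_fraction(gf)
  truth <- lt$value[match(est$date, lt$date)]
  expect_equal(est$lai, truth, tolerance = 1e-12)
  expect_error(synth_gap_fractions(weekly_series(monday, -1), 2), ">= 0")
})

test_that("life spans are reproducible, positive and modal where configured", {
  expect_equal(nrow(synth_lifespans(0)), 0)
  a <- synth_lifespans(500, rng_seed = 5)
  b <- synth_lifespans(500, rng_seed = 5)
  expect_identical(a, b)
  expect_true(all(a$lifespan_months > 0))
  canopy <- a$lifespan_months[a$stratum == "canopy"]
  h <- hist(canopy, breaks = seq(0, 6 * ceiling(max(canopy) / 6), by = 6), plot = FALSE)
  modal_bin <- which.max(h$counts)
  expect_equal(modal_bin, 2) # the (6, 12] bin
})
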