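test_that("seed equivalents follow mature seeds + fruits * seeds_per_fruit", {
  x <- tibble::tibble(
    species = c("a", "a", "b"),
    date = monday + c(0, 7, 0),
    mature_seeds = c(3, 0, 0),
    mature_fruits = c(2, 0, 0),
    immature = c(9, 4, 7),
    damaged = c(1, 0, 2),
    seeds_per_fruit = c(5, 5, 2)
  )
  se <- seed_equivalents(x)
  expect_equal(se$seeds[se$species == "a" & se$date == monday], 13)
  expect_equal(se$seeds[se$species == "a" & se$date == monday + 7], 0)
  # weeks with only immature/damaged records contribute zero
  expect_equal(se$seeds[se$species == "b"], 0)
})

test_that("seed equivalents are additive over traps within a species-week", {
  one <- tibble::tibble(species = "a", date = monday, mature_seeds = 7,
                        mature_fruits = 3, seeds_per_fruit = 4)
  split3 <- tibble::tibble(species = "a", date = monday,
                           mature_seeds = c(3, 4, 0), mature_fruits = c(1, 0, 2),
                           seeds_per_fruit = 4)
  expect_equal(seed_equivalents(one)$seeds, seed_equivalents(split3)$seeds)
})

test_that("missing seeds_per_fruit with nonzero fruits names the species", {
  x <- tibble::tibble(species = "puzzlewood", date = monday,
                      mature_seeds = 0, mature_fruits = 2,
                      seeds_per_fruit = NA_real_)
  expect_error(seed_equivalents(x), "puzzlewood")
})

test_that("species filtering uses a strict census threshold and exclusions", {
  mk <- function(sp, k) tibble::tibble(species = sp, date = monday + 7 * seq_len(k),
                                       seeds = 1)
  d <- dplyr::bind_rows(mk("ten", 10), mk("eleven", 11), mk("many", 500))
  suppressMessages({
    out <- filter_species(d, min_censuses = 10, record_cols = "seeds")
    expect_setequal(unique(out$species), c("eleven", "many"))
    out2 <- filter_species(d, min_censuses = 10, exclude = "many",
                           record_cols = "seeds")
    expect_setequal(unique(out2$species), "eleven")
    # zero-count weeks are not censuses with a record
    d3 <- dplyr::bind_rows(mk("zeros", 11), mk("ok", 11))
    d3$seeds[d3$species == "zeros"][1:5] <- 0
    out3 <- filter_species(d3, min_censuses = 10, record_cols = "seeds")
    expect_setequal(unique(out3$species), "ok")
  })
})

test_that("community series z-scores then averages, with affine invariance", {
  n <- 30
  set.seed(1)
  base <- rnorm(n)
  d <- dplyr::bind_rows(
    wk_tbl(species = "a", x = base, n = n),
    wk_tbl(species = "b", x = base * 10, n = n) # pure rescaling
  )
  cs <- community_series(d, value = "x")
  one <- community_series(dplyr::filter(d, species == "a"), value = "x")
  expect_equal(cs$value, one$value)
  expect_equal(mean(cs$value), 0, tolerance = 1e-12)
  expect_equal(sd(one$value), 1, tolerance = 1e-12)
  # species A = -species B cancels out
  d2 <- dplyr::bind_rows(
    wk_tbl(species = "a", x = base - mean(base), n = n),
    wk_tbl(species = "b", x = -(base - mean(base)), n = n)
  )
  cs2 <- community_series(d2, value = "x")
  expect_equal(cs2$value, rep(0, n), tolerance = 1e-12)
  # per-species affine rescaling leaves the community series unchanged
  d3 <- d
  d3$x[d3$species == "b"] <- 3 * d3$x[d3$species == "b"] + 42
  expect_equal(community_series(d3, value = "x")$value, cs$value)
  expect_error(
    community_series(wk_tbl(species = "a", x = rep(2, n), n = n), value = "x"),
    "constant"
  )
})

test_that("soil water deficit maps extremes to 0/1 and is monotone in swc", {
  s <- tibble::tibble(date = monday + c(0, 10, 21, 35), swc = c(0.5, 0.3, 0.4, 0.1))
  d <- soil_water_deficit(s)
  expect_true(all(d$value >= 0 & d$value <= 1))
  expect_equal(min(d$value), 0)
  expect_equal(max(d$value), 1)
  # endpoints and midpoint via explicit extremes
  s2 <- tibble::tibble(date = monday + 7 * (0:2), swc = c(0.6, 0.4, 0.2))
  d2 <- soil_water_deficit(s2, swc_max = 0.6, swc_min = 0.2)
  expect_equal(d2$value, c(0, 0.5, 1))
  # monotone decreasing in swc
  ord <- order(approx(as.numeric(s$date), s$swc, xout = as.numeric(d$date), rule = 2)$y)
  expect_true(all(diff(d$value[ord]) <= 1e-12))
  expect_error(soil_water_deficit(s2, swc_max = 0.4, swc_min = 0.4), "degenerate")
})

test_that("midday VPD keeps the 10-17h window and matches the Magnus formula", {
  ts <- as.POSIXct("2000-01-03 00:00", tz = "UTC") + 3600 * (0:167) # one week, hourly
  d <- tibble::tibble(timestamp = ts, temperature = 25, rh = 50)
  v <- midday_vpd(d)
  # independent evaluation of the documented formula at T = 25, RH = 50
  expect_equal(v$value[1], 0.61094 * exp(17.625 * 25 / (25 + 243.04)) * 0.5,
               tolerance = 1e-12)
  expect_equal(v$value[1], 1.580868, tolerance = 1e-4)
  # saturated air has zero VPD at any temperature
  d$rh <- 100
  expect_equal(midday_vpd(d)$value[1], 0)
  # records only outside the window leave the week flagged missing
  d2 <- d[lubridate::hour(d$timestamp) < 9, ]
  expect_true(is.na(midday_vpd(d2)$value[1]))
  d$rh[1] <- 140
  expect_error(midday_vpd(d), "humidity")
})

test_that("seasonal detrend removes the annual climatology", {
  n <- 52 * 6
  t <- seq_len(n)
  d <- wk_tbl(value = sin(2 * pi * t / 52) + 5, n = n)
  # 52-week-periodic input leaves only calendar-irregularity residue
  raw <- seasonal_detrend(d, scale = FALSE)
  expect_lt(sd(raw$value) / sd(d$value), 0.2)
  out <- seasonal_detrend(d)
  # adding a constant changes nothing
  d2 <- d; d2$value <- d2$value + 100
  expect_equal(seasonal_detrend(d2)$value, out$value)
  expect_error(seasonal_detrend(wk_tbl(value = rnorm(30), n = 30)), "2 full years")
  # white noise passes through (climatology ~ 0), up to rescaling: compare
  # against a brute-force week-of-year grouping oracle
  set.seed(3)
  dn <- wk_tbl(value = rnorm(n), n = n)
  woy <- pmin(lubridate::yday(dn$date) %/% 7L + 1L, 53L)
  clim <- tapply(dn$value, woy, mean)
  oracle <- dn$value - clim[as.character(woy)]
  oracle <- (oracle - mean(oracle)) / sd(oracle)
  expect_equal(seasonal_detrend(dn)$value, as.numeric(oracle), tolerance = 1e-12)
})

test_that("running mean is a centered boxcar with missing ends", {
  expect_equal(running_mean(rep(4, 30), 13),
               c(rep(NA_real_, 6), rep(4, 18), rep(NA_real_, 6)))
  x <- rnorm(10)
  expect_equal(running_mean(x, 1), x)
  imp <- rep(0, 41); imp[21] <- 13
  rm13 <- running_mean(imp, 13)
  expect_equal(rm13[15:27], rep(1, 13))
  expect_error(running_mean(1:5, 0), "window")
  expect_error(running_mean(1:5, 9), "longer")
})

test_that("ENSO event detection honours strict thresholds and minimum runs", {
  mk <- function(x) tibble::tibble(date = seq(as.Date("2000-01-01"),
                                              by = "month", length.out = length(x)),
                                   oni = x)
  ev <- identify_enso_events(mk(c(0, 0, rep(0.6, 5), 0, 0)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$months, 5)
  expect_equal(ev$sign, "warm")
  expect_equal(nrow(identify_enso_events(mk(c(0, rep(0.6, 4), 0)))), 0)
  # exactly 0.5 for a year: strict inequality, no event
  expect_equal(nrow(identify_enso_events(mk(rep(0.5, 12)))), 0)
  ev2 <- identify_enso_events(mk(c(rep(-0.7, 6), 0, rep(0.8, 7))))
  expect_equal(ev2$sign, c("cold", "warm"))
})

test_that("detected ENSO events match brute-force enumeration on random series", {
  set.seed(11)
  for (rep in 1:5) {
    x <- round(as.vector(arima.sim(list(ar = 0.8), 240, sd = 0.4)), 2)
    d <- tibble::tibble(date = seq(as.Date("1990-01-01"), by = "month",
                                   length.out = 240), oni = x)
    got <- identify_enso_events(d)
    want <- brute_events(x)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$start[k], d$date[want[[k]]["start"]])
      expect_equal(got$end[k], d$date[want[[k]]["end"]])
      expect_equal(got$sign[k], if (want[[k]]["sign"] > 0) "warm" else "cold")
      # every month of the event satisfies its defining predicate
      seg <- x[want[[k]]["start"]:want[[k]]["end"]]
      if (got$sign[k] == "warm") expect_true(all(seg > 0.5))
      else expect_true(all(seg < -0.5))
    }
    # same-sign events separated by at least one non-qualifying month
    for (sgn in c("warm", "cold")) {
      same <- got[got$sign == sgn, ]
      if (nrow(same) > 1) {
        expect_true(all(diff(as.numeric(lubridate::interval(same$start, same$end) |>
                                          lubridate::int_start())) > 0))
        gaps <- as.numeric(difftime(same$start[-1], same$end[-nrow(same)], units = "days"))
        expect_true(all(gaps > 31))
      }
    }
  }
})

test_that("normalize_01 maps extremes to 0/1 and is affine invariant", {
  x <- c(3, 7)
  expect_equal(normalize_01(x), c(0, 1))
  y <- rnorm(50)
  expect_equal(normalize_01(2.5 * y - 4), normalize_01(y))
  expect_equal(range(normalize_01(y)), c(0, 1))
  expect_error(normalize_01(rep(1, 5)), "degenerate")
})

test_that("weekly series validation and imputation behave", {
  expect_error(weekly_series(monday + c(0, 7, 15), 1:3), "weekly")
  ws <- weekly_series(monday, c(1, NA, 3, NA, 5))
  imp <- impute_missing(ws)
  expect_equal(imp$value, c(1, 2, 3, 4, 5))
  expect_equal(imp$imputed, c(FALSE, TRUE, FALSE, TRUE, FALSE))
})
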