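# Shared fixture builders; everything is generated in code at test time.

monday <- as.Date("2000-01-03")

wk_tbl <- function(..., n = NULL) {
  cols <- list(...)
  if (is.null(n)) n <- length(cols[[1]])
  tibble::tibble(date = monday + 7 * (seq_len(n) - 1L), !!!cols)
}

# Two noisy sinusoids, the first delayed relative to the second.
delayed_pair <- function(n = 1560, period = 52, delay = 13, snr = 5, seed = 42) {
  set.seed(seed)
  noise_sd <- sqrt(0.5 / snr) # unit-amplitude cosine has variance 1/2
  t <- seq_len(n)
  wk_tbl(
    lagged = cos(2 * pi * (t - delay) / period) + rnorm(n, 0, noise_sd),
    ref = cos(2 * pi * t / period) + rnorm(n, 0, noise_sd)
  )
}

# A small synthetic configuration for fast end-to-end tests.
small_synth <- function(...) {
  args <- utils::modifyList(
    list(n_years = 12, n_species_seed = 12, n_species_leaf = 12, rng_seed = 7),
    list(...)
  )
  do.call(synth_config, args)
}

# Brute-force oracle for the smoothing operator: direct kernel sums in time
# (truncated renormalized Gaussian, sd = scale), then a renormalized boxcar
# across scales. Written independently of the package internals.
brute_smooth <- function(M, scales, dt = 1, dj = 1 / 12) {
  n <- nrow(M); J <- ncol(M)
  out <- M
  for (j in seq_len(J)) {
    s <- scales[j]
    h <- min(ceiling(3 * s / dt), n - 1)
    for (t0 in seq_len(n)) {
      u <- max(1, t0 - h):min(n, t0 + h)
      k <- exp(-((u - t0)^2) / (2 * (s / dt)^2))
      out[t0, j] <- sum(k * M[u, j]) / sum(k)
    }
  }
  hw <- max(0, floor(0.3 / dj))
  if (hw == 0 || J == 1) return(out)
  out2 <- out
  for (j in seq_len(J)) {
    win <- max(1, j - hw):min(J, j + hw)
    out2[, j] <- rowMeans(out[, win, drop = FALSE])
  }
  out2
}

# Brute-force ENSO event enumeration, independent of the implementation.
brute_events <- function(oni, threshold = 0.5, min_months = 5) {
  state <- ifelse(oni > threshold, 1L, ifelse(oni < -threshold, -1L, 0L))
  ev <- list()
  i <- 1L
  while (i <= length(state)) {
    if (state[i] != 0L) {
      j <- i
      while (j < length(state) && state[j + 1] == state[i]) j <- j + 1L
      if (j - i + 1L >= min_months) {
        ev[[length(ev) + 1L]] <- c(start = i, end = j, sign = state[i])
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  ev
}
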