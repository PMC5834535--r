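# Monte-Carlo significance testing of wavelet coherence against an AR(1)
# (red-noise) null.
#
# Null construction: lag-1 autocorrelation and variance are estimated from
# each observed series; pairs of independent AR(1) surrogates with those
# parameters are generated and their coherence computed with the identical
# transform and smoothing operator. Because the null is time-stationary, the
# per-scale null distribution is pooled over in-COI time cells; to keep the
# cost manageable the surrogate fields are evaluated only at a per-scale
# decimated set of in-COI time points (the same operator at fewer points draws
# from the same distribution). The observed field is always smoothed in full.

ar1_fit <- function(x) {
  n <- length(x)
  if (sd(x) == 0) abort("degenerate AR(1) fit: constant series")
  r1 <- stats::cor(x[-1], x[-n])
  if (!is.finite(r1) || abs(r1) >= 1) {
    abort("degenerate AR(1) fit: |lag-1 autocorrelation| >= 1 or undefined")
  }
  list(r1 = r1, sd = sd(x))
}

# n x B matrix of stationary AR(1) draws.
ar1_surrogates <- function(n, B, r1, sd = 1) {
  X <- matrix(0, n, B)
  X[1, ] <- rnorm(B, 0, sd)
  innov_sd <- sd * sqrt(1 - r1^2)
  for (t in 2:n) X[t, ] <- r1 * X[t - 1, ] + rnorm(B, 0, innov_sd)
  X
}

# Time points used to pool the null distribution at scale index j: inside the
# COI at that scale, decimated. The decimation step only sets how many (valid)
# draws from the stationary null are pooled per surrogate, not the operator;
# about three scales apart, at most ~24 points per scale.
null_pool_points <- function(n, dt, scale, period, coi) {
  inside <- which(coi >= period)
  if (length(inside) == 0L) return(integer())
  lo <- min(inside); hi <- max(inside)
  step <- max(1L, as.integer(round(3 * scale / dt)), ceiling((hi - lo) / 24))
  seq(lo, hi, by = step)
}

# Dense smoothing matrix K (n x p): column i holds the renormalized truncated
# Gaussian kernel at scale s centred on pts[i], so crossprod(K, field) is the
# time-smoothing operator of smooth_time() evaluated at pts. For large
# kernels (s/dt > 6) the kernel rows are subsampled with step d ~ s/(6 dt)
# and column-renormalized: a quadrature of the same integral that is exact to
# rounding for the band-limited wavelet products being smoothed (the Morlet
# transform at scale s carries no energy above frequency ~12/s, well below
# the pi*d/s... Nyquist of the subsampled grid).
smoothing_matrix <- function(n, s, dt, pts) {
  h <- time_kernel_halfwidth(s, dt, n)
  d <- max(1L, as.integer(floor(s / (8 * dt))))
  rows <- seq(1L, n, by = d)
  K <- matrix(0, length(rows), length(pts))
  for (i in seq_along(pts)) {
    u <- rows - pts[i]
    inw <- abs(u) <= h
    K[inw, i] <- exp(-(u[inw]^2) / (2 * (s / dt)^2))
  }
  K <- sweep(K, 2, colSums(K), "/")
  list(K = K, rows = rows)
}

# Pooled per-scale null coherence values for `n_pairs` AR(1) surrogate pairs.
null_coherence_pool <- function(n, dt, scale_spec, r1x, r1y, n_pairs,
                                chunk_pairs = 250L) {
  scales <- scale_spec$scales
  periods <- scale_spec$periods
  J <- length(scales)
  hw <- scale_smooth_halfwidth(scale_spec$dj)
  coi <- cone_of_influence(n, dt)
  pts_list <- lapply(seq_len(J), function(j) {
    null_pool_points(n, dt, scales[j], periods[j], coi)
  })
  # smoothing matrices reused across chunks: one per (target scale, window scale)
  K_list <- lapply(seq_len(J), function(j) {
    if (length(pts_list[[j]]) == 0L) return(NULL)
    win <- max(1L, j - hw):min(J, j + hw)
    stats::setNames(
      lapply(win, function(jp) smoothing_matrix(n, scales[jp], dt, pts_list[[j]])),
      win
    )
  })
  pool <- vector("list", J)
  done <- 0L
  while (done < n_pairs) {
    B <- min(chunk_pairs, n_pairs - done)
    X <- ar1_surrogates(n, B, r1x)
    Y <- ar1_surrogates(n, B, r1y)
    W <- cwt_engine(cbind(X, Y), dt, scales)
    # scale-normalised real block [Re(cross) | Im(cross) | power_x | power_y],
    # built lazily per scale, kept only inside the cross-scale window.
    prod_cache <- vector("list", J)
    prod_at <- function(j) {
      if (is.null(prod_cache[[j]])) {
        Wx <- W[[j]][, seq_len(B), drop = FALSE]
        Wy <- W[[j]][, B + seq_len(B), drop = FALSE]
        Cxy <- Wx * Conj(Wy)
        prod_cache[[j]] <<- cbind(Re(Cxy), Im(Cxy),
                                  Re(Wx)^2 + Im(Wx)^2,
                                  Re(Wy)^2 + Im(Wy)^2) / scales[j]
      }
      prod_cache[[j]]
    }
    iB <- seq_len(B) # column blocks
    for (j in seq_len(J)) {
      pts <- pts_list[[j]]
      if (length(pts) == 0L) next
      win <- max(1L, j - hw):min(J, j + hw)
      S <- 0
      for (jp in win) {
        Km <- K_list[[j]][[as.character(jp)]]
        S <- S + crossprod(Km$K, prod_at(jp)[Km$rows, , drop = FALSE])
      }
      S <- S / length(win)
      if (j - hw - 1L >= 1L) prod_cache[j - hw - 1L] <- list(NULL)
      coh <- (S[, iB, drop = FALSE]^2 + S[, B + iB, drop = FALSE]^2) /
        (S[, 2L * B + iB, drop = FALSE] * S[, 3L * B + iB, drop = FALSE])
      pool[[j]] <- c(pool[[j]], as.vector(coh))
    }
    done <- done + B
  }
  pool
}

#' Monte-Carlo significance test for wavelet coherence
#'
#' Tests observed coherence against a red-noise null: AR(1) models are fitted
#' to both series, `n_surrogates` independent surrogate pairs are generated,
#' their coherence is computed with the identical estimator, and an in-COI
#' cell of the observed field is marked significant when it exceeds the
#' (1 - alpha) quantile of the per-scale pooled surrogate coherence
#' distribution. The mask is reported only inside the cone of influence.
#'
#' @inheritParams wavelet_coherence
#' @param alpha nominal level in (0, 1]; `alpha = 1` marks every in-COI cell.
#' @param n_surrogates number of surrogate pairs (>= 100 recommended).
#' @param rng_seed integer seed for the surrogate generator.
#' @param chunk_pairs surrogate pairs processed per batch (memory/speed
#'   trade-off only; no effect on results beyond RNG draw order; keep fixed
#'   for reproducibility).
#' @param object optionally, an existing `wavelet_coherence` for the same
#'   data; skips recomputing the observed field.
#' @return the `wavelet_coherence` object with `significant` (logical
#'   time x scale mask), `alpha` and `null_quantile` (per scale) filled in.
#' @export
coherence_significance <- function(data, x, y, dt = 1, scale_spec = NULL,
                                   alpha = 0.05, n_surrogates = 300,
                                   rng_seed = 1, chunk_pairs = 250L,
                                   object = NULL) {
  if (!(alpha > 0 && alpha <= 1)) abort("`alpha` must be in (0, 1]")
  if (is.data.frame(data)) {
    xn <- as_name(enquo(x)); yn <- as_name(enquo(y))
    xv <- series_values(data, xn, require_complete = TRUE, what = xn)
    yv <- series_values(data, yn, require_complete = TRUE, what = yn)
  } else {
    xv <- as.numeric(data); yv <- as.numeric(x)
  }
  n <- length(xv)
  if (is.null(scale_spec)) scale_spec <- scale_grid(n = n, dt = dt)
  if (is.null(object)) {
    object <- wavelet_coherence(tibble(date = series_dates(NULL, n), x = xv, y = yv),
                                x = "x", y = "y", dt = dt, scale_spec = scale_spec)
  }
  fx <- ar1_fit(xv); fy <- ar1_fit(yv)
  J <- length(scale_spec$scales)
  if (alpha == 1) {
    q <- rep(-Inf, J)
  } else {
    set.seed(rng_seed)
    pool <- null_coherence_pool(n, dt, scale_spec, fx$r1, fy$r1,
                                n_pairs = n_surrogates, chunk_pairs = chunk_pairs)
    q <- vapply(pool, function(v) {
      if (is.null(v)) Inf else as.numeric(quantile(v, 1 - alpha, type = 8))
    }, numeric(1))
  }
  sig <- sweep(object$coherence, 2, q, `>`) & object$inside_coi
  object$significant <- sig
  object$alpha <- alpha
  object$null_quantile <- q
  object$ar1 <- c(x = fx$r1, y = fy$r1)
  object
}
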