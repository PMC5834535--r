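---
title: "Methods: wavelet coherence analysis of phenology and climate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet coherence analysis of phenology and climate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(phenowave)
```

phenowave asks a time-scale question about tropical forest phenology: at which
periods do community-level leaf fall and seed fall co-vary with climate
drivers (soil water deficit, solar radiation, vapour pressure deficit), and
who leads whom at each period? Seasonally dry forests have a dominant annual
cycle, and ENSO superimposes a 2-7-year alternation of warm-dry and cool-wet
phases on it. Ordinary cross-correlation conflates these timescales; the
continuous wavelet transform separates them, and wavelet coherence with
cross-spectrum phase quantifies, period by period and moment by moment, both
the strength of the coupling and the lead/lag between the series.

## From trap censuses to community series

Seed rain is counted weekly per species as *seed equivalents*: mature seeds
plus mature fruits times the species mean seeds-per-fruit
(`seed_equivalents()`); records classified immature or damaged never enter
the sum. Leaf fall is weekly species-level litter dry mass. Community series
are built by z-scoring each species over its full record and averaging the
standardized series without weights (`community_series()`), so abundant and
rare species contribute equally to community timing. Species observed in too
few censuses carry more noise than signal and are dropped first
(`filter_species()`); the thresholds are *strictly more than* 10 censuses for
seeds and 3 for leaves, where a census is a week in which the species has a
nonzero record. An exclusion list handles species whose trap record is known
to be unreliable.

Climate indices: gravimetric soil water content, sampled every 1-3 weeks, is
linearly interpolated to the weekly grid and mapped to the deficit index
`(swc_max - swc) / (swc_max - swc_min)` in [0, 1] (0 = wet, 1 = dry;
`soil_water_deficit()`). The reference extremes default to the record-wide
extrema of the interpolated series and are configurable. Vapour pressure
deficit uses a Magnus-type saturation curve,
`e_sat(T) = 0.61094 exp(17.625 T / (T + 243.04))` kPa, with only 10:00-17:00
records retained before the weekly mean (`midday_vpd()`), the part of the day
when atmospheric demand matters most for stomatal behaviour. Weekly bins are
anchored at the first observation date. The wavelet analysis consumes
*non-detrended* series; `seasonal_detrend()` (week-of-year climatology,
weeks = day-of-year blocks of 7, the 53rd partial week kept separate) and the
13-week `running_mean()` exist for anomaly displays only. ENSO events are
maximal runs of a monthly ONI-style index strictly above +0.5 degC (warm) or
below -0.5 degC (cold) lasting at least five months
(`identify_enso_events()`); a month at exactly 0.5 never qualifies.

Missing weeks are carried as explicit `NA` and refused by the wavelet layer;
the one imputation offered is linear interpolation with end-value extension
(`impute_missing()`), applied by the pipeline to community series with
unreported weeks.

## Wavelet machinery

`cwt()` computes the Morlet transform (shape parameter k0 = 6) by
frequency-domain convolution with zero padding to the next power of two.
Scale and period are interchangeable through the Morlet relation
(period = 1.033 scale for k0 = 6). The default scale grid has 12 voices per
octave from an 8-week period up to half the record length. The cone of
influence (COI) uses the Morlet e-folding time sqrt(2) s: the trustworthy
period grows linearly with distance from the nearer series end, collapsing to
zero at the first and last samples; everything downstream (significance
masks, phase selection, global spectra) is restricted to the cone.

Coherence is the smoothed, scale-normalised squared cross-spectrum:

wc = |< c_xy / s >|^2 / ( < |w_x|^2 / s > < |w_y|^2 / s > ),

where `< >` is a separable smoothing operator: in time, a Gaussian matched to
the Morlet envelope at each scale (standard deviation = the scale, truncated
at 3 standard deviations, renormalized over the in-record support so the
operator has exact unit DC gain including at the edges); across scales, a
boxcar of about 0.6 octaves, also edge-renormalized. The operator is linear
and preserves constant fields exactly, which makes self-coherence exactly 1.
Without smoothing, coherence would be identically 1 everywhere; the smoothing
windows set its effective degrees of freedom. Values escape [0, 1] only at
rounding level; they are clipped and the clip count is reported.

**Phase convention.** The cross-spectrum is `c_xy = w_x Conj(w_y)` and
`phase_angle()` is its plain four-quadrant arctangent. The lead/lag reading
is fixed at the coherence level: `wavelet_coherence(x, y)` reports the angle
of the *conjugated* smoothed cross-spectrum, so that **a positive angle means
the first series lags the second**. Calling coherence with phenology first
and climate second therefore gives positive angles when the biology lags the
climate, and the constructed-delay unit tests pin the convention down.
`angle_to_lag()` converts angles to time with lag = angle/360 x period: 30
degrees is one month at the annual period and 2-7 months across the ENSO
band. When a band-averaged lag is reported, each selected cell is converted
with its own period and the lags are averaged, which is why ENSO-band lags
carry a wider spread than seasonal ones.

Band phase statistics (`band_select()`, `circular_mean_sd()`,
`phase_histogram()`) collect cells inside the COI with coherence strictly
above 0.5 (the conventional threshold for phase interpretation) in a period
band - here 0.8-1.25 years for the seasonal band and 2-7 years for the ENSO
band - and summarise them with circular statistics: the mean is the argument
of the mean resultant vector, the dispersion is the circular standard
deviation sqrt(-2 log R). Cells are unweighted by default (the hard coherence
threshold already gates them); coherence weighting is available. Adjacent
time-scale cells are strongly dependent, so alongside the raw cell count we
report an effective sample size: per selected period, the selected time
extent divided by that period (at least one), summed over periods - a
deliberate, simple decorrelation heuristic, not an exact dof calculation.

**Significance.** The null hypothesis is "two independent red-noise series".
Lag-1 autocorrelation and variance are estimated from each observed series,
`n_surrogates` independent AR(1) pairs are generated, and their coherence is
computed with the identical transform and smoothing operator. Because the
null is time-stationary, the surrogate coherence values are pooled per scale
across in-COI times, and an observed cell is significant when it exceeds the
per-scale (1 - alpha) quantile. Two performance devices are used, neither of
which changes the test definition: surrogate pairs are processed in batched
matrix FFTs, and the surrogate fields are evaluated at a decimated set of
in-COI time points (samples of the same stationary distribution; about 3
scales apart, at most ~24 points per scale) with the smoothing sums for
large kernels computed by a renormalized subsampled quadrature whose error on
the pooled quantiles is below half a percent. The observed field is always
smoothed in full. Calibration is verified by simulation: for independent
AR(1) pairs (r1 = 0.7, 30-year weekly records, 500 surrogates, alpha = 0.05)
the mean rejection rate over 100 replicate pairs sits near the nominal level
(the acceptance suite requires it in [0.025, 0.10]).

## Leaf area index and leaf life span

Gap fractions from hemispherical photographs are inverted with the light
penetration model `LAI = -log(P) cos(theta) / (Omega G)` with spherical leaf
angle distribution (G = 0.5), broadleaf clumping index (Omega = 0.9), and
only the near-zenith disk (theta < 4.5 degrees), within which Omega and G are
treated as constants (`lai_from_gap_fraction()`, `lai_params()`). P = 1 is
exactly LAI 0; an all-vegetation disk (P = 0) implies infinite LAI, so such
records are floored at half a pixel fraction, flagged saturated, and excluded
from aggregation by default (`gap_fraction_from_mask()`, `aggregate_lai()`).
Monthly summaries are means across locations with SE = sd/sqrt(n); a single
reporting location leaves the SE undefined and flagged. One value per
location-month is assumed. Life-span tables are binned by
`lifespan_histogram()`, optionally by stratum.

## The synthetic generator: what it emulates, and what it does not

`synth_config()` defines the simulated study conditions: 30 years of weekly
data; every climate variable = annual sinusoid + a shared narrowband ENSO
mode + AR(1) noise. The ENSO mode is a sum of three sinusoids at periods
P0 (1 +- bandwidth) around a 4-year centre with seeded phases - chosen over
band-passed noise because it permits *exact* band-specific delays and a
trivially verifiable spectral placement (>99% of its variance lies at 2-7-yr
periods under a Hann-tapered periodogram). Soil moisture gets high lag-1
autocorrelation (0.85) and low noise; radiation low autocorrelation (0.3) and
high noise, reproducing the buffered-soil vs cloud-driven spectra contrast of
real records. The monthly ONI-like index is the shared mode plus small
observation noise, scaled so warm/cold episodes cross the +-0.5 degC rule.

Phenology latents are the deficit signal with each band shifted by its
injected lead or lag - by default leaf fall *leads* the deficit by 6 weeks
seasonally and 4 months in the ENSO band, seed fall *lags* by 4 weeks and 5
months - realized exactly by phase-shifting the seasonal and ENSO components
separately before summing (a single time shift could not encode two
band-specific lags). Species series are loading x latent + AR(1) species
noise; seed counts are Poisson around the exponentiated latent (log link;
identity link and a no-sampling mode exist for exact unit tests), leaf mass
is Gamma around a softplus-transformed latent. Both links are monotone and
phase-preserving at the fundamental of each injected band, which is what
makes end-to-end lag recovery a fair test. Species counts default to 60
(seed) and 80 (leaf): community averages of z-scored series concentrate
quickly, so these desk-scale counts already behave like large communities. A
configurable fraction (15%) of species is generated too rare to pass the
inclusion thresholds, and one species arrives flagged on the exclusion list,
so the filtering rules are exercised, not just available. Random streams are
seeded per component (climate, phenology, gap fractions, life spans), so one
module's fixtures are stable under changes to another's draw count.

The generator does *not* emulate: species-to-species covariance beyond the
shared community latent (the loading model is a pragmatic choice), plant
demography or succession-driven trends, trap-level spatial structure,
rainfall as a process (soil moisture is generated directly), observation
gaps, or calendar artefacts such as trap losses. Passing recovery tests
therefore demonstrates that the estimator chain is correct and unbiased under
the assumed data model - not that real trap data meet those assumptions.

## Numerical choices and degenerate inputs

- Padding: zero padding to the next power of two; coefficients un-padded
  after the transform. Edge effects are handled by the COI, not the padding.
- Scale grid: fractional powers of two; 12 voices/octave default. The
  calibration studies in the acceptance suite use 4 voices/octave over
  periods 8-512 weeks - scale-grid density does not enter the calibration
  property, and the coarser grid keeps 50,000 surrogate coherence fields
  affordable.
- Quantile estimation: type-8 sample quantiles per scale; `alpha = 1` is
  honoured as "everything in the cone significant".
- Degenerate inputs are errors, not warnings: zero-variance series in
  coherence, |r1| >= 1 in the AR(1) fit, constant series in `normalize_01()`
  and `community_series()` (all species constant), swc_max = swc_min, P = 0
  in the LAI inversion, missing values in `cwt()`.
- Zero cross-spectrum cells have undefined phase and are returned as `NA`;
  a zero resultant makes the circular mean an error rather than a number.
- The 3-month running mean is centered (window 13); whether the original
  displays used centered or trailing means is not documented, and centered
  is the package's fixed choice.
- Problem sizes in the test suite (30-year records for coherence checks,
  100 x 500 surrogate calibration, 200-replicate LAI coverage simulation)
  are the package's chosen verification scale.

## A worked synthetic run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(synth = synth_config(rng_seed = 1),
                       pairs = rbind(c("seed", "deficit"), c("leaf", "deficit")))
res <- run_pipeline(cfg, out_dir = tempfile("phenowave_"))
res$phase_summary
autoplot(res$coherence$leaf_deficit)
autoplot(phase_histogram(res$phases$leaf_deficit_seasonal))
```

`phase_summary` reports, per pair and band, the circular mean and sd of the
selected phase angles and the mean per-cell lag in weeks; with the default
injected structure the leaf x deficit seasonal row recovers about -6 weeks
(leaf fall leading) and the seed x deficit row about +4 weeks (seed fall
lagging), with ENSO-band lags recovered within a month.

## Known limitations

- Coherence smoothing windows are a documented choice; other toolboxes use
  slightly different windows, so numerical agreement with them holds only up
  to the operator definition.
- The AR(1) null tests "no coupling beyond red noise"; it does not model
  seasonal phase locking, so strongly seasonal pairs are (correctly) nearly
  always significant at the annual period.
- The effective-sample-size heuristic for phase statistics understates
  dependence between neighbouring scales.
- The LAI inversion treats Omega and G as scalars within the zenith disk and
  does not model multi-ring inversions or raw-image classification.
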