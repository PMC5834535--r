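# phenowave

Wavelet coherence analysis of tropical-forest phenology and climate.

In seasonally dry tropical forests, leaf fall and seed fall track climate at
two very different timescales at once: the annual wet/dry cycle, and the
2–7-year alternation of warm-dry (El Niño) and cool-wet (La Niña) phases of
ENSO. phenowave is for ecologists who have long weekly records — per-species
seed-trap counts, litter-trap dry mass, tower meteorology, soil moisture, a
monthly Oceanic-Niño-style index, hemispherical-photo gap fractions — and
want to ask, period by period: *how strongly is community phenology coupled
to each climate driver, and who leads whom?*

## What it computes

- **Community series** (`seed_equivalents()`, `filter_species()`,
  `community_series()`): weekly seed equivalents (mature seeds + mature
  fruits × seeds-per-fruit), species inclusion by strict census thresholds
  (>10 for seeds, >3 for leaves) and exclusion lists, then the unweighted
  mean of per-species z-scored series.
- **Climate indices** (`soil_water_deficit()`, `midday_vpd()`): the soil
  water deficit index `(swc_max − swc)/(swc_max − swc_min)` from irregular
  gravimetric samples, and midday (10:00–17:00) vapour pressure deficit from
  a Magnus-type saturation curve, aggregated weekly.
- **Wavelet coherence and phase** (`cwt()`, `wavelet_coherence()`,
  `coherence_significance()`): Morlet (k0 = 6) continuous wavelet transform;
  coherence `wc = |⟨c_xy/s⟩|² / (⟨s_x/s⟩⟨s_y/s⟩)` with a documented
  time-and-scale smoothing operator; four-quadrant cross-spectrum phase with
  the convention *positive angle = first series lags the second*; cone of
  influence; Monte-Carlo significance against AR(1) red-noise surrogate
  pairs, with per-scale null quantiles.
- **Band lead/lag statistics** (`band_select()`, `circular_mean_sd()`,
  `angle_to_lag()`, `phase_histogram()`): phase angles of in-cone cells with
  coherence > 0.5 in the seasonal (≈12-month) and ENSO (2–7-year) bands,
  circular means ± circular standard deviations, angle→lag conversion
  (30° = 1 month at the annual period), wind-rose histograms.
- **ENSO events** (`identify_enso_events()`): maximal runs of the monthly
  index strictly beyond ±0.5 °C for ≥5 consecutive months.
- **Leaf area index** (`lai_from_gap_fraction()`, `aggregate_lai()`):
  `LAI = −log(P)·cos(θ)/(Ω·G)` with G = 0.5, Ω = 0.9 inside the 4.5° zenith
  disk; monthly means ± standard errors across locations; leaf life-span
  histograms (`lifespan_histogram()`).
- **Synthetic fixtures with known truth** (`synth_config()`,
  `synth_climate()`, `synth_phenology()`, `synth_gap_fractions()`,
  `synth_lifespans()`, `write_synth_fixtures()`): 30 years of weekly climate
  with an annual cycle, a shared narrowband ENSO mode and AR(1) noise, plus
  species-level trap tables whose leaf fall *leads* and seed fall *lags* soil
  water deficit by configurable, band-specific amounts — so every estimator
  in the chain can be checked against injected ground truth.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` accessors for the
wavelet objects and `autoplot()` methods (coherence maps with COI shading and
significance contours, wind roses, monthly LAI ribbons). `run_pipeline()`
orchestrates the whole analysis from a config and writes a reproducible
artifact directory; `inst/scripts/phenowave` is a thin CLI over it.

## Worked example

```r
library(phenowave)

cfg <- pipeline_config(
  synth = synth_config(rng_seed = 1),  # leaf leads deficit 6 wk / 4 mo; seed lags 4 wk / 5 mo
  pairs = rbind(c("seed", "deficit"), c("leaf", "deficit"))
)
res <- run_pipeline(cfg, out_dir = "phenowave_run")
res$phase_summary
#>           pair     band mean_deg sd_deg mean_lag_weeks     n
#> 1 seed_deficit seasonal    29.07   3.03           4.25 11358
#> 2 seed_deficit     enso    43.47   6.87          24.59 19458
#> 3 leaf_deficit seasonal   -40.95   2.57          -5.99 11358
#> 4 leaf_deficit     enso   -27.13   7.23         -14.93 20236
```

Read: in the seasonal band, community seed fall *lags* soil water deficit by
4.3 weeks (circular mean +29° ± 3° at ~52-week periods; truth: +4 weeks) and
leaf fall *leads* it by 6.0 weeks (−41° ± 2.6°; truth: −6 weeks). In the
ENSO band the recovered lags, −14.9 and +24.6 weeks, sit within a month of
the injected 4- and 5-month offsets. `res$enso_events` lists the warm/cold
episodes detected from the synthetic ONI (e.g. a 13-month warm event peaking
at +1.47 °C), and `phenowave_run/` holds the tidy coherence grids, phase
histograms, anomaly series, monthly LAI table and a manifest with the config
hash and seed.

```r
autoplot(res$coherence$leaf_deficit)                       # coherence map + COI + significance
autoplot(phase_histogram(res$phases$leaf_deficit_seasonal)) # wind rose
```

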