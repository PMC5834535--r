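Package: phenowave
Title: Wavelet Coherence Analysis of Tropical Forest Phenology and Climate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing how community-level leaf fall and seed fall
    in tropical forests co-vary with climate at seasonal and ENSO (El
    Nino-Southern Oscillation) timescales. Builds analysis-ready weekly
    community phenology series from seed-trap and litter-trap censuses,
    derives climate indices (soil water deficit, midday vapour pressure
    deficit), computes Morlet continuous wavelet transforms, smoothed wavelet
    coherence and cross-spectrum phase angles with cone-of-influence and
    AR(1) red-noise Monte-Carlo significance testing, summarises band
    restricted lead/lag phase angles with circular statistics, detects ENSO
    events from an Oceanic Nino-style index, and inverts leaf area index from
    hemispherical-photograph gap fractions. A synthetic-data generator with
    known injected seasonal and interannual structure supports end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    zoo
Config/testthat/edition: 3
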