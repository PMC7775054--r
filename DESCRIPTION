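Package: phenorisk
Title: Degree-Day Phenology and Temperature-Stress Suitability Mapping for
    Insect Pests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily time-step, cohort-based simulator of insect phenology
    (degree-days, life stages, generations, and phenological events) coupled
    with a temperature-stress climatic suitability model (moderate and severe
    cold and heat stress exclusions). Operates point-wise or over gridded
    daily minimum/maximum temperature series, supports multi-cohort
    overwintering emergence distributions, and writes multi-band GeoTIFF
    rasters, summary map images, and run manifests. Includes a synthetic
    gridded weather generator with seasonal and latitudinal structure and a
    mean-preserving monthly-to-daily temperature interpolator, so the full
    pipeline is testable without external climate data.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
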