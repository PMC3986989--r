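Package: soilrisk
Title: Ecological and Human Health Risk Assessment of Heavy Metals in Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative assessment of soil heavy-metal contamination along
    disturbance gradients such as pipeline construction corridors. Implements
    the geo-accumulation index with Mueller's seven contamination classes, the
    Hakanson potential ecological risk index, and USEPA/USDOE-style
    three-pathway human health risk assessment (ingestion, inhalation of
    resuspended particulates, dermal contact) for child and adult receptors,
    including age-adjusted carcinogenic exposure factors. Provides one-way
    ANOVA zone comparisons and correlation-based hierarchical clustering of
    metals for source attribution, a seeded synthetic transect-sampling
    generator with known ground truth, and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
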