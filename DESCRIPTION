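Package: traitbloom
Title: Trait-Based Analysis of Flowering Phenology in Grassland Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trait-based phenological analysis of flowering-shoot
    counts in plant communities. Aggregates per-species counts of shoots in
    full bloom into trait-state mean flowering proportions on a
    releves-by-trait-states matrix, detects indicator trait states of
    observation times (including combinations of two and three times) by
    indicator value analysis with seeded permutation inference and
    abundance/frequency retention filters, partitions flowering variance
    among observation time and environmental predictors (soil temperature,
    soil relative humidity, canopy height) by redundancy analysis with
    adjusted R-squared variation partitioning, and models trait-state
    flowering trends with linear mixed-effects models compared by likelihood
    ratio tests. A synthetic-study generator emulates the sampling design
    (three topographic communities, 35 plots each, twelve biweekly
    observation times with mowing gaps) with plantable indicator trait
    states for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
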