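Package: antdiv
Title: Global Invertebrate Biodiversity Mapping from Noisy Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for inferring global biodiversity
    patterns of a data-poor taxon (motivated by ants) from heterogeneous
    occurrence records: record cleaning and coordinate resolution,
    range estimation by buffered points, alpha hulls and penalized
    presence-background suitability models, stacking into species
    richness and rarity-weighted richness rasters, diversity-center
    detection, cross-taxon congruence, incidence-based rarefaction, and
    a Random Forest sampling-bias counterfactual that projects diversity
    under universally high sampling. Ships a seeded synthetic-world
    generator (environment, species, biased collecting, record noise,
    companion taxa, protected areas) so the whole chain is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    geosphere,
    ranger,
    jsonlite,
    rlang,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
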