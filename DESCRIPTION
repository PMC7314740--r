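Package: dogedge
Title: Edge Effects of Free-Roaming Dogs on Protected Habitat
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies landscape-scale edge effects of free-roaming dogs on
    wildlife habitat in and around protected areas. Converts digitized
    residence locations into populated-area masks via a housing-density
    threshold, computes terrain-aware multi-source path-distance surfaces
    over a digital elevation model, extracts human-impact and dog-foray
    zones, accounts effective habitat area, compares occurrence locations
    against available habitat as a function of path distance, and ranks
    reserves into threat tiers with exact Jenks natural-breaks
    classification. Includes a synthetic-landscape simulator so the whole
    pipeline runs and is tested without sensitive occurrence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
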