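Package: paretoprior
Title: Pareto Ranking for Spatial Conservation Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-criteria prioritization of raster grid cells for
    conservation monitoring and management. Derives wildfire-threat,
    habitat-fragmentation, species-richness and genetic-biodiversity
    attributes from aligned raster layers, transforms them into
    minimization criteria with linear min-max value functions, ranks
    cells by iterative extraction of non-dominated sets (Pareto
    ranking), including composite rank-of-ranks, and summarizes
    priorities by zone and conservation status. Includes a synthetic
    landscape generator and a simulation harness for studying how the
    range of Pareto ranks depends on the number of criteria, their
    correlation, and the number of units ranked.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
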