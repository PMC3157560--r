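Package: forage3d
Title: Ordinal-Distance Analysis of Foraging in Vertical and Volumetric Mazes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how climbing rodents distribute movement
    between horizontal and vertical dimensions while foraging. Implements
    the ordinal-distance clustering statistic over layers, columns and
    slices of a discretised maze, genetic-algorithm distance-optimal
    reference routes, per-dimension bin/cube crossing counts, and
    detour-choice tallies, together with seeded synthetic generators for
    food layouts, agent visit orders, trajectories and choice records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
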