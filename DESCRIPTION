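Package: pondscape
Title: Circuit-Theory Connectivity of Urban Pond Networks and Odonate
    Community Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models landscape connectivity around urban ponds as electric
    current flowing through a resistance-classified land-cover raster
    (graph-Laplacian circuit theory with a randomized representative
    edge-correction buffer and random perimeter nodes), extracts per-pond
    connectivity predictors (mean and standard deviation of current within
    taxon-specific radii, nearest-neighbour habitat counts), and links them
    to dragonfly and damselfly abundance, richness, Shannon diversity and
    composition through Gaussian linear models, Hellinger
    transformation-based redundancy analysis with permutation tests, and
    Wilcoxon rank-sum pond-type comparisons. Includes a synthetic landscape
    and community generator so the full pipeline is testable without
    external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
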