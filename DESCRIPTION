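Package: streamnet
Title: Weighted Structural Connectomes from Streamline Tractography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds dimensionless, scale-invariant weighted brain connectomes
    from streamline tractograms, computes threshold-free weighted topology
    indices (graph density, node strength, Zhang-Horvath clustering,
    strength-of-shortest-path length, small-worldness against Erdos-Renyi
    nulls), compares groups with density-controlled Mann-Whitney tests and a
    Grenander-based false-nondiscovery multiple-comparison correction, and
    correlates network indices with cognitive composites via Spearman partial
    correlations with Fisher z transforms. Includes synthetic tractography
    phantoms and grouped cohort generators so the full pipeline is testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
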