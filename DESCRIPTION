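Package: hummnet
Title: Structure and Trait-Matching Mechanisms of Plant-Hummingbird
    Pollination Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing quantitative plant-hummingbird visitation
    networks sampled by monthly camera transects. Builds site-level
    visitation-rate matrices from long-format monthly records, computes four
    community-level descriptors (Barber weighted bipartite modularity via a
    label-propagation optimizer, connectance, H2' specialization and weighted
    NODF nestedness), standardizes them against temporally constrained null
    models that preserve phenological overlap, hummingbird visit totals and
    camera recording effort, quantifies species-level contributions to each
    descriptor by focal-species randomization, measures visitation-weighted
    bill-corolla trait mismatch and its standardized effect size, and reports
    site-level taxonomic richness, standardized Faith's phylogenetic
    diversity and functional divergence. Includes a synthetic community
    generator with a tunable trait-matching linkage rule for calibration and
    power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    boot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
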