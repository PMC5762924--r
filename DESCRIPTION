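Package: paleotrait
Title: Trait-Based Analysis of Late-Quaternary Plant Communities from
    Sedimentary Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trait-based analysis of metabarcoding read-count
    tables from sedimentary ancient DNA, built around the community record
    of northern high-latitude vegetation across the last glacial cycle.
    Provides climatic-period classification and dataset filtering,
    source-precedence merging of plant mutualist trait databases
    (mycorrhizal type and status, nitrogen fixation, pollination mode,
    growth form), read- and taxon-weighted trait composition with
    stratified bootstrap confidence intervals, PERMANOVA with sequential
    sums of squares and pairwise contrasts, outlying mean index (OMI)
    niche ordination with a Monte Carlo randomization test and Dunn's
    post-hoc tests, Mantel correlograms and multi-scale variance
    decomposition for spatial diagnostics, grafting of molecular taxa onto
    a backbone phylogeny with phylogenetic generalized least squares under
    Pagel's lambda, a trait-database error-propagation simulation, and a
    synthetic-data generator emulating the statistical structure of
    permafrost metabarcoding data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    phytools,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
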