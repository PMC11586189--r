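Package: microdeg
Title: Hydrocarbon Degradation Potential and Kinetics for Amplicon Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the hydrocarbon-degradation potential of
    bacterial communities from genus-level amplicon abundance tables, using
    genome-database-derived marker-gene coefficients (the fraction of a
    genus's genomes carrying alkB, ladA-alpha, naphthalene-dioxygenase and
    related marker sets). Also provides percent-removal accounting against
    heat-killed controls, fixed-intercept first-order degradation kinetics
    with half-life estimation and condition contrasts, ASV filtering, rank
    collapse, minor-taxon aggregation, Hellinger-transform PCA, Kruskal-Wallis
    tests with Dunn post-hoc comparisons, and seeded synthetic-data generators
    with ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
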