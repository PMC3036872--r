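Package: crpopgen
Title: Population Genetics of Mitochondrial Control-Region Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for aligned mitochondrial control-region
    sequences sampled from several localities: haplotype collapsing and
    frequency tables, haplotype and nucleotide diversity with their
    variances, Tamura-Nei (optionally gamma-corrected) distances, Tajima's D
    and Fu's Fs neutrality tests with coalescent p-values, mismatch
    distributions with sudden-expansion model fitting (tau, theta0, theta1),
    Harpending's raggedness and parametric-bootstrap goodness of fit, AMOVA
    variance components and pairwise Phi-ST with permutation tests, minimum
    spanning haplotype networks, a reduced two-population
    isolation-with-migration coalescent MCMC for divergence time, migration
    and TMRCA, and a structured coalescent simulator with HKY sequence
    evolution that generates synthetic data sets with the statistical
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    xml2,
    phangorn,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
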