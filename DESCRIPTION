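Package: omegascan
Title: Genome-Wide Branch-Site Scans for Positive Selection in Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects episodic positive selection on focal branches of a species
    phylogeny from in-frame codon alignments. Implements the Goldman-Yang codon
    substitution process with F3x4 equilibrium frequencies, the branch-site
    mixture model with four site classes and its omega2=1 null, maximum
    likelihood fitting by Felsenstein pruning, likelihood ratio tests, Bayes
    Empirical Bayes site posteriors, an aggregation filter that removes genes
    whose positively selected sites cluster tightly along the alignment (a
    signature of alignment error), Benjamini-Hochberg false discovery rate
    control, and GC3 confounder diagnostics. Includes a codon-sequence
    simulator with known site-class truth and fragmentary-coverage dropout,
    and a downstream stage that builds protein-protein interaction networks
    from scored edge lists, maps Gene Ontology categories onto them, tests
    category clustering by label permutation, and runs classic Fisher GO
    enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
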