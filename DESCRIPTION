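Package: ffascreen
Title: Screening and Ranking of Microbial Proteomes for Free Fatty Acid
    Production Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores, ranks and categorizes microbial strains (originally
    cyanobacteria) for their potential as free-fatty-acid producing cell
    factories, from their predicted proteomes. A curated panel of criterion
    proteins with positive, negative or required impact on fatty-acid
    production, organized into orthologous groups, is matched against each
    proteome using homology evidence (BLAST tabular), domain evidence (HMMER
    domtblout) and a stringent domain-completeness filter; presence/absence
    feature vectors are scored with sign-constrained weights, min-max
    normalized over a cohort, ranked, and split into Top-ranked, Positive and
    Negative categories using reference strains and an exact one-dimensional
    2-means boundary. Includes reference-anchored weight calibration,
    engineering-modification suggestions, a dependency-free Smith-Waterman
    fallback aligner, and a synthetic-data generator producing panels,
    proteomes, evidence files and cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
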