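Package: sspfam
Title: De Novo Discovery of Small Secretory Peptide Families from
    Predicted Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects families of small secretory peptides (SSPs) in
    predicted proteomes without relying on prior annotation. Short
    proteins (< 200 aa) carrying a cleavable N-terminal signal peptide
    are selected, their C-terminal 50 residues are compared all-against-
    all by exact Smith-Waterman local alignment (BLOSUM50), and the
    resulting e-value graph is clustered with the Markov Cluster
    Algorithm (inflation 1.5). Each cluster is aligned, pruned to its
    conserved columns (BLOSUM62), and modelled as a calibrated profile
    hidden Markov model; unclustered singletons are recruited
    iteratively until a fixpoint. Clusters are aggregated into families
    by profile-profile comparison followed by a second round of Markov
    clustering, and arbitrary proteomes can be screened against the
    family library. Includes a seeded generator of synthetic
    preproprotein datasets with planted motif families for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    mclust,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
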