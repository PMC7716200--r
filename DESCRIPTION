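Package: lpeval
Title: Imputation from Low-Pass Sequencing and Genomic Prediction Evaluation
Version: 0.1.0
Authors@R:
    person("lpeval", "maintainers", email = "devnull@example.org", role = c("aut", "cre"))
Description: Simulation-based evaluation of genotype imputation from low-pass
    (sub-1X) whole-genome sequencing against a phased haplotype reference
    panel, and of the downstream use of imputed genotypes for genomic
    prediction in livestock. Provides a coalescent-free synthetic-data
    generator with known truth (multi-breed haplotype panels, pedigreed
    mosaic individuals, additive phenotypes, Poisson read counts), a diploid
    Li-Stephens haplotype-copying hidden Markov model yielding per-site
    genotype posteriors, phred-scaled call-confidence scoring and
    MAF-stratified agreement metrics, pedigree and genomic BLUP with EM/AI
    restricted maximum likelihood, marker-effect backsolving to molecular
    breeding values, permutation-based variant-subset selection, and a
    deterministic end-to-end pipeline with plain-text artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
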