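Package: finekin
Title: Fine-Scale Population Genetic Structure and Kinship Analysis for
    Codominant Microsatellite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing codominant multilocus genotypes sampled
    under a nested spatial design (locality, transect, point, aggregate).
    Reads and writes GenAlEx-style genotype tables, computes per-site
    diversity statistics (allele counts, private alleles, observed and
    unbiased expected heterozygosity, inbreeding coefficients), exact
    Hardy-Weinberg tests by Markov chain Monte Carlo, genotypic linkage
    disequilibrium permutation tests, probabilities of identity, and
    null-allele frequencies by expectation-maximisation.  Population
    structure is summarised by codominant AMOVA with permutation tests,
    pairwise FST, and null-allele-corrected (ENA) Weir-Cockerham FST with
    locus-bootstrap confidence intervals.  Fine-scale structure is
    assessed with multilocus spatial autocorrelograms, Lynch-Ritland
    relatedness with hierarchical permutation tests, full-sibling
    likelihood-ratio classification with simulated significance, Loiselle
    kinship profiles, and duplicate-genotype scans.  A simulator with
    known truth (cluster membership, pedigrees, selfing, null alleles)
    generates data matching the assumed sampling structure so every
    estimator can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
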