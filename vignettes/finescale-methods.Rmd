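---
title: "Methods: fine-scale structure and kinship from hierarchical microsatellite sampling"
author: "finekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale structure and kinship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finekin)
```

# The problem

`finekin` analyses codominant multilocus genotypes (microsatellites)
collected under a nested spatial design: localities tens of kilometres
apart, two 50 m transects per locality, points every 10 m along each
transect, and "perchas" — natural aggregates of sessile individuals —
sampled within one metre of each point.  The scientific questions are
those of fine-scale marine population genetics: is genetic similarity
spatially autocorrelated below 50 m?  Are close relatives (full sibs,
selfed offspring) aggregated within perchas or points, as expected if
larval cohorts disperse cohesively?  And is differentiation between
localities (a genetic break) attributable to such fine-scale processes?

The package provides the full chain: file I/O and filtering, per-site
diversity statistics, exact Hardy-Weinberg and linkage-disequilibrium
tests, null-allele estimation, AMOVA-based F-statistics, pairwise FST
(permutation and null-corrected), spatial autocorrelograms, pairwise
relatedness and kinship with hierarchical permutation tests, full-sib
likelihood-ratio classification, and duplicate-genotype scans — plus a
synthetic-data generator with known truth against which every estimator
is validated.

# Data model and filtering

A genotype is an unordered pair of integer allele sizes (bp); `0` in
files marks a missing allele.  A genotype with exactly one missing
allele is promoted to fully missing with a warning: half-calls have no
defined meaning in any downstream estimator, and counting rules stay
unambiguous.  Individuals missing more than `max_missing_loci = 2` of
the ten loci are removed, i.e. retained samples are typed at eight or
more loci.  Only fully missing loci are counted.

Alleles are matched by exact integer size; no binning of near sizes is
attempted (binning belongs to the chromatogram-scoring stage upstream).

# Diversity statistics

Per site (transect) and locus: `N` typed individuals, allele count `Na`,
observed heterozygosity `Ho`, unbiased expected heterozygosity
`uHe = (2N/(2N-1)) (1 - sum p^2)`, and the inbreeding coefficient as the
ratio convention `FIS = 1 - Ho/uHe`.  This convention reproduces the
arithmetic of the standard spreadsheet tools for codominant data; the
Weir-Cockerham single-sample `f` is available under `fis = "wc"` for
cross-tool comparison.  Multilocus summaries are across-locus means — in
particular the multilocus `FIS` is the mean of per-locus `FIS`, not
`1 - mean(Ho)/mean(uHe)`.  Private alleles (`PAP`) are counted at the
site level: an allele observed in exactly one of the six sites.

Probabilities of identity use the standard unrelated and full-sib
expressions per locus,
`PI = 2 (sum p^2)^2 - sum p^4` and
`PIsibs = 0.25 + 0.5 sum p^2 + 0.5 (sum p^2)^2 - 0.25 sum p^4`,
with multilocus values the product over loci.

## Hardy-Weinberg exact tests

`hwe_test_mc()` runs a Markov chain over the genotype configurations
with the observed allele counts fixed.  The state is the assignment of
allele copies to the two slots of each labelled individual; a symmetric
swap of one allele between two individuals is always accepted, because
every distinct assignment is equally likely under the conditional
Hardy-Weinberg null.  The induced table distribution is the exact
conditional one (proportional to `2^h / prod n_ij!`).  Two p-values are
reported: the two-sided exact p (frequency of tables no more probable
than observed) and a heterozygote-deficit p (frequency of tables with no
more heterozygotes than observed); the deficit side is the headline flag
because heterozygote deficiency is the alternative of interest.  The
chain uses the classic parameterisation (1,000 dememorisation steps, 100
batches of 1,000 iterations; batch means give a Monte Carlo standard
error).  A full enumeration for biallelic loci
(`hwe_exact_biallelic()`) serves as the oracle in the test suite.

## Linkage disequilibrium

`genotypic_ld_mc()` tests genotypic association per site and locus pair
with a log-likelihood-ratio (G) statistic on the two-locus genotype
table, permuting one locus's genotypes among individuals.  The
permutation p-value carries the +1 correction, so its resolution is
`1/(n_perm + 1)`.  We implement the genotypic permutation LLR variant;
the commonly used software default is the same family but its exact
Markov-chain settings are not reproducible from published descriptions.
Note that true family structure (co-settled sib clutches) induces
genotypic associations, so on kin-structured data this test rejects more
often than its nominal level — that is signal, not miscalibration.

## Null alleles

`null_allele_em()` fits, per site and locus, the model in which a null
allele of frequency `b` segregates under Hardy-Weinberg proportions:
visible/null heterozygotes present as visible homozygotes, null
homozygotes as blanks.  Blanks are excluded from the likelihood
(truncated multinomial; they are confounded with experimental dropout),
and the EM augments the data with the expected number of unobserved null
homozygotes.  Convergence is declared when the null-frequency update
falls below `tol = 1e-8`; the observed-data log-likelihood is
non-decreasing (asserted in tests).

False-discovery-rate control uses Benjamini-Hochberg step-up
(`bh_fdr()`), applied within each test family separately (HWE across
site x locus; LD across site x pairs).

# Population structure

`amova()` partitions variance among populations, among individuals
within populations, and within individuals, treating the two allele
copies of an individual as the lowest level, with squared distance 1
between distinct alleles.  Sums of squares are accumulated over loci
(missing genotypes drop out per locus); degrees of freedom follow the
multilocus convention `P - 1`, `N - P`, `N`, so the table has the
familiar shape and the df sum is `2N - 1`.  Negative variance components
are truncated to zero before percentages and F-statistics are formed.
Permutation schemes: individuals among populations (FST), allele copies
among individuals within populations (FIS), allele copies among all
individuals (FIT); p-values carry the +1 correction.

`pairwise_fst_permutation()` applies the two-population AMOVA to every
site pair (9,999 permutations by default, BH-FDR across the 15 pairs).
`ena_corrected_fst()` computes multilocus Weir-Cockerham theta with the
null-allele correction: per site and locus the EM re-estimates visible
allele frequencies jointly with the null frequency, the null class is
excluded from the summation over alleles, and per-allele
heterozygosities enter at their Hardy-Weinberg expectation given the
corrected frequencies (the observed heterozygosity is exactly what nulls
distort).  95% confidence intervals bootstrap loci (10,000 replicates);
a pair is significant when its CI excludes zero.  With a single locus
the CI is undefined and flagged.

# Fine-scale structure

## Spatial autocorrelation

Positions are known only to the transect point, so same-point (and
same-percha) pairs sit at 0 m and cross-transect pairs are masked.
Distance classes are half-open `(upper - 10, upper]` labelled by their
upper bound, with distance 0 forming its own class — six classes (0, 10,
..., 50 m) over a 50 m transect, one per attainable point separation.

The multilocus squared genetic distance between two genotypes is
`0.5 sum (y1 - y2)^2` per locus on allele-count vectors (0 for identical
genotypes up to 4 between distinct homozygotes), summed over mutually
typed loci and rescaled by `L / L_shared`.  The distance matrix is
double-centred to covariance form, and the autocorrelation `r` for a
class is the ratio of summed between-individual covariances to summed
within-individual variances over the class's pairs.  The estimator's
expectation under no structure is slightly negative (about `-1/(n-1)`,
an intrinsic property of the centring); the permutation envelope shares
this offset, so observed-versus-envelope comparisons are calibrated.
The null envelope permutes individuals among positions (9,999 by
default); the CI around each observed `r` bootstraps pairs within the
class (10,000 by default; resampling pairs rather than individuals is a
documented choice, exposed through the code path rather than a flag).

## Relatedness and its hierarchical test

`lynch_ritland_matrix()` implements the regression estimator of pairwise
relatedness with the published information weighting across loci and
resolves the reference/proband asymmetry by averaging the two directed
estimates.  Reference frequencies come from the data subset under
analysis (each locality, for the hierarchical tests), matching the
workflow in which each locality is analysed against its own frequencies;
kinship (below) instead uses full-dataset frequencies so values are
comparable across localities.  Alleles absent from the reference receive
a floor frequency `1/(2n + 1)` with renormalisation.  Uninformative loci
(zero regression denominator) are skipped per pair; pairs sharing fewer
than 5 typed loci are masked.

`hierarchical_relatedness_test()` compares each group's mean within-group
relatedness (perchas with at least 10 individuals; points; transects)
against a null built by permuting individuals among the groups of the
same locality, preserving group sizes (9,999 permutations; two-sided
empirical p; 2.5/97.5% null limits).  A bootstrap CI on the observed
mean (resampling pairs) supports plotting.

## Full-sib classification

`sib_likelihood_test()` scores every within-locality pair with the
multilocus likelihood ratio of full sibship (identity-by-descent
coefficients 0.25/0.5/0.25) against unrelatedness, with locality allele
frequencies and missing loci skipped.  Significance comes from 10,000
simulated unrelated pairs: simulated per-locus log-LRs are summed over
exactly the observed pair's typed loci, so pairs with missing data are
compared against their own null.  The full-sib flag uses `p <= 0.01`.
A parallel set of simulated full-sib pairs is retained for power
reporting only — the null simulation alone determines p-values, since
the reference tool's use of the alternative-hypothesis simulations is
not specified in published descriptions.  Pairs spanning localities are
not classified (the frequency reference would be ambiguous).

Proportions of full-sib pairs within versus among groups at each level
are compared with the pooled two-proportion Z test without continuity
correction; `chisq = Z^2` is reported alongside, matching the common
df = 1 presentation.  We report exact p-values throughout.

## Kinship profile and duplicates

`loiselle_kinship_profile()` computes the correlation-type kinship
coefficient with the small-sample correction term
`sum p(1-p)/(n_g - 1)` per locus (`n_g` gene copies), multilocus as the
ratio of sums over polymorphic loci.  Referenced to full-dataset
frequencies, its mean over all pairs is ~0, full sibs sit near 0.25 and
identical genotypes near 0.5.  Coefficients are binned into half-open
`[x, x + 0.01)` bins split within/among localities; pairs above the
configurable threshold 0.36 are listed with their hierarchy context.

`duplicate_genotype_scan()` reports pairs identical over their mutually
typed loci (at least 8 by default) and pairs differing at exactly one
locus, with the expected number of identical unrelated (PI-based) and
full-sib (PIsibs-based) pairs for interpretation.

# The synthetic-data generator

`simulate_dataset()` draws a dataset with known truth under the nested
design.  Its defaults are fixed to emulate the survey the package's
analyses are shaped around:

* design: 3 localities x 2 transects x 6 points x 3-5 perchas x 3-10
  individuals (about 950 individuals, matching the ~900-sample scale);
* loci: ten microsatellites with per-locus allele counts
  28, 18, 23, 18, 22, 15, 23, 26, 29, 12 (the published per-locus
  counts; range 12-29, mean 21);
* ancestral allele frequencies: symmetric Dirichlet with concentration
  1, giving multilocus expected heterozygosities of 0.84-0.90;
* clusters: two, localities 2-3 sharing one cluster, Balding-Nichols
  divergence `F = 0.03` (the scale of the published pairwise FST,
  0.00-0.05);
* kin aggregation: 20% of perchas carry one co-settled full-sib clutch
  of 3 (two simulated parents, Mendelian offspring), yielding
  within-percha sib-pair proportions of a few percent;
* selfing: with probability 0.01 an individual is the selfed offspring
  of an inbred parent (autozygous at half its loci, emulating a
  selfing lineage) placed in the same percha, so the sample contains
  identical and one-locus-different pairs at the published rate (2 and
  4 among ~900);
* null alleles: a latent per-locus null allele with frequencies
  0.24, 0.12, 0.07, 0.03, 0.08, 0.03, 0.19, 0.26, 0.30, 0 — about half
  the published per-locus inbreeding coefficients, concentrating the
  heterozygote deficit at the most polymorphic loci as the published
  FIS pattern implies; visible/null heterozygotes present as visible
  homozygotes, null homozygotes as missing.  The resulting multilocus
  FIS is 0.19-0.26 per site;
* dropout: 1% of genotypes at random, applied last.

All randomness flows from one seed; the same configuration reproduces
the same dataset bit for bit.

## What the generator does and does not emulate

It reproduces the sampling design, diversity level, cluster divergence,
kin aggregation, selfing signature, heterozygote deficit, and
missingness of the motivating survey; recovery tests against its truth
records validate every estimator's scale (full-sib relatedness 0.5,
full-sib kinship 0.25, EM null frequencies, pairwise FST against the
Balding-Nichols parameter).

Two caveats.  Dirichlet frequency spectra cannot match both the per-locus
heterozygosities and the tail behaviour of real microsatellite spectra:
shared-homozygote coincidences (two unrelated individuals homozygous for
the same mid-frequency allele at several loci, a tail fattened by null
masking) push more unrelated pairs above kinship 0.36 than real data
show.  The within-locality concentration of extreme-kinship pairs is
therefore asserted as a pooled-over-replicates enrichment (fraction at
least 0.75, against a random expectation of about one third) rather than
as a near-total exclusivity.  Second, the generator places sib clutches
strictly within perchas (at most one per percha); it deliberately does
not model larval advection or distinguish "cohesive dispersal" from
"occasional limited dispersal" — both hypotheses produce within-percha
kin excess, and the generator's knobs (clutch rate, clutch size) emulate
the pattern without claiming either mechanism.

# Numerical and testing choices

Permutation and simulation p-values always use the +1 correction.
Replicate counts default to the classical 9,999 permutations / 10,000
bootstraps or simulations; the test suite and the acceptance script use
reduced counts (typically 199-2,000) chosen so Monte Carlo error is
small relative to the tolerances being asserted, with problem sizes of
150-1,000 individuals depending on the statistic.  Calibration tests
assert empirical type-I error inside 99% binomial envelopes; where test
statistics within a replicate are dependent (distance classes of one
transect, pairs sharing individuals) the envelope is widened or the test
restricted to disjoint pairs, as noted in the test code.  Degenerate
inputs (monomorphic loci, strata with no typed individuals, groups below
minimum size, single-locus bootstraps) are skipped with a recorded
reason, never errors.
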