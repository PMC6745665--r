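#' Pairwise Loiselle kinship coefficient matrix
#'
#' A correlation-type kinship estimator referenced to a set of allele
#' frequencies (by default the full dataset, so values are comparable
#' across localities).  Writing `x_ia` for individual i's frequency of
#' allele a (0, 0.5, 1) and `p_a` for the reference frequency, the
#' per-locus numerator is
#' `sum_a (x_ia - p_a)(x_ja - p_a) + sum_a p_a (1 - p_a) / (n_g - 1)`
#' with `n_g = 2 N_typed` gene copies (the second term is the small-sample
#' correction that centres the estimator near zero for random pairs), and
#' the denominator is `sum_a p_a (1 - p_a)`.  The multilocus coefficient
#' is the ratio of numerator and denominator sums over the pair's mutually
#' typed polymorphic loci, which weights loci by their polymorphism.
#' Expected values are about 0.25 for full sibs and 0.5 for identical
#' genotypes.
#'
#' @param table a [genotab()].
#' @param freqs a `freq_table`; `NULL` computes global frequencies from
#'   `table`.
#' @param stratum stratum of `freqs` to use.
#' @param min_shared_loci minimum mutually typed polymorphic loci.
#' @return symmetric matrix of kinship coefficients (`NA` diagonal and
#'   masked pairs).
#' @export
loiselle_kinship_matrix <- function(table, freqs = NULL, stratum = 1L,
                                    min_shared_loci = 5) {
  stopifnot(inherits(table, "genotab"))
  if (is.null(freqs)) freqs <- allele_frequencies(table, NULL, "global")
  st <- freqs$strata[[stratum]]
  n <- length(table$ind)
  px <- pair_indices(n)
  num <- den <- numeric(length(px$i))
  shared <- integer(length(px$i))
  for (l in seq_along(table$loci)) {
    loc <- table$loci[l]
    a <- table$a[, l]; b <- table$b[, l]
    obs <- unique(c(a, b)); obs <- obs[!is.na(obs)]
    if (!length(obs)) next
    p <- locus_freq_lookup(st$freq[[loc]], st$n_typed[[loc]],
                           as.character(obs))
    s2 <- sum(p^2)
    denom_l <- 1 - s2                      # sum p (1 - p)
    if (denom_l <= 1e-12) next             # monomorphic locus excluded
    corr_l <- denom_l / (2 * st$n_typed[[loc]] - 1)
    # s_i = sum_a x_ia p_a = (p_a + p_b) / 2
    si <- (unname(p[as.character(a)]) + unname(p[as.character(b)])) / 2
    a1 <- a[px$i]; b1 <- b[px$i]; a2 <- a[px$j]; b2 <- b[px$j]
    ok <- !is.na(a1) & !is.na(a2)
    if (!any(ok)) next
    # sum_a x_ia x_ja = matches / 4 over the four allele comparisons
    xx <- ((a1 == a2) + (a1 == b2) + (b1 == a2) + (b1 == b2)) / 4
    num_l <- xx - si[px$i] - si[px$j] + s2 + corr_l
    num[ok] <- num[ok] + num_l[ok]
    den[ok] <- den[ok] + denom_l
    shared[ok] <- shared[ok] + 1L
  }
  f <- ifelse(den > 0 & shared >= min_shared_loci, num / den, NA_real_)
  out <- matrix(NA_real_, n, n, dimnames = list(table$ind, table$ind))
  out[cbind(px$i, px$j)] <- f
  out[cbind(px$j, px$i)] <- f
  out
}

#' Loiselle kinship profile: within- versus among-locality distributions
#'
#' Computes the pairwise Loiselle kinship matrix against full-dataset
#' allele frequencies, bins the coefficients into half-open intervals
#' `[x, x + bin_width)`, splits each bin into within-locality and
#' among-locality pairs, and lists "extreme" pairs whose coefficient
#' exceeds `extreme_threshold` together with their hierarchy context.
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()].
#' @param bin_width histogram bin width.
#' @param extreme_threshold kinship value above which a pair is listed.
#' @param min_shared_loci passed to [loiselle_kinship_matrix()].
#' @return list of class `kinship_profile`: `kinship` (the matrix),
#'   `histogram` (data.frame bin_lo, n_within, n_among, prop_within,
#'   prop_among), `extremes` (data.frame of flagged pairs), and `range`
#'   (within/among min-max).
#' @export
loiselle_kinship_profile <- function(table, hier, bin_width = 0.01,
                                     extreme_threshold = 0.36,
                                     min_shared_loci = 5) {
  hier <- align_hierarchy(table, hier)
  K <- loiselle_kinship_matrix(table, min_shared_loci = min_shared_loci)
  n <- nrow(K)
  px <- pair_indices(n)
  f <- K[cbind(px$i, px$j)]
  same_loc <- hier$locality[px$i] == hier$locality[px$j]
  okv <- !is.na(f)
  fw <- f[okv & same_loc]; fa <- f[okv & !same_loc]
  lo <- floor(min(f[okv]) / bin_width) * bin_width
  hi <- max(f[okv])
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  binify <- function(v) findInterval(v, breaks, rightmost.closed = FALSE)
  tw <- tabulate(binify(fw), nbins = length(breaks) - 1)
  ta <- tabulate(binify(fa), nbins = length(breaks) - 1)
  total <- sum(tw) + sum(ta)
  hist <- data.frame(bin_lo = breaks[-length(breaks)],
                     n_within = tw, n_among = ta,
                     prop_within = tw / total, prop_among = ta / total)
  ext <- which(okv & f > extreme_threshold)
  extremes <- data.frame(
    id1 = rownames(K)[px$i[ext]], id2 = rownames(K)[px$j[ext]],
    kinship = f[ext],
    locality1 = hier$locality[px$i[ext]],
    locality2 = hier$locality[px$j[ext]],
    same_locality = same_loc[ext],
    same_percha = same_loc[ext] &
      hier$transect[px$i[ext]] == hier$transect[px$j[ext]] &
      hier$point_m[px$i[ext]] == hier$point_m[px$j[ext]] &
      hier$percha[px$i[ext]] == hier$percha[px$j[ext]])
  structure(list(kinship = K, histogram = hist, extremes = extremes,
                 range = list(within = range(fw), among = range(fa)),
                 bin_width = bin_width,
                 extreme_threshold = extreme_threshold),
            class = "kinship_profile")
}
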