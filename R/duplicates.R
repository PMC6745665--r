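#' Scan for identical and near-identical multilocus genotypes
#'
#' Compares every pair of individuals over their mutually typed loci and
#' reports pairs with identical multilocus genotypes and pairs differing
#' at exactly one locus — the signature expected from selfing or clonal
#' replication.  Pairs typed at fewer than `min_shared_loci` mutual loci
#' are excluded.  For interpretation, the expected number of identical
#' unrelated (and full-sib) pairs is computed from the probabilities of
#' identity over the full dataset.
#'
#' @param table a [genotab()].
#' @param hier optional [hierarchy()] adding sampling context to each
#'   reported pair.
#' @param min_shared_loci minimum mutually typed loci.
#' @return list of class `duplicate_report` with `identical` and
#'   `one_mismatch` data.frames (id1, id2, shared_loci, n_mismatch, and
#'   hierarchy context when available), and `expected`: expected counts
#'   of identical pairs among unrelated pairs (`PI`-based) and among
#'   full-sib pairs (`PIsibs`-based) for the observed number of pairs.
#' @export
duplicate_genotype_scan <- function(table, hier = NULL,
                                    min_shared_loci = 8) {
  stopifnot(inherits(table, "genotab"))
  n <- length(table$ind)
  px <- pair_indices(n)
  mism <- integer(length(px$i))
  shared <- integer(length(px$i))
  for (l in seq_along(table$loci)) {
    a1 <- table$a[px$i, l]; b1 <- table$b[px$i, l]
    a2 <- table$a[px$j, l]; b2 <- table$b[px$j, l]
    ok <- !is.na(a1) & !is.na(a2)
    same <- ok & a1 == a2 & b1 == b2
    shared[ok] <- shared[ok] + 1L
    mism[ok & !same] <- mism[ok & !same] + 1L
  }
  eligible <- shared >= min_shared_loci
  mk <- function(w) {
    d <- data.frame(id1 = table$ind[px$i[w]], id2 = table$ind[px$j[w]],
                    shared_loci = shared[w], n_mismatch = mism[w])
    if (!is.null(hier)) {
      h <- hier[match(d$id1, hier$individual), ]
      h2 <- hier[match(d$id2, hier$individual), ]
      d$locality1 <- h$locality; d$locality2 <- h2$locality
      d$same_percha <- h$locality == h2$locality &
        h$transect == h2$transect & h$point_m == h2$point_m &
        h$percha == h2$percha
    }
    d
  }
  pio <- probability_of_identity(allele_frequencies(table, NULL, "global"))
  n_pairs <- sum(eligible)
  structure(list(
    identical = mk(which(eligible & mism == 0L)),
    one_mismatch = mk(which(eligible & mism == 1L)),
    expected = list(identical_if_unrelated = n_pairs * pio$PI,
                    identical_if_sibs = n_pairs * pio$PIsibs,
                    PI = pio$PI, PIsibs = pio$PIsibs),
    n_pairs_compared = n_pairs), class = "duplicate_report")
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat("duplicate scan over", x$n_pairs_compared, "pairs\n")
  cat("identical multilocus genotypes:", nrow(x$identical), "pair(s)\n")
  cat("one-locus mismatches:", nrow(x$one_mismatch), "pair(s)\n")
  cat(sprintf("expected identical unrelated pairs: %.3g (PI = %.3g)\n",
              x$expected$identical_if_unrelated, x$expected$PI))
  invisible(x)
}
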