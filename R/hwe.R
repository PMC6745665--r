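#' Exact Hardy-Weinberg tests by Markov chain Monte Carlo
#'
#' For each stratum x locus, runs the Guo-Thompson Markov chain over
#' genotype tables with the observed allele counts held fixed.  Two
#' p-values are reported: the two-sided exact p (chain frequency of tables
#' no more probable than the observed one) and a one-sided heterozygote-
#' deficit p (chain frequency of tables with no more heterozygotes than
#' observed).  The batch structure of the chain yields a Monte Carlo
#' standard error on each p.  Loci with fewer than two alleles or fewer
#' than `min_n` typed individuals in a stratum are skipped with a reason.
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()]; `NULL` with `level = "global"`.
#' @param level stratification level.
#' @param mc list of chain parameters: `dememorization`, `batches`,
#'   `iters_per_batch`.
#' @param min_n minimum typed individuals per stratum x locus.
#' @param seed RNG seed.
#' @param adjust apply Benjamini-Hochberg FDR across the tested
#'   stratum x locus family (on the deficit-side p, which is the headline
#'   test for heterozygote deficiency).
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with columns `stratum`, `locus`, `n`, `k`, `p_two`,
#'   `p_deficit`, `se`, `p_adj`, `significant`, `skipped`, `reason`.
#' @export
hwe_test_mc <- function(table, hier = NULL,
                        level = c("site", "locality", "global"),
                        mc = list(dememorization = 1000, batches = 100,
                                  iters_per_batch = 1000),
                        min_n = 5, seed = NULL, adjust = TRUE,
                        alpha = 0.05) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  lab <- if (level == "global") rep("all", length(table$ind))
         else stratum_labels(align_hierarchy(table, hier), level)
  out <- list()
  for (s in unique(lab)) {
    idx <- which(lab == s)
    for (l in seq_along(table$loci)) {
      a <- table$a[idx, l]; b <- table$b[idx, l]
      typed <- !is.na(a)
      a <- a[typed]; b <- b[typed]
      alleles <- sort(unique(c(a, b)))
      row <- data.frame(stratum = s, locus = table$loci[l],
                        n = length(a), k = length(alleles),
                        p_two = NA_real_, p_deficit = NA_real_,
                        se = NA_real_, skipped = TRUE, reason = "")
      if (length(a) < min_n) {
        row$reason <- "too few typed individuals"
      } else if (length(alleles) < 2) {
        row$reason <- "monomorphic"
      } else {
        res <- hwe_chain_cpp(match(a, alleles) - 1L, match(b, alleles) - 1L,
                             length(alleles),
                             mc$dememorization, mc$batches,
                             mc$iters_per_batch)
        row$p_two <- res$p_two
        row$p_deficit <- res$p_deficit
        row$se <- res$se_deficit
        row$skipped <- FALSE
      }
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  out$p_adj <- NA_real_
  if (adjust) {
    tested <- !out$skipped
    out$p_adj[tested] <- bh_fdr(out$p_deficit[tested])
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  out
}

#' Exact Hardy-Weinberg enumeration for two alleles
#'
#' Full enumeration of the conditional distribution of heterozygote counts
#' given the allele counts, for a biallelic locus.  Used as an independent
#' oracle for the Markov-chain test on small samples.
#'
#' @param n11,n12,n22 observed genotype counts.
#' @return list with `p_two` (two-sided exact p) and `p_deficit`
#'   (probability of a table with heterozygote count `<=` observed).
#' @export
hwe_exact_biallelic <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  n1 <- 2 * n11 + n12  # copies of allele 1
  hvals <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  logp <- vapply(hvals, function(h) {
    x11 <- (n1 - h) / 2; x22 <- n - x11 - h
    h * log(2) + lgamma(n + 1) - lgamma(x11 + 1) - lgamma(h + 1) -
      lgamma(x22 + 1)
  }, 0)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- match(n12, hvals)
  eps <- 1e-12
  list(p_two = sum(p[p <= p[obs] * (1 + eps)]),
       p_deficit = sum(p[hvals <= n12]))
}
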