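#' Genotypic linkage disequilibrium permutation tests
#'
#' For every stratum x locus pair, tests genotypic association with a
#' log-likelihood-ratio (G) statistic on the two-locus genotype
#' contingency table, with significance from permutations that shuffle one
#' locus's genotypes among the individuals typed at both loci.  Pairs with
#' a monomorphic member or fewer than `min_n` shared typed individuals are
#' skipped.
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()]; `NULL` with `level = "global"`.
#' @param level stratification level.
#' @param n_perm number of permutations; the attained p has resolution
#'   `1 / (n_perm + 1)`.
#' @param min_n minimum shared typed individuals.
#' @param seed RNG seed.
#' @param adjust apply Benjamini-Hochberg FDR across the tested family.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with columns `stratum`, `locus1`, `locus2`, `n`,
#'   `G`, `p`, `p_adj`, `significant`, `skipped`, `reason`.
#' @export
genotypic_ld_mc <- function(table, hier = NULL,
                            level = c("site", "locality", "global"),
                            n_perm = 999, min_n = 5, seed = NULL,
                            adjust = TRUE, alpha = 0.05) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  lab <- if (level == "global") rep("all", length(table$ind))
         else stratum_labels(align_hierarchy(table, hier), level)
  L <- length(table$loci)
  out <- list()
  for (s in unique(lab)) {
    idx <- which(lab == s)
    geno <- lapply(seq_len(L), function(l)
      ifelse(is.na(table$a[idx, l]), NA,
             paste(table$a[idx, l], table$b[idx, l], sep = "/")))
    for (l1 in seq_len(L - 1)) for (l2 in seq((l1 + 1), L)) {
      shared <- !is.na(geno[[l1]]) & !is.na(geno[[l2]])
      g1 <- factor(geno[[l1]][shared]); g2 <- factor(geno[[l2]][shared])
      row <- data.frame(stratum = s, locus1 = table$loci[l1],
                        locus2 = table$loci[l2], n = sum(shared),
                        G = NA_real_, p = NA_real_,
                        skipped = TRUE, reason = "")
      if (sum(shared) < min_n) {
        row$reason <- "too few shared typed individuals"
      } else if (nlevels(g1) < 2 || nlevels(g2) < 2) {
        row$reason <- "monomorphic genotype column"
      } else {
        g_obs <- g_statistic(g1, g2)
        g_null <- vapply(seq_len(n_perm), function(i)
          g_statistic(g1[sample.int(length(g1))], g2), 0)
        row$G <- g_obs
        row$p <- (1 + sum(g_null >= g_obs - 1e-12)) / (n_perm + 1)
        row$skipped <- FALSE
      }
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  out$p_adj <- NA_real_
  if (adjust) {
    tested <- !out$skipped
    out$p_adj[tested] <- bh_fdr(out$p[tested])
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  out
}

# log-likelihood-ratio statistic of a two-way genotype contingency table
g_statistic <- function(g1, g2) {
  tab <- table(g1, g2)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  nz <- tab > 0
  2 * sum(tab[nz] * log(tab[nz] / e[nz]))
}
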