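# ---- internal AMOVA machinery -------------------------------------------
# Codominant AMOVA treats the two allele copies within an individual as the
# lowest level.  Sums of squares for a set of allele copies with type
# counts n_a (n copies total) follow the pairwise-difference identity
# SS = (n - sum(n_a^2) / n) / 2, with squared distance 1 between distinct
# alleles.  SS are summed over loci; missing genotypes drop out per locus.

ss_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  (n - sum(counts^2) / n) / 2
}

# per-locus integer codes (1..k) for typed individuals
locus_codes <- function(table, l) {
  a <- table$a[, l]; b <- table$b[, l]
  typed <- which(!is.na(a))
  alleles <- sort(unique(c(a[typed], b[typed])))
  list(idx = typed, k = length(alleles),
       ai = match(a[typed], alleles), bi = match(b[typed], alleles))
}

# SS decomposition for one locus given population assignment (int 1..P)
amova_locus_ss <- function(lc, pop, P) {
  ai <- lc$ai; bi <- lc$bi; k <- lc$k
  p <- pop[lc$idx]
  n <- length(ai)
  all_counts <- tabulate(c(ai, bi), nbins = k)
  ss_total <- ss_counts(all_counts)
  ss_wi <- 0.5 * sum(ai != bi)
  comp <- tabulate(c((p - 1L) * k + ai, (p - 1L) * k + bi), nbins = P * k)
  m <- matrix(comp, nrow = k)
  csum <- colSums(m)
  ss_pop <- sum(ifelse(csum > 0, (csum - colSums(m^2) / pmax(csum, 1)) / 2, 0))
  c(ss_ap = ss_total - ss_pop, ss_ai = ss_pop - ss_wi, ss_wi = ss_wi)
}

# variance components from SS summed over loci, with the multilocus df
# convention of distance-based codominant AMOVA: among pops P - 1, among
# individuals N - P, within individuals N (N = individuals analysed;
# per-locus missing genotypes drop out of the SS only)
amova_components <- function(ssmat, pop, P) {
  ss <- colSums(ssmat)
  N <- length(pop)
  df <- c(P - 1, N - P, N)
  ms <- ss / df
  cp <- 2 * tabulate(pop, nbins = P)  # allele copies per population
  n0 <- (sum(cp) - sum(cp^2) / sum(cp)) / (P - 1)
  vc <- ms[3]
  vb <- (ms[2] - vc) / 2
  va <- (ms[1] - ms[2]) / n0
  list(df = df, SS = unname(ss), MS = unname(ms), var = c(va, vb, vc))
}

amova_fstats <- function(v, truncate = TRUE) {
  if (truncate) v <- pmax(v, 0)
  tot <- sum(v)
  c(FST = if (tot > 0) v[[1]] / tot else 0,
    FIS = if (v[[2]] + v[[3]] > 0) v[[2]] / (v[[2]] + v[[3]]) else 0,
    FIT = if (tot > 0) (v[[1]] + v[[2]]) / tot else 0)
}

#' Analysis of molecular variance (AMOVA) for codominant genotypes
#'
#' Partitions genetic variance among populations, among individuals within
#' populations, and within individuals, treating the two allele copies of
#' an individual as the lowest level.  Negative variance components are
#' truncated to zero before computing percentages and F-statistics.
#' Permutation p-values: individuals are permuted among populations for
#' FST, allele copies among individuals within populations for FIS, and
#' allele copies among all individuals for FIT.
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()].
#' @param level populations are `"site"` (transects) or `"locality"`.
#' @param n_perm permutations per F-statistic.
#' @param seed RNG seed.
#' @return list of class `amova` with `components` (data.frame: source,
#'   df, SS, MS, var_comp, pct) and `fstats` (data.frame: statistic,
#'   value, p).
#' @export
amova <- function(table, hier, level = c("site", "locality"),
                  n_perm = 9999, seed = NULL) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  hier <- align_hierarchy(table, hier)
  pop_lab <- stratum_labels(hier, level)
  keep <- pop_lab %in% names(which(table(pop_lab) >= 2))
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " individual(s) in populations of size 1")
    table <- table[keep, ]; pop_lab <- pop_lab[keep]
  }
  pop <- as.integer(factor(pop_lab))
  P <- max(pop)
  if (P < 2) stop("AMOVA needs at least two populations")
  L <- length(table$loci)
  lcs <- lapply(seq_len(L), locus_codes, table = table)
  lcs <- lcs[vapply(lcs, function(x) length(x$idx) > 0, TRUE)]

  obs_ss <- do.call(rbind, lapply(lcs, amova_locus_ss, pop = pop, P = P))
  comp <- amova_components(obs_ss, pop, P)
  fs <- amova_fstats(comp$var)

  # permutation nulls
  n <- length(table$ind)
  fst_null <- fis_null <- fit_null <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    perm_pop <- pop[sample.int(n)]
    ssm <- do.call(rbind, lapply(lcs, amova_locus_ss, pop = perm_pop, P = P))
    fst_null[r] <- amova_fstats(amova_components(ssm, perm_pop, P)$var)[["FST"]]
  }
  for (r in seq_len(n_perm)) {
    ssm <- do.call(rbind, lapply(lcs, function(lc)
      amova_locus_ss(shuffle_within_pop(lc, pop), pop, P)))
    fis_null[r] <- amova_fstats(amova_components(ssm, pop, P)$var)[["FIS"]]
  }
  for (r in seq_len(n_perm)) {
    ssm <- do.call(rbind, lapply(lcs, function(lc)
      amova_locus_ss(shuffle_all(lc), pop, P)))
    fit_null[r] <- amova_fstats(amova_components(ssm, pop, P)$var)[["FIT"]]
  }
  pval <- function(null, obs) (1 + sum(null >= obs - 1e-12)) / (n_perm + 1)

  vtr <- pmax(comp$var, 0)
  structure(list(
    components = data.frame(
      source = c("Among Pops", "Among Indiv", "Within Indiv"),
      df = comp$df, SS = comp$SS, MS = comp$MS,
      var_comp = vtr, pct = 100 * vtr / sum(vtr)),
    fstats = data.frame(
      statistic = c("FST", "FIS", "FIT"),
      value = unname(fs),
      p = c(pval(fst_null, fs[["FST"]]), pval(fis_null, fs[["FIS"]]),
            pval(fit_null, fs[["FIT"]]))),
    n_perm = n_perm, level = level), class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat("Codominant AMOVA (", x$n_perm, " permutations)\n", sep = "")
  print(x$components, row.names = FALSE, digits = 4)
  print(x$fstats, row.names = FALSE, digits = 4)
  invisible(x)
}

# repair allele copies among individuals within each population (per locus)
shuffle_within_pop <- function(lc, pop) {
  p <- pop[lc$idx]
  ai <- lc$ai; bi <- lc$bi
  for (g in unique(p)) {
    w <- which(p == g)
    copies <- sample(c(ai[w], bi[w]))
    ai[w] <- copies[seq_along(w)]
    bi[w] <- copies[seq_along(w) + length(w)]
  }
  list(idx = lc$idx, k = lc$k, ai = ai, bi = bi)
}

shuffle_all <- function(lc) {
  nn <- length(lc$ai)
  copies <- sample(c(lc$ai, lc$bi))
  list(idx = lc$idx, k = lc$k, ai = copies[seq_len(nn)],
       bi = copies[seq_len(nn) + nn])
}

#' Pairwise FST between sites with permutation significance
#'
#' Each site pair's FST comes from a two-population codominant [amova()];
#' the p-value is the fraction of permutations (individuals shuffled
#' between the two sites) with FST at least as large, with the +1
#' correction, so the minimum attainable p is `1 / (n_perm + 1)`.
#' Benjamini-Hochberg FDR is applied across all pairs.
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()].
#' @param level `"site"` or `"locality"`.
#' @param n_perm permutations per pair.
#' @param seed RNG seed.
#' @param fdr apply BH-FDR across pairs.
#' @param alpha significance level.
#' @return list of class `pairwise_fst` with symmetric matrices `fst`,
#'   `p`, `p_adj`, logical `significant`, and `method = "amova_permutation"`.
#' @export
pairwise_fst_permutation <- function(table, hier,
                                     level = c("site", "locality"),
                                     n_perm = 9999, seed = NULL,
                                     fdr = TRUE, alpha = 0.05) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  hier <- align_hierarchy(table, hier)
  lab <- stratum_labels(hier, level)
  pops <- sort(unique(lab))
  P <- length(pops)
  if (P < 2) stop("need at least two sites")
  fst <- p <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  diag(fst) <- 0; diag(p) <- NA
  L <- length(table$loci)
  for (i in seq_len(P - 1)) for (j in seq((i + 1), P)) {
    sel <- lab %in% pops[c(i, j)]
    sub <- table[sel, ]
    pop <- as.integer(factor(lab[sel], levels = pops[c(i, j)]))
    lcs <- lapply(seq_len(L), locus_codes, table = sub)
    lcs <- lcs[vapply(lcs, function(x) length(x$idx) > 0, TRUE)]
    obs <- amova_fstats(amova_components(
      do.call(rbind, lapply(lcs, amova_locus_ss, pop = pop, P = 2L)),
      pop, 2L)$var)[["FST"]]
    nsub <- length(sub$ind)
    null <- vapply(seq_len(n_perm), function(r) {
      pp <- pop[sample.int(nsub)]
      amova_fstats(amova_components(
        do.call(rbind, lapply(lcs, amova_locus_ss, pop = pp, P = 2L)),
        pp, 2L)$var)[["FST"]]
    }, 0)
    fst[i, j] <- fst[j, i] <- obs
    p[i, j] <- p[j, i] <- (1 + sum(null >= obs - 1e-12)) / (n_perm + 1)
  }
  p_adj <- p
  if (fdr) {
    ut <- upper.tri(p)
    p_adj[ut] <- bh_fdr(p[ut])
    p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  }
  structure(list(fst = fst, p = p, p_adj = p_adj,
                 significant = !is.na(p_adj) & p_adj <= alpha,
                 method = "amova_permutation", n_perm = n_perm),
            class = "pairwise_fst")
}

# ---- Weir-Cockerham FST with optional ENA null-allele correction --------

# per-locus WC components for two or more pops.
# freq: list per pop of named allele freq vectors (may sum to < 1 when a
# null-allele class is present); hom excluded ENA-style by summing visible
# alleles only.  het: list per pop of per-allele observed (or expected)
# heterozygote frequencies; n: typed individuals per pop.
wc_locus_components <- function(freq, het, n) {
  alleles <- unique(unlist(lapply(freq, names)))
  r <- length(freq)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  a_sum <- 0; d_sum <- 0
  for (al in alleles) {
    p_i <- vapply(freq, function(f) if (al %in% names(f)) f[[al]] else 0, 0)
    h_i <- vapply(het, function(h) if (al %in% names(h)) h[[al]] else 0, 0)
    pbar <- sum(n * p_i) / sum(n)
    s2 <- sum(n * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h_i) / sum(n)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    d_sum <- d_sum + a + b + cc
  }
  c(a = a_sum, d = d_sum)
}

# observed per-allele het frequencies and freqs for a site x locus sample
site_locus_obs <- function(a, b) {
  alleles <- sort(unique(c(a, b)))
  n <- length(a)
  p <- vapply(alleles, function(x) sum(a == x) + sum(b == x), 0) / (2 * n)
  h <- vapply(alleles, function(x) mean((a == x) != (b == x)), 0)
  list(freq = stats::setNames(p, alleles), het = stats::setNames(h, alleles),
       n = n)
}

#' Pairwise Weir-Cockerham FST with ENA null-allele correction
#'
#' Computes multilocus Weir-Cockerham theta for every site pair.  With
#' `correct = TRUE` (the ENA approach), allele frequencies per site x locus
#' are re-estimated by the null-allele EM ([null_allele_em()] model), the
#' null class is excluded from the summation over alleles, and per-allele
#' heterozygosities are taken at their Hardy-Weinberg expectation given the
#' corrected frequencies.  95% confidence intervals come from
#' bootstrapping loci; a pair is flagged significant when its CI excludes
#' zero.  With a single locus the CI is undefined and flagged.
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()].
#' @param level `"site"` or `"locality"`.
#' @param n_boot bootstrap replicates over loci.
#' @param seed RNG seed.
#' @param correct apply the ENA correction (`FALSE` gives the uncorrected
#'   Weir-Cockerham estimate from observed frequencies).
#' @return list of class `pairwise_fst` with matrices `fst`, `ci_lo`,
#'   `ci_hi`, logical `significant`, and `method = "wc_ena"` (or
#'   `"wc"`).
#' @export
ena_corrected_fst <- function(table, hier, level = c("site", "locality"),
                              n_boot = 10000, seed = NULL, correct = TRUE) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  hier <- align_hierarchy(table, hier)
  lab <- stratum_labels(hier, level)
  pops <- sort(unique(lab))
  P <- length(pops); L <- length(table$loci)
  if (P < 2) stop("need at least two sites")

  # per site x locus: frequency and het summaries (corrected or observed)
  summ <- vector("list", P)
  for (i in seq_len(P)) {
    idx <- which(lab == pops[i])
    summ[[i]] <- lapply(seq_len(L), function(l) {
      a <- table$a[idx, l]; b <- table$b[idx, l]
      typed <- !is.na(a); a <- a[typed]; b <- b[typed]
      if (!length(a)) return(NULL)
      if (!correct) return(site_locus_obs(a, b))
      fit <- em_null_locus(a, b)
      q <- fit$p_visible
      if (is.null(q)) {  # monomorphic: no null signal estimable
        obs <- site_locus_obs(a, b)
        return(list(freq = obs$freq, het = obs$het, n = length(a)))
      }
      list(freq = q, het = stats::setNames(2 * q * (1 - q), names(q)),
           n = length(a))
    })
  }

  fst <- ci_lo <- ci_hi <- matrix(NA_real_, P, P,
                                  dimnames = list(pops, pops))
  diag(fst) <- 0
  sig <- matrix(FALSE, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) for (j in seq((i + 1), P)) {
    comp <- t(vapply(seq_len(L), function(l) {
      si <- summ[[i]][[l]]; sj <- summ[[j]][[l]]
      if (is.null(si) || is.null(sj) || (si$n < 2 && sj$n < 2))
        return(c(a = NA_real_, d = NA_real_))
      wc_locus_components(list(si$freq, sj$freq), list(si$het, sj$het),
                          c(si$n, sj$n))
    }, c(a = 0, d = 0)))
    ok <- stats::complete.cases(comp)
    comp <- comp[ok, , drop = FALSE]
    theta <- sum(comp[, "a"]) / sum(comp[, "d"])
    fst[i, j] <- fst[j, i] <- theta
    if (nrow(comp) >= 2) {
      bt <- vapply(seq_len(n_boot), function(r) {
        pick <- sample.int(nrow(comp), replace = TRUE)
        sum(comp[pick, "a"]) / sum(comp[pick, "d"])
      }, 0)
      qs <- stats::quantile(bt, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      ci_lo[i, j] <- ci_lo[j, i] <- qs[1]
      ci_hi[i, j] <- ci_hi[j, i] <- qs[2]
      sig[i, j] <- sig[j, i] <- qs[1] > 0 || qs[2] < 0
    }
  }
  structure(list(fst = fst, ci_lo = ci_lo, ci_hi = ci_hi,
                 significant = sig,
                 method = if (correct) "wc_ena" else "wc",
                 n_boot = n_boot),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("Pairwise FST (", x$method, ")\n", sep = "")
  print(round(x$fst, 4))
  invisible(x)
}
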