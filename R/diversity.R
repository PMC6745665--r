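#' Per-stratum allele frequencies
#'
#' Frequencies are computed from observed (non-missing) allele counts;
#' missing genotypes are excluded from the denominators.  A stratum x locus
#' combination with no typed individual yields an empty frequency map with
#' `n_typed = 0`.
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()]; may be `NULL` when `level = "global"`.
#' @param level stratification: `"site"` (transect), `"locality"`, or
#'   `"global"`.
#' @return an object of class `freq_table`: a list with `level`, `loci`,
#'   and `strata` — for each stratum a list with `freq` (per-locus named
#'   frequency vectors, names are allele sizes) and `n_typed` (per-locus
#'   count of typed individuals).
#' @export
allele_frequencies <- function(table, hier = NULL,
                               level = c("site", "locality", "global")) {
  level <- match.arg(level)
  stopifnot(inherits(table, "genotab"))
  lab <- if (level == "global") rep("all", length(table$ind))
         else stratum_labels(align_hierarchy(table, hier), level)
  strata <- lapply(split(seq_along(table$ind), lab), function(idx) {
    freq <- vector("list", length(table$loci))
    names(freq) <- table$loci
    n_typed <- integer(length(table$loci))
    names(n_typed) <- table$loci
    for (l in seq_along(table$loci)) {
      al <- c(table$a[idx, l], table$b[idx, l])
      al <- al[!is.na(al)]
      n_typed[l] <- length(al) %/% 2L
      freq[[l]] <- if (length(al)) {
        tb <- table(al)
        stats::setNames(as.numeric(tb) / length(al), names(tb))
      } else numeric(0)
    }
    list(freq = freq, n_typed = n_typed)
  })
  structure(list(level = level, loci = table$loci, strata = strata),
            class = "freq_table")
}

#' Diversity summary per site and locus
#'
#' For every site (transect) and locus: `N` typed individuals, `Na` allele
#' count, observed heterozygosity `Ho`, unbiased expected heterozygosity
#' `uHe = (2N / (2N - 1)) * (1 - sum(p^2))`, and the inbreeding coefficient
#' `FIS = 1 - Ho / uHe` (`NA` when `uHe = 0`).  A `multilocus` block holds
#' per-site means across loci, and `private` counts alleles observed in
#' exactly one site (PAP).
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()].
#' @param fis one of `"ratio"` (default, `1 - Ho/uHe`) or `"wc"`
#'   (Weir-Cockerham per-locus f from the two-level variance components,
#'   exposed for cross-tool comparison).
#' @return list of class `diversity_summary` with data.frames `per_locus`,
#'   `multilocus`, and `private`.
#' @export
diversity_summary <- function(table, hier, fis = c("ratio", "wc")) {
  fis <- match.arg(fis)
  stopifnot(inherits(table, "genotab"))
  hier <- align_hierarchy(table, hier)
  sites <- stratum_labels(hier, "site")
  ft <- allele_frequencies(table, hier, "site")
  per <- list()
  for (s in names(ft$strata)) {
    idx <- which(sites == s)
    st <- ft$strata[[s]]
    for (l in seq_along(table$loci)) {
      N <- st$n_typed[l]
      if (N == 0) {
        per[[length(per) + 1L]] <- data.frame(
          site = s, locus = table$loci[l], N = 0L, Na = 0L,
          Ho = NA_real_, uHe = NA_real_, FIS = NA_real_)
        next
      }
      p <- st$freq[[l]]
      a <- table$a[idx, l]; b <- table$b[idx, l]
      typed <- !is.na(a)
      ho <- mean(a[typed] != b[typed])
      uhe <- (2 * N / (2 * N - 1)) * (1 - sum(p^2))
      f <- if (fis == "ratio") {
        if (uhe > 0) 1 - ho / uhe else NA_real_
      } else {
        wc_f_locus(a[typed], b[typed])
      }
      per[[length(per) + 1L]] <- data.frame(
        site = s, locus = table$loci[l], N = N, Na = length(p),
        Ho = ho, uHe = uhe, FIS = f)
    }
  }
  per <- do.call(rbind, per)
  multi <- do.call(rbind, lapply(split(per, per$site), function(d) {
    data.frame(site = d$site[1], N = mean(d$N), Na = mean(d$Na),
               Ho = mean(d$Ho, na.rm = TRUE),
               uHe = mean(d$uHe, na.rm = TRUE),
               FIS = mean(d$FIS, na.rm = TRUE))
  }))
  rownames(multi) <- NULL

  # private alleles: present in exactly one site (counted over site x locus)
  pap <- stats::setNames(integer(length(ft$strata)), names(ft$strata))
  for (l in seq_along(table$loci)) {
    where <- lapply(ft$strata, function(st) names(st$freq[[l]]))
    all_alleles <- unlist(where, use.names = FALSE)
    priv <- names(which(table(all_alleles) == 1))
    for (s in names(where))
      pap[s] <- pap[s] + sum(where[[s]] %in% priv)
  }
  structure(list(per_locus = per, multilocus = multi,
                 private = data.frame(site = names(pap), PAP = as.integer(pap),
                                      row.names = NULL)),
            class = "diversity_summary")
}

# Weir-Cockerham per-locus f (FIS) for a single sample: 1 - c/(b + c)
# with b, c the within-population variance components summed over alleles
wc_f_locus <- function(a, b) {
  n <- length(a)
  if (n < 2) return(NA_real_)
  p <- table(c(a, b)) / (2 * n)
  bsum <- 0; csum <- 0
  for (x in names(p)) {
    pa <- as.numeric(p[x])
    h <- mean((a == x) != (b == x))  # observed het frequency for allele x
    bsum <- bsum + n / (n - 1) * (pa * (1 - pa) - (2 * n - 1) / (4 * n) * h)
    csum <- csum + h / 2
  }
  if (bsum + csum <= 0) return(NA_real_)
  1 - csum / (bsum + csum)
}

#' Probability of identity for unrelated and sibling pairs
#'
#' Per locus, with allele frequencies `p_i`:
#' `PI = 2 (sum p_i^2)^2 - sum p_i^4` and
#' `PIsibs = 0.25 + 0.5 sum p_i^2 + 0.5 (sum p_i^2)^2 - 0.25 sum p_i^4`.
#' Multilocus values are products over loci with at least one typed
#' individual; loci with empty frequency maps are excluded.
#'
#' @param freqs a `freq_table` (typically at `level = "global"`).
#' @param stratum which stratum of `freqs` to use (default the first).
#' @return list with `per_locus` (data.frame locus, PI, PIsibs) and
#'   multilocus `PI` and `PIsibs`.
#' @export
probability_of_identity <- function(freqs, stratum = 1L) {
  stopifnot(inherits(freqs, "freq_table"))
  st <- freqs$strata[[stratum]]
  rows <- lapply(names(st$freq), function(l) {
    p <- st$freq[[l]]
    if (!length(p)) return(NULL)
    s2 <- sum(p^2); s4 <- sum(p^4)
    data.frame(locus = l, PI = 2 * s2^2 - s4,
               PIsibs = 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4)
  })
  per <- do.call(rbind, rows)
  list(per_locus = per, PI = prod(per$PI), PIsibs = prod(per$PIsibs))
}

#' Null-allele frequency by expectation-maximisation
#'
#' Fits, per stratum x locus, the model in which a null allele of frequency
#' `b` segregates with the visible alleles under Hardy-Weinberg
#' proportions: a visible/null heterozygote presents as a visible
#' homozygote and a null homozygote as a blank.  Blanks are excluded from
#' the likelihood (they are confounded with experimental dropout), so the
#' observed categories are renormalised by `1 - b^2`; the EM augments the
#' data with the expected number of unobserved null homozygotes.
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()]; `NULL` with `level = "global"`.
#' @param level stratification level, as in [allele_frequencies()].
#' @param tol convergence tolerance on the null-frequency update.
#' @param max_iter maximum EM iterations.
#' @return data.frame with columns `stratum`, `locus`, `null_freq`,
#'   `iterations`, `converged`, `loglik`.
#' @export
null_allele_em <- function(table, hier = NULL,
                           level = c("site", "locality", "global"),
                           tol = 1e-8, max_iter = 10000) {
  level <- match.arg(level)
  lab <- if (level == "global") rep("all", length(table$ind))
         else stratum_labels(align_hierarchy(table, hier), level)
  out <- list()
  for (s in unique(lab)) {
    idx <- which(lab == s)
    for (l in seq_along(table$loci)) {
      a <- table$a[idx, l]; b <- table$b[idx, l]
      typed <- !is.na(a)
      fit <- em_null_locus(a[typed], b[typed], tol = tol,
                           max_iter = max_iter)
      out[[length(out) + 1L]] <- data.frame(
        stratum = s, locus = table$loci[l], null_freq = fit$beta,
        iterations = fit$iter, converged = fit$converged,
        loglik = fit$loglik)
    }
  }
  do.call(rbind, out)
}

# EM for one locus sample (observed genotypes only; a, b complete)
em_null_locus <- function(a, b, tol = 1e-8, max_iter = 10000) {
  n <- length(a)
  if (n == 0) return(list(beta = NA_real_, iter = 0L, converged = FALSE,
                          loglik = NA_real_))
  alleles <- sort(unique(c(a, b)))
  k <- length(alleles)
  ai <- match(a, alleles); bi <- match(b, alleles)
  het <- ai != bi
  hom_counts <- tabulate(ai[!het], nbins = k)        # apparent homozygotes
  het_counts <- tabulate(c(ai[het], bi[het]), nbins = k)  # allele copies in hets
  if (k < 2) return(list(beta = 0, iter = 0L, converged = TRUE,
                         loglik = 0))
  # init: visible freqs from counts, small null freq
  p <- (hom_counts * 2 + het_counts)
  p <- p / sum(p) * 0.95
  beta <- 0.05
  ll_old <- -Inf; conv <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    # expected unobserved null homozygotes given truncation
    m_nn <- n * beta^2 / (1 - beta^2)
    # E-step: split apparent homozygotes aa into true aa vs a/null
    denom <- p^2 + 2 * p * beta
    w_true <- ifelse(denom > 0, p^2 / denom, 0)
    cnt_vis <- het_counts + hom_counts * (2 * w_true + (1 - w_true))
    cnt_null <- sum(hom_counts * (1 - w_true)) + 2 * m_nn
    tot <- sum(cnt_vis) + cnt_null
    p_new <- cnt_vis / tot
    beta_new <- cnt_null / tot
    # observed-data log-likelihood (truncated multinomial)
    ll <- em_null_loglik(p_new, beta_new, het, ai, bi, hom_counts, k)
    delta <- abs(beta_new - beta)
    p <- p_new; beta <- beta_new
    if (delta < tol) { conv <- TRUE; ll_old <- ll; break }
    ll_old <- ll
  }
  list(beta = beta, iter = it, converged = conv, loglik = ll_old,
       p_visible = stats::setNames(p, alleles))
}

em_null_loglik <- function(p, beta, het, ai, bi, hom_counts, k) {
  norm <- 1 - beta^2
  ll <- 0
  if (any(het))
    ll <- ll + sum(log(2 * p[ai[het]] * p[bi[het]] / norm))
  hz <- which(hom_counts > 0)
  if (length(hz))
    ll <- ll + sum(hom_counts[hz] *
                     log((p[hz]^2 + 2 * p[hz] * beta) / norm))
  ll
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
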