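# per-locus likelihood ratio (full-sib vs unrelated), vectorised over
# pairs.  Genotype 1 = (a1, b1), genotype 2 = (a2, b2); p* are reference
# frequencies of the corresponding alleles.  The parental-configuration
# expansion gives
#   P(g2 | g1, FS) = 0.25 P(g2) + 0.5 T1 + 0.25 I(g2 == g1)
# with T1 the one-allele-IBD transition probability, so the ratio to
# P(g2) is independent of P(g1).
sib_lr_locus <- function(a1, b1, a2, b2, pa2, pb2, pa1, pb1) {
  het2 <- a2 != b2
  Pg2 <- ifelse(het2, 2 * pa2 * pb2, pa2 * pa2)
  U <- function(x) {
    # P(g2 | shared allele x, other allele from frequencies)
    ifelse(het2,
           (x == a2) * pb2 + (x == b2) * pa2,
           (x == a2) * pa2)
  }
  T1 <- ifelse(a1 != b1, 0.5 * U(a1) + 0.5 * U(b1), U(a1))
  same <- (a1 == a2) & (b1 == b2)
  (0.25 * Pg2 + 0.5 * T1 + 0.25 * same) / Pg2
}

#' Full-sibling likelihood-ratio classification of pairs
#'
#' For every within-locality pair, computes the multilocus likelihood
#' ratio of the full-sib hypothesis (identity coefficients 0.25/0.5/0.25)
#' against unrelatedness, referenced to the locality's allele
#' frequencies, skipping missing loci.  Significance comes from `n_sim`
#' simulated unrelated pairs drawn from the same frequencies: the p-value
#' is the fraction of simulated pairs (restricted to the observed pair's
#' typed loci) with a log-likelihood-ratio at least as large.  A pair is
#' flagged full-sib at `p <= alpha`.  A parallel set of simulated
#' full-sib pairs provides the power of the test at `alpha`.
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()].
#' @param n_sim simulated pairs for the null (and power) distributions.
#' @param alpha significance level for the full-sib flag.
#' @param min_shared_loci pairs typed at fewer mutual loci are
#'   unclassified (`NA`).
#' @param seed RNG seed.
#' @return list of class `sib_test` with `pairs` (data.frame: id1, id2,
#'   locality, n_loci, logLR, p, is_full_sib), `power` (data.frame per
#'   locality: power at `alpha` for fully typed pairs), `alpha`, `n_sim`.
#' @export
sib_likelihood_test <- function(table, hier, n_sim = 10000, alpha = 0.01,
                                min_shared_loci = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hier <- align_hierarchy(table, hier)
  L <- length(table$loci)
  res <- list(); pow <- list()
  for (loc in unique(hier$locality)) {
    ids <- hier$individual[hier$locality == loc]
    sub <- table[ids, ]
    fr <- allele_frequencies(sub, NULL, "global")
    st <- fr$strata[[1]]
    plist <- lapply(seq_len(L), function(l) {
      obs <- unique(c(sub$a[, l], sub$b[, l]))
      obs <- obs[!is.na(obs)]
      locus_freq_lookup(st$freq[[l]], st$n_typed[[l]], as.character(obs))
    })
    n <- length(ids)
    px <- pair_indices(n)
    llr <- numeric(length(px$i))
    typed_pat <- matrix(FALSE, length(px$i), L)
    for (l in seq_len(L)) {
      p <- plist[[l]]
      a <- sub$a[, l]; b <- sub$b[, l]
      pa <- unname(p[as.character(a)]); pb <- unname(p[as.character(b)])
      a1 <- a[px$i]; b1 <- b[px$i]; a2 <- a[px$j]; b2 <- b[px$j]
      ok <- !is.na(a1) & !is.na(a2)
      if (!any(ok)) next
      lr <- sib_lr_locus(a1, b1, a2, b2, pa[px$j], pb[px$j], pa[px$i],
                         pb[px$i])
      llr[ok] <- llr[ok] + log(lr[ok])
      typed_pat[, l] <- ok
    }
    # simulated per-locus log-LRs for unrelated (null) and full-sib pairs
    null_l <- matrix(0, n_sim, L); fs_l <- matrix(0, n_sim, L)
    for (l in seq_len(L)) {
      p <- plist[[l]]
      sim_u <- sim_pair_lr(p, n_sim, related = FALSE)
      sim_f <- sim_pair_lr(p, n_sim, related = TRUE)
      null_l[, l] <- sim_u; fs_l[, l] <- sim_f
    }
    nl <- rowSums(typed_pat)
    pat_key <- apply(typed_pat, 1, function(z) paste(which(z), collapse = ","))
    pv <- rep(NA_real_, length(llr))
    for (key in unique(pat_key)) {
      w <- which(pat_key == key)
      loci_used <- as.integer(strsplit(key, ",")[[1]])
      if (length(loci_used) < min_shared_loci) next
      nulls <- sort(rowSums(null_l[, loci_used, drop = FALSE]))
      # p = (1 + #null >= obs) / (n_sim + 1)
      below <- findInterval(llr[w] - 1e-12, nulls)
      pv[w] <- (1 + n_sim - below) / (n_sim + 1)
    }
    res[[loc]] <- data.frame(
      id1 = ids[px$i], id2 = ids[px$j], locality = loc, n_loci = nl,
      logLR = ifelse(nl >= min_shared_loci, llr, NA_real_), p = pv,
      is_full_sib = !is.na(pv) & pv <= alpha)
    # power for fully typed pairs
    full_null <- sort(rowSums(null_l))
    fs_sum <- rowSums(fs_l)
    crit <- stats::quantile(full_null, 1 - alpha, names = FALSE)
    pow[[loc]] <- data.frame(locality = loc,
                             power = mean(fs_sum > crit),
                             mean_null_logLR = mean(full_null),
                             mean_fs_logLR = mean(fs_sum))
  }
  structure(list(pairs = do.call(rbind, c(res, list(make.row.names = FALSE))),
                 power = do.call(rbind, pow), alpha = alpha, n_sim = n_sim),
            class = "sib_test")
}

# simulate per-pair one-locus log-LR values under unrelated or full-sib
# sampling from frequency vector p
sim_pair_lr <- function(p, n_sim, related = FALSE) {
  k <- length(p)
  al <- as.integer(names(p))
  g1 <- matrix(al[sample.int(k, 2 * n_sim, TRUE, prob = p)], n_sim, 2)
  if (!related) {
    g2 <- matrix(al[sample.int(k, 2 * n_sim, TRUE, prob = p)], n_sim, 2)
  } else {
    u <- stats::runif(n_sim)
    g2 <- matrix(al[sample.int(k, 2 * n_sim, TRUE, prob = p)], n_sim, 2)
    # one allele IBD: replace one slot by a random allele of g1
    one <- u >= 0.25 & u < 0.75
    pickg1 <- ifelse(stats::runif(n_sim) < 0.5, g1[, 1], g1[, 2])
    g2[one, 1] <- pickg1[one]
    # both IBD: copy g1
    two <- u >= 0.75
    g2[two, ] <- g1[two, ]
  }
  pa1 <- unname(p[as.character(g1[, 1])]); pb1 <- unname(p[as.character(g1[, 2])])
  pa2 <- unname(p[as.character(g2[, 1])]); pb2 <- unname(p[as.character(g2[, 2])])
  # canonical order for the identity indicator
  swap1 <- g1[, 1] > g1[, 2]; swap2 <- g2[, 1] > g2[, 2]
  a1 <- ifelse(swap1, g1[, 2], g1[, 1]); b1 <- ifelse(swap1, g1[, 1], g1[, 2])
  a2 <- ifelse(swap2, g2[, 2], g2[, 1]); b2 <- ifelse(swap2, g2[, 1], g2[, 2])
  pa1 <- unname(p[as.character(a1)]); pb1 <- unname(p[as.character(b1)])
  pa2 <- unname(p[as.character(a2)]); pb2 <- unname(p[as.character(b2)])
  log(sib_lr_locus(a1, b1, a2, b2, pa2, pb2, pa1, pb1))
}

#' Two-proportion Z test (pooled variance, no continuity correction)
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with `z`, `chisq` (`= z^2`, the common reporting form),
#'   and two-sided `p`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0) {
    warning("zero pairs in a cell; Z undefined")
    return(list(z = NA_real_, chisq = NA_real_, p = NA_real_))
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, chisq = z^2, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare full-sib proportions within versus among groups
#'
#' For each locality and hierarchical level, splits the classified
#' within-locality pairs into pairs sharing a group (percha, point, or
#' transect) versus pairs in different groups, and tests the difference of
#' full-sib proportions with the pooled two-proportion Z test
#' ([two_proportion_z()]).
#'
#' @param sibs result of [sib_likelihood_test()].
#' @param hier a [hierarchy()].
#' @param level `"percha"`, `"point"`, or `"transect"`.
#' @return data.frame per locality: counts, proportions, `z`, `chisq`,
#'   and two-sided `p`.
#' @export
sib_proportion_compare <- function(sibs, hier,
                                   level = c("percha", "point",
                                             "transect")) {
  level <- match.arg(level)
  stopifnot(inherits(sibs, "sib_test"))
  d <- sibs$pairs[!is.na(sibs$pairs$p), ]
  key <- stratum_labels(hier, level)
  names(key) <- hier$individual
  same <- key[d$id1] == key[d$id2]
  out <- list()
  for (loc in unique(d$locality)) {
    w <- d$locality == loc
    n_w <- sum(w & same); s_w <- sum(w & same & d$is_full_sib)
    n_a <- sum(w & !same); s_a <- sum(w & !same & d$is_full_sib)
    zt <- two_proportion_z(s_w, n_w, s_a, n_a)
    out[[length(out) + 1L]] <- data.frame(
      locality = loc, level = level,
      n_within = n_w, sib_within = s_w,
      n_among = n_a, sib_among = s_a,
      prop_within = if (n_w) s_w / n_w else NA_real_,
      prop_among = if (n_a) s_a / n_a else NA_real_,
      z = zt$z, chisq = zt$chisq, p = zt$p)
  }
  do.call(rbind, out)
}
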