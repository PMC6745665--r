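# upper-triangle pair indices
pair_indices <- function(n) {
  j <- rep.int(seq_len(n), seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  list(i = i, j = j)
}

# per-locus allele-frequency lookup with an unseen-allele floor of
# 1/(2n + 1) and renormalisation
locus_freq_lookup <- function(freq, n_typed, observed) {
  p <- freq
  unseen <- setdiff(observed, names(p))
  if (length(unseen)) {
    floor_f <- 1 / (2 * n_typed + 1)
    p <- c(p, stats::setNames(rep(floor_f, length(unseen)), unseen))
    p <- p / sum(p)
  }
  p
}

#' Pairwise Lynch-Ritland relatedness matrix
#'
#' The regression estimator of pairwise relatedness referenced to a set of
#' allele frequencies.  For reference genotype (a, b) and proband (c, d)
#' at one locus the directed estimate is
#' `r = (p_a (S_bc + S_bd) + p_b (S_ac + S_ad) - 4 p_a p_b) /
#'      ((1 + S_ab)(p_a + p_b) - 4 p_a p_b)`
#' with `S` allele-identity indicators; multilocus values are the
#' information-weighted average with locus weight
#' `W = ((1 + S_ab)(p_a + p_b) - 4 p_a p_b) / (2 p_a p_b)`.  The asymmetry
#' of reference and proband is resolved by averaging the two directed
#' multilocus estimates.  Loci that are uninformative for a pair
#' (zero regression denominator, e.g. the reference homozygous for a
#' near-fixed allele) are skipped for that pair; pairs sharing fewer than
#' `min_shared_loci` typed loci are masked `NA`.
#'
#' Alleles observed in the data but absent from the frequency reference
#' receive a floor frequency of `1/(2n + 1)` followed by renormalisation.
#'
#' @param table a [genotab()].
#' @param freqs a `freq_table` giving the reference allele frequencies
#'   (one stratum; typically the data subset under analysis).  `NULL`
#'   computes global frequencies from `table`.
#' @param stratum stratum of `freqs` to use.
#' @param min_shared_loci minimum mutually typed loci per pair.
#' @return symmetric matrix of relatedness values with `NA` on the
#'   diagonal and for masked pairs; attribute `n_shared` holds the
#'   per-pair shared-locus count matrix.
#' @export
lynch_ritland_matrix <- function(table, freqs = NULL, stratum = 1L,
                                 min_shared_loci = 5) {
  stopifnot(inherits(table, "genotab"))
  if (is.null(freqs)) freqs <- allele_frequencies(table, NULL, "global")
  st <- freqs$strata[[stratum]]
  n <- length(table$ind)
  px <- pair_indices(n)
  num_xy <- den_xy <- num_yx <- den_yx <- numeric(length(px$i))
  shared <- integer(length(px$i))
  for (l in seq_along(table$loci)) {
    loc <- table$loci[l]
    a <- table$a[, l]; b <- table$b[, l]
    obs <- unique(c(a, b)); obs <- obs[!is.na(obs)]
    if (!length(obs)) next
    p <- locus_freq_lookup(st$freq[[loc]], st$n_typed[[loc]],
                           as.character(obs))
    key <- as.character(a)
    pa <- unname(p[as.character(a)]); pb <- unname(p[as.character(b)])
    a1 <- a[px$i]; b1 <- b[px$i]; a2 <- a[px$j]; b2 <- b[px$j]
    ok <- !is.na(a1) & !is.na(a2)
    if (!any(ok)) next
    shared[ok] <- shared[ok] + 1L
    dd <- lr_directed(a1[ok], b1[ok], a2[ok], b2[ok],
                      pa[px$i][ok], pb[px$i][ok])
    num_xy[ok] <- num_xy[ok] + dd$num; den_xy[ok] <- den_xy[ok] + dd$wt
    dd <- lr_directed(a2[ok], b2[ok], a1[ok], b1[ok],
                      pa[px$j][ok], pb[px$j][ok])
    num_yx[ok] <- num_yx[ok] + dd$num; den_yx[ok] <- den_yx[ok] + dd$wt
  }
  r_xy <- ifelse(den_xy > 0, num_xy / den_xy, NA_real_)
  r_yx <- ifelse(den_yx > 0, num_yx / den_yx, NA_real_)
  r <- rowMeans(cbind(r_xy, r_yx), na.rm = TRUE)
  r[shared < min_shared_loci] <- NA_real_
  r[is.nan(r)] <- NA_real_
  out <- matrix(NA_real_, n, n, dimnames = list(table$ind, table$ind))
  out[cbind(px$i, px$j)] <- r
  out[cbind(px$j, px$i)] <- r
  ns <- matrix(NA_integer_, n, n, dimnames = dimnames(out))
  ns[cbind(px$i, px$j)] <- shared; ns[cbind(px$j, px$i)] <- shared
  attr(out, "n_shared") <- ns
  out
}

# directed Lynch-Ritland terms for one locus, vectorised over pairs.
# Reference genotype (a1, b1) with frequencies (pa, pb); proband (a2, b2).
# Returns weighted numerator W*r and weight W (skipped loci contribute 0).
lr_directed <- function(a1, b1, a2, b2, pa, pb) {
  Sab <- as.numeric(a1 == b1)
  Sac <- as.numeric(a1 == a2); Sad <- as.numeric(a1 == b2)
  Sbc <- as.numeric(b1 == a2); Sbd <- as.numeric(b1 == b2)
  den <- (1 + Sab) * (pa + pb) - 4 * pa * pb
  num <- pa * (Sbc + Sbd) + pb * (Sac + Sad) - 4 * pa * pb
  usable <- den > 1e-12 & pa > 0 & pb > 0
  # weighted numerator: W * r = num / (2 pa pb); weight W = den / (2 pa pb)
  wnum <- ifelse(usable, num / (2 * pa * pb), 0)
  wt <- ifelse(usable, den / (2 * pa * pb), 0)
  list(num = wnum, wt = wt)
}

#' Hierarchical permutation tests of mean within-group relatedness
#'
#' For each locality and each group at the chosen level (percha, point, or
#' transect), compares the observed mean pairwise relatedness within the
#' group against a null distribution obtained by permuting individuals
#' among the groups of that locality (group sizes preserved).  Reports the
#' two-sided empirical p-value and the 2.5%/97.5% null limits, plus a
#' bootstrap 95% CI on the observed mean obtained by resampling the
#' group's pairs.
#'
#' Relatedness is referenced to each locality's own allele frequencies
#' when a [genotab()] is supplied (the default workflow); a precomputed
#' matrix is used as-is.
#'
#' @param x a [genotab()] (per-locality Lynch-Ritland matrices are
#'   computed internally) or a symmetric relatedness matrix with
#'   individual IDs as dimnames.
#' @param hier a [hierarchy()].
#' @param level `"percha"`, `"point"`, or `"transect"`.
#' @param n_perm permutations.
#' @param n_boot bootstrap replicates for the observed-mean CI.
#' @param min_group minimum group size; defaults to 10 for perchas and 2
#'   otherwise.
#' @param min_shared_loci passed to [lynch_ritland_matrix()].
#' @param seed RNG seed.
#' @return data.frame with one row per retained group: `locality`,
#'   `level`, `group`, `n`, `mean_r`, `null_lo`, `null_hi`, `p`,
#'   `boot_lo`, `boot_hi`.
#' @export
hierarchical_relatedness_test <- function(x, hier,
                                          level = c("percha", "point",
                                                    "transect"),
                                          n_perm = 9999, n_boot = 1000,
                                          min_group = NULL,
                                          min_shared_loci = 5,
                                          seed = NULL) {
  level <- match.arg(level)
  if (is.null(min_group)) min_group <- if (level == "percha") 10L else 2L
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (loc in unique(hier$locality)) {
    ids <- hier$individual[hier$locality == loc]
    if (inherits(x, "genotab")) {
      sub <- x[intersect(x$ind, ids), ]
      fr <- allele_frequencies(sub, NULL, "global")
      rel <- lynch_ritland_matrix(sub, fr, min_shared_loci = min_shared_loci)
    } else {
      keep <- intersect(rownames(x), ids)
      rel <- x[keep, keep, drop = FALSE]
    }
    h <- hier[match(rownames(rel), hier$individual), , drop = FALSE]
    grp <- stratum_labels(h, level)
    sizes <- table(grp)
    groups <- names(sizes[sizes >= min_group])
    if (!length(groups)) next
    gidx <- lapply(groups, function(g) which(grp == g))
    obs <- vapply(gidx, function(w) mean(rel[w, w], na.rm = TRUE), 0)
    nulls <- matrix(NA_real_, n_perm, length(groups))
    nr <- nrow(rel)
    for (r in seq_len(n_perm)) {
      perm <- sample.int(nr)
      nulls[r, ] <- vapply(gidx, function(w) {
        pw <- perm[w]; mean(rel[pw, pw], na.rm = TRUE)
      }, 0)
    }
    for (gi in seq_along(groups)) {
      nv <- nulls[, gi]
      p_hi <- (1 + sum(nv >= obs[gi] - 1e-12)) / (n_perm + 1)
      p_lo <- (1 + sum(nv <= obs[gi] + 1e-12)) / (n_perm + 1)
      w <- gidx[[gi]]
      sub <- rel[w, w]
      vals <- sub[upper.tri(sub)]
      vals <- vals[!is.na(vals)]
      bt <- vapply(seq_len(n_boot), function(r)
        mean(vals[sample.int(length(vals), replace = TRUE)]), 0)
      out[[length(out) + 1L]] <- data.frame(
        locality = loc, level = level, group = groups[gi],
        n = length(w), mean_r = obs[gi],
        null_lo = stats::quantile(nv, 0.025, names = FALSE),
        null_hi = stats::quantile(nv, 0.975, names = FALSE),
        p = min(1, 2 * min(p_hi, p_lo)),
        boot_lo = stats::quantile(bt, 0.025, names = FALSE),
        boot_hi = stats::quantile(bt, 0.975, names = FALSE))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
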