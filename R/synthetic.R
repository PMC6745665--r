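#' Simulation configuration for hierarchical microsatellite sampling
#'
#' The defaults emulate a fine-scale survey of a sessile marine
#' invertebrate: ten microsatellite loci with 12-29 alleles each; three
#' localities with two 50 m transects each, six points per transect at
#' 10 m spacing, 3-5 perchas (aggregates) per point, and 3-10 sampled
#' individuals per percha (giving roughly 900 individuals); two genetic
#' clusters (the first locality versus the rest) diverged at FST 0.03;
#' a fifth of perchas seeded with a co-settled full-sib clutch of three;
#' occasional selfing; null alleles at frequency 0.1 per locus producing a
#' heterozygote deficit; and 1% genotype dropout.
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus allele counts per locus: a length-2 range to
#'   draw from uniformly, or a length-`n_loci` vector of exact counts.
#'   The default fixes the ten counts at the published per-locus values of
#'   the emulated survey (12-29 alleles, mean 21).
#' @param base_freq_concentration Dirichlet concentration for the ancestral
#'   allele frequencies (scalar or length `n_loci`).  The default 1 (a
#'   uniform simplex) reproduces the emulated survey's multilocus expected
#'   heterozygosities of 0.84-0.90 given the per-locus allele counts.
#' @param n_clusters number of genetic clusters.
#' @param cluster_divergence target pairwise FST between clusters in
#'   `[0, 1)` (Balding-Nichols parameter).
#' @param n_localities,n_transects,n_points numbers of localities, transects
#'   per locality, points per transect.
#' @param perchas_per_point integer vector of candidate percha counts per
#'   point (sampled uniformly).
#' @param ind_per_percha integer vector of candidate individuals per percha
#'   (sampled uniformly; at most 16).
#' @param cluster_of_locality integer vector mapping localities to
#'   clusters; default assigns locality 1 to cluster 1 and the rest to
#'   cluster 2.
#' @param sib_clutch_rate fraction of perchas seeded with one full-sib
#'   clutch.
#' @param sib_clutch_size individuals per clutch.
#' @param selfing_rate probability that an independent individual is
#'   replaced by a selfed offspring of a single local parent.
#' @param null_allele_freq per-locus null-allele frequency (scalar or
#'   length `n_loci`).  The default mirrors the emulated survey, where the
#'   heterozygote deficit (and hence the inferred null-allele load) is
#'   concentrated at the most polymorphic loci; per-locus rates are about
#'   half the published per-locus inbreeding coefficients.
#' @param missing_rate per-genotype dropout probability applied last.
#' @param seed RNG seed used by [simulate_dataset()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 10,
                       alleles_per_locus = NULL,
                       base_freq_concentration = 1,
                       n_clusters = 2,
                       cluster_divergence = 0.03,
                       n_localities = 3,
                       n_transects = 2,
                       n_points = 6,
                       perchas_per_point = 3:5,
                       ind_per_percha = 3:10,
                       cluster_of_locality = NULL,
                       sib_clutch_rate = 0.2,
                       sib_clutch_size = 3,
                       selfing_rate = 0.01,
                       null_allele_freq = NULL,
                       missing_rate = 0.01,
                       seed = 1L) {
  # defaults emulate the published ten-locus survey: per-locus allele
  # counts and null-allele loads paired so the heterozygote deficit sits
  # at the most polymorphic loci
  if (is.null(alleles_per_locus))
    alleles_per_locus <- if (n_loci == 10)
      c(28L, 18L, 23L, 18L, 22L, 15L, 23L, 26L, 29L, 12L) else c(12L, 29L)
  if (is.null(null_allele_freq))
    null_allele_freq <- if (n_loci == 10)
      c(0.24, 0.12, 0.07, 0.03, 0.08, 0.03, 0.19, 0.26, 0.30, 0) else 0.1
  if (is.null(cluster_of_locality))
    cluster_of_locality <- c(1L, rep(2L, n_localities - 1L))
  cluster_of_locality <- pmin(as.integer(cluster_of_locality),
                              as.integer(n_clusters))
  cfg <- list(n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              base_freq_concentration = rep_len(base_freq_concentration,
                                                n_loci),
              n_clusters = as.integer(n_clusters),
              cluster_divergence = cluster_divergence,
              n_localities = as.integer(n_localities),
              n_transects = as.integer(n_transects),
              n_points = as.integer(n_points),
              perchas_per_point = as.integer(perchas_per_point),
              ind_per_percha = as.integer(ind_per_percha),
              cluster_of_locality = cluster_of_locality,
              sib_clutch_rate = sib_clutch_rate,
              sib_clutch_size = as.integer(sib_clutch_size),
              selfing_rate = selfing_rate,
              null_allele_freq = rep_len(null_allele_freq, n_loci),
              missing_rate = missing_rate,
              seed = as.integer(seed))
  probs <- c(cfg$sib_clutch_rate, cfg$selfing_rate, cfg$null_allele_freq,
             cfg$missing_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$cluster_divergence < 0 || cfg$cluster_divergence >= 1)
    stop("cluster_divergence must lie in [0, 1)")
  if (any(c(cfg$n_loci, cfg$n_clusters, cfg$n_localities, cfg$n_transects,
            cfg$n_points, cfg$perchas_per_point, cfg$ind_per_percha,
            cfg$sib_clutch_size) < 1))
    stop("counts must be >= 1")
  if (max(cfg$ind_per_percha) > 16)
    stop("at most 16 individuals are sampled per percha")
  if (cfg$sib_clutch_size > min(cfg$ind_per_percha))
    stop("config error: sib clutch larger than the smallest percha")
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (all(g == 0)) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

#' Draw per-cluster allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies at each locus are drawn from a symmetric Dirichlet
#' with concentration `base_freq_concentration`; each cluster's frequencies
#' are then drawn from `Dirichlet(p * (1 - F) / F)` with
#' `F = cluster_divergence`, so the expected pairwise FST between clusters
#' is approximately `F`.  With `F = 0` all clusters share the ancestral
#' frequencies exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with `alleles` (per-locus allele size vectors) and `freq`:
#'   a list indexed `[[cluster]][[locus]]` of named frequency vectors
#'   summing to 1.
#' @export
draw_cluster_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  k <- if (length(cfg$alleles_per_locus) == 1) {
    rep(cfg$alleles_per_locus, cfg$n_loci)
  } else if (length(cfg$alleles_per_locus) == cfg$n_loci) {
    cfg$alleles_per_locus          # exact per-locus allele counts
  } else {
    sample(seq(cfg$alleles_per_locus[1], cfg$alleles_per_locus[2]),
           cfg$n_loci, replace = TRUE)
  }
  alleles <- lapply(k, function(m) 100L + 2L * seq_len(m))  # bp sizes
  F <- cfg$cluster_divergence
  freq <- vector("list", cfg$n_clusters)
  conc <- rep_len(cfg$base_freq_concentration, cfg$n_loci)
  base <- lapply(seq_len(cfg$n_loci), function(l)
    stats::setNames(rdirichlet1(rep(conc[l], k[l])), alleles[[l]]))
  for (cl in seq_len(cfg$n_clusters)) {
    freq[[cl]] <- lapply(seq_len(cfg$n_loci), function(l) {
      p <- base[[l]]
      if (F == 0) return(p)
      stats::setNames(rdirichlet1(p * (1 - F) / F), alleles[[l]])
    })
  }
  list(alleles = alleles, base = base, freq = freq)
}

# draw n HWE genotypes (2 gametes) from freq vector; returns 2-col matrix of
# allele indices into names(p)
draw_gametes <- function(p, n) {
  matrix(sample.int(length(p), 2 * n, replace = TRUE, prob = p), n, 2)
}

#' Simulate a hierarchical genotype dataset with known truth
#'
#' Builds the nested sampling design from the configuration, assigns each
#' locality to a genetic cluster, and draws genotypes:
#' independent individuals are Hardy-Weinberg draws from their cluster's
#' allele frequencies; a fraction of perchas receives one full-sib clutch
#' (two simulated parents, Mendelian offspring, co-settled in the percha);
#' independent individuals are replaced with probability `selfing_rate` by
#' a selfed offspring of a single parent drawn from a selfing lineage
#' (inbred, autozygous at half its loci on average); where possible the
#' parent occupies the neighbouring slot of the same percha, so selfing
#' leaves sampled pairs of identical or near-identical multilocus
#' genotypes.  A latent null allele
#' segregates at each locus with frequency `null_allele_freq`: a
#' visible/null heterozygote presents as a visible homozygote and a null
#' homozygote as a missing genotype.  Random dropout at `missing_rate` is
#' applied last.  All randomness flows from `cfg$seed`, so the same
#' configuration reproduces the same dataset.
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (observed [genotab()]), `hierarchy`
#'   ([hierarchy()]), `truth` (data.frame: individual, cluster, family,
#'   parent1, parent2, selfed), `latent` (pre-masking `genotab`, null
#'   allele coded as size 0... stored as `NA` alleles replaced: see
#'   Details), and `freqs` (the cluster frequency draw).
#' @details In the latent table the null allele is stored as the sentinel
#'   size `-1L` so null carriers can be identified by truth-aware tests.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fr <- draw_cluster_frequencies(cfg)
  L <- cfg$n_loci

  # ---- hierarchy plan ----
  loc_names <- sprintf("L%02d", seq_len(cfg$n_localities))
  rows <- list(); fam <- 0L
  truth <- list()
  for (li in seq_len(cfg$n_localities)) {
    for (ti in seq_len(cfg$n_transects)) {
      tr <- sprintf("%sT%d", loc_names[li], ti)
      for (pi in seq_len(cfg$n_points)) {
        pm <- 10L * (pi - 1L)
        np <- if (length(cfg$perchas_per_point) == 1) cfg$perchas_per_point
              else sample(cfg$perchas_per_point, 1)
        for (qi in seq_len(np)) {
          sz <- if (length(cfg$ind_per_percha) == 1) cfg$ind_per_percha
                else sample(cfg$ind_per_percha, 1)
          clutch <- if (stats::runif(1) < cfg$sib_clutch_rate)
            min(cfg$sib_clutch_size, sz) else 0L
          if (clutch > 0L) fam <- fam + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            locality = loc_names[li], transect = tr, point_m = pm,
            percha = sprintf("q%02d", qi),
            cluster = cfg$cluster_of_locality[li],
            family = c(rep(fam, clutch), rep(NA_integer_, sz - clutch)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  plan <- do.call(rbind, rows)
  n <- nrow(plan)
  plan$individual <- sprintf("i%04d", seq_len(n))

  # ---- latent genotypes (allele indices; 0 = null allele) ----
  ga <- matrix(0L, n, L); gb <- matrix(0L, n, L)
  parent1 <- rep(NA_character_, n); parent2 <- rep(NA_character_, n)
  selfed <- rep(FALSE, n)

  # extend each cluster/locus frequency with the null allele
  pnull <- cfg$null_allele_freq
  freq_ext <- lapply(fr$freq, function(fl)
    lapply(seq_len(L), function(l)
      c(fl[[l]] * (1 - pnull[l]), null = pnull[l])))
  null_idx <- vapply(seq_len(L), function(l)
    length(fr$alleles[[l]]) + 1L, integer(1))

  draw_ind <- function(cl) {
    vapply(seq_len(L), function(l) draw_gametes(freq_ext[[cl]][[l]], 1)[1, ],
           integer(2))  # 2 x L
  }
  # inbred individual (selfing lineage): autozygous at each locus with
  # probability f, else an independent two-gamete draw
  draw_ind_inbred <- function(cl, f = 0.5) {
    g <- draw_ind(cl)
    auto <- stats::runif(L) < f
    g[2, auto] <- g[1, auto]
    g
  }
  mendel <- function(p1, p2) {
    pick <- function(g) g[cbind(sample(c(1, 2), L, replace = TRUE),
                                seq_len(L))]
    rbind(pick(p1), pick(p2))
  }

  fams <- unique(plan$family[!is.na(plan$family)])
  fam_parents <- lapply(fams, function(f) {
    cl <- plan$cluster[match(f, plan$family)]
    list(p1 = draw_ind(cl), p2 = draw_ind(cl))
  })
  names(fam_parents) <- as.character(fams)

  # percha-local key for pairing a selfed offspring with a sampled parent
  percha_key <- paste(plan$transect, plan$point_m, plan$percha)
  for (i in seq_len(n)) {
    cl <- plan$cluster[i]
    if (!is.na(plan$family[i])) {
      fp <- fam_parents[[as.character(plan$family[i])]]
      g <- mendel(fp$p1, fp$p2)
      parent1[i] <- sprintf("f%03d_p1", plan$family[i])
      parent2[i] <- sprintf("f%03d_p2", plan$family[i])
    } else if (stats::runif(1) < cfg$selfing_rate) {
      # a selfing event: the parent comes from a lineage with a selfing
      # history (inbred, so homozygote-rich) and settles in the same
      # percha as its selfed offspring whenever a slot is available
      j <- i - 1L
      if (j >= 1L && percha_key[j] == percha_key[i] &&
          is.na(plan$family[j]) && !selfed[j] && is.na(parent1[j])) {
        par <- draw_ind_inbred(cl)
        ga[j, ] <- par[1, ]; gb[j, ] <- par[2, ]
        parent1[i] <- parent2[i] <- plan$individual[j]
      } else {
        par <- draw_ind_inbred(cl)
        parent1[i] <- parent2[i] <- sprintf("self_ext_%s", plan$individual[i])
      }
      g <- mendel(par, par)
      selfed[i] <- TRUE
    } else {
      g <- draw_ind(cl)
    }
    ga[i, ] <- g[1, ]; gb[i, ] <- g[2, ]
  }

  # ---- map indices to allele sizes; apply null-allele masking ----
  size_a <- matrix(NA_integer_, n, L); size_b <- size_a
  lat_a <- size_a; lat_b <- size_a
  for (l in seq_len(L)) {
    sizes <- c(fr$alleles[[l]], -1L)  # -1 = null sentinel
    va <- sizes[ga[, l]]; vb <- sizes[gb[, l]]
    lat_a[, l] <- va; lat_b[, l] <- vb
    a_null <- va == -1L; b_null <- vb == -1L
    oa <- va; ob <- vb
    oa[a_null & !b_null] <- vb[a_null & !b_null]  # present as visible hom
    ob[b_null & !a_null] <- va[b_null & !a_null]
    oa[a_null & b_null] <- NA_integer_
    ob[a_null & b_null] <- NA_integer_
    size_a[, l] <- oa; size_b[, l] <- ob
  }

  # ---- random dropout ----
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    size_a[drop] <- NA_integer_; size_b[drop] <- NA_integer_
  }

  loci <- sprintf("loc%02d", seq_len(L))
  tab <- genotab(size_a, size_b, plan$individual, loci)
  lat <- suppressWarnings(genotab(lat_a, lat_b, plan$individual, loci))
  hier <- hierarchy(plan$individual, plan$locality, plan$transect,
                    plan$point_m, plan$percha)
  truth <- data.frame(individual = plan$individual,
                      cluster = plan$cluster,
                      family = plan$family,
                      parent1 = parent1, parent2 = parent2,
                      selfed = selfed, stringsAsFactors = FALSE)
  list(table = tab, hierarchy = hier, truth = truth, latent = lat,
       freqs = fr, seed = cfg$seed)
}

#' Enumerate truth full-sib pairs of a simulated dataset
#'
#' @param truth the `truth` data.frame from [simulate_dataset()].
#' @return two-column matrix of individual IDs, one row per full-sib pair.
#' @export
truth_sib_pairs <- function(truth) {
  fams <- split(truth$individual, truth$family)
  out <- lapply(fams, function(ids)
    if (length(ids) >= 2) t(utils::combn(ids, 2)) else NULL)
  do.call(rbind, out)
}
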