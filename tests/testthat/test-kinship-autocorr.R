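test_that("Loiselle kinship matches the explicit indicator-sum oracle", {
  sim <- simulate_dataset(sim_config(
    n_localities = 1, n_transects = 1, n_points = 3, perchas_per_point = 3,
    ind_per_percha = 6, missing_rate = 0.1, null_allele_freq = 0, seed = 37))
  tab <- sim$table
  ft <- allele_frequencies(tab, NULL, "global")
  st <- ft$strata[[1]]
  K <- loiselle_kinship_matrix(tab, ft, min_shared_loci = 1)
  as_list <- function(i) lapply(seq_along(tab$loci), function(l)
    if (is.na(tab$a[i, l])) NULL else c(tab$a[i, l], tab$b[i, l]))
  set.seed(2)
  for (r in 1:30) {
    ij <- sample(length(tab$ind), 2)
    oracle <- loiselle_pair_naive(as_list(ij[1]), as_list(ij[2]),
                                  st$freq, st$n_typed)
    expect_equal(K[ij[1], ij[2]], oracle, tolerance = 1e-10)
  }
})

test_that("kinship has the expected scale: sibs ~0.25, overall mean ~0,
           identical selfed pairs in the extreme tail", {
  cfg <- sim_config(n_localities = 2, n_transects = 1, n_points = 6,
                    perchas_per_point = 4, ind_per_percha = 8,
                    sib_clutch_rate = 0.5, sib_clutch_size = 4,
                    selfing_rate = 0, null_allele_freq = 0,
                    missing_rate = 0, cluster_divergence = 0.02, seed = 41)
  sim <- simulate_dataset(cfg)
  K <- loiselle_kinship_matrix(sim$table)
  sp <- truth_sib_pairs(sim$truth)
  expect_lt(abs(mean(K[sp]) - 0.25), 0.03)
  expect_lt(abs(mean(K, na.rm = TRUE)), 0.005)

  # a literal clone pair lands near 0.5, above the 0.36 threshold
  tab <- sim$table
  a <- rbind(tab$a, tab$a[1, ]); b <- rbind(tab$b, tab$b[1, ])
  tab2 <- genotab(a, b, c(tab$ind, "clone"), tab$loci)
  K2 <- loiselle_kinship_matrix(tab2)
  expect_gt(K2[1, length(tab2$ind)], 0.36)
})

test_that("kinship profile bins conserve the pair count", {
  sim <- simulate_dataset(sim_config(
    n_localities = 2, n_transects = 1, n_points = 3, perchas_per_point = 2,
    ind_per_percha = 5, missing_rate = 0.05, seed = 43))
  prof <- loiselle_kinship_profile(sim$table, sim$hierarchy)
  n <- length(sim$table$ind)
  K <- prof$kinship
  n_valid <- sum(!is.na(K[upper.tri(K)]))
  expect_equal(sum(prof$histogram$n_within) + sum(prof$histogram$n_among),
               n_valid)
  expect_equal(sum(prof$histogram$prop_within) +
                 sum(prof$histogram$prop_among), 1)
})

test_that("geographic distances follow the transect arithmetic", {
  h <- hierarchy(c("a", "b", "c", "d"),
                 locality = c("A", "A", "A", "B"),
                 transect = c("A1", "A1", "A1", "B1"),
                 point_m = c(10L, 40L, 10L, 0L),
                 percha = c("q1", "q1", "q2", "q1"))
  d <- geographic_distances(h)
  expect_equal(d["a", "b"], 30)
  expect_equal(d["a", "c"], 0)   # same point, different percha
  expect_true(is.na(d["a", "d"]))
  expect_equal(distance_class(30), 30L)   # class (20, 30]
  expect_equal(distance_class(c(0, 1, 10, 11)), c(0L, 10L, 10L, 20L))
})

test_that("the genetic distance takes the documented per-genotype values
           and is invariant to allele relabeling", {
  tab <- make_tab(list(list(c(1L, 1L)), list(c(1L, 2L)), list(c(2L, 2L)),
                       list(c(3L, 4L)), list(c(1L, 3L))))
  D <- genetic_distance_sp(tab)
  expect_equal(D[1, 2], 1)  # AA vs AB
  expect_equal(D[1, 3], 4)  # AA vs BB
  expect_equal(D[1, 4], 3)  # AA vs CD
  expect_equal(D[2, 5], 1)  # AB vs AC
  expect_equal(D[2, 4], 2)  # AB vs CD
  # relabel alleles with a permutation of the sizes
  relab <- c(`1` = 9L, `2` = 7L, `3` = 5L, `4` = 3L)
  tab2 <- make_tab(list(list(relab[c(1, 1)]), list(relab[c(1, 2)]),
                        list(relab[c(2, 2)]), list(relab[c(3, 4)]),
                        list(relab[c(1, 3)])))
  expect_equal(unname(genetic_distance_sp(tab2)), unname(D))
})

test_that("clones co-located at one point push r above the envelope in the
           first distance class", {
  set.seed(51)
  # 30 unrelated individuals spread over a transect, plus a clonal cluster
  # of 6 at point 0
  cfg <- sim_config(n_localities = 1, n_transects = 1, n_points = 6,
                    perchas_per_point = 1, ind_per_percha = 6,
                    n_clusters = 1, sib_clutch_rate = 0, selfing_rate = 0,
                    null_allele_freq = 0, missing_rate = 0, seed = 53)
  sim <- simulate_dataset(cfg)
  a <- sim$table$a; b <- sim$table$b
  at0 <- which(sim$hierarchy$point_m == 0)
  for (i in at0[-1]) { a[i, ] <- a[at0[1], ]; b[i, ] <- b[at0[1], ] }
  tab <- genotab(a, b, sim$table$ind, sim$table$loci)
  ac <- autocorrelogram(tab, sim$hierarchy, n_perm = 199, n_boot = 50,
                        seed = 3)
  first <- ac[ac$class == 0, ]
  expect_gt(first$r, first$env_hi)
})

test_that("position-independent genotypes stay inside the null envelope in
           most classes", {
  hits <- 0L; total <- 0L
  for (s in 1:6) {
    sim <- simulate_dataset(sim_config(
      n_localities = 1, n_transects = 1, n_points = 6, perchas_per_point = 2,
      ind_per_percha = 5, n_clusters = 1, sib_clutch_rate = 0,
      selfing_rate = 0, null_allele_freq = 0, missing_rate = 0,
      seed = 60 + s))
    ac <- autocorrelogram(sim$table, sim$hierarchy, n_perm = 199,
                          n_boot = 20, seed = s)
    ok <- !is.na(ac$r)
    total <- total + sum(ok)
    hits <- hits + sum(ac$r[ok] < ac$env_lo[ok] | ac$r[ok] > ac$env_hi[ok])
  }
  expect_lt(hits / total, 0.25)
})
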