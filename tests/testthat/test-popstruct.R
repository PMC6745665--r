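two_pop_hier <- function(n1, n2) {
  ids <- sprintf("i%03d", seq_len(n1 + n2))
  hierarchy(ids, rep(c("A", "B"), c(n1, n2)),
            rep(c("A1", "B1"), c(n1, n2)), 0L, "q1")
}

test_that("populations fixed for different alleles give FST = 1", {
  tab <- make_tab(c(rep(list(list(c(1L, 1L), c(5L, 5L))), 5),
                    rep(list(list(c(2L, 2L), c(6L, 6L))), 5)))
  am <- amova(tab, two_pop_hier(5, 5), level = "site", n_perm = 99, seed = 1)
  expect_equal(am$fstats$value[am$fstats$statistic == "FST"], 1)
  expect_equal(am$components$pct[3], 0)  # no within-individual variance
  # only permutations recreating the exact split reach FST = 1
  expect_lte(am$fstats$p[1], 0.05)
})

test_that("a duplicated population gives FST near zero with uniform-ish p", {
  sim <- simulate_dataset(sim_config(
    n_localities = 2, n_transects = 1, n_points = 3, perchas_per_point = 3,
    ind_per_percha = 6, n_clusters = 1, cluster_divergence = 0,
    sib_clutch_rate = 0, selfing_rate = 0, null_allele_freq = 0,
    missing_rate = 0, seed = 3))
  am <- amova(sim$table, sim$hierarchy, level = "locality", n_perm = 199,
              seed = 2)
  expect_lt(am$fstats$value[1], 0.01)
  expect_gt(am$fstats$p[1], 0.05)
})

test_that("variance components match a hand-computed nested ANOVA oracle", {
  # 6 individuals, 2 populations, 2 loci; oracle computes SS from explicit
  # pairwise allele mismatches
  geno <- list(list(c(1L, 2L), c(10L, 10L)),
               list(c(1L, 1L), c(10L, 11L)),
               list(c(2L, 2L), c(11L, 11L)),
               list(c(1L, 3L), c(12L, 10L)),
               list(c(3L, 3L), c(12L, 12L)),
               list(c(3L, 2L), c(12L, 11L)))
  tab <- make_tab(geno)
  hier <- two_pop_hier(3, 3)
  am <- amova(tab, hier, level = "site", n_perm = 9, seed = 1)

  ss_t <- ss_w <- ss_i <- 0
  for (l in 1:2) {
    copies <- unlist(lapply(geno, function(g) g[[l]]))
    pops <- rep(rep(1:2, each = 3), each = 1)
    lab_by_pop <- split(copies, rep(1:2, each = 6))
    ss_total <- ss_pairwise_naive(copies)
    ss_pop <- sum(vapply(lab_by_pop, ss_pairwise_naive, 0))
    ss_ind <- sum(vapply(geno, function(g) ss_pairwise_naive(g[[l]]), 0))
    ss_t <- ss_t + ss_total - ss_pop      # among populations
    ss_w <- ss_w + ss_pop - ss_ind        # among individuals within pops
    ss_i <- ss_i + ss_ind                 # within individuals
  }
  expect_equal(am$components$SS, c(ss_t, ss_w, ss_i), tolerance = 1e-12)
  expect_equal(am$components$df, c(1, 4, 6))

  # variance components from the oracle's mean squares
  ms <- c(ss_t / 1, ss_w / 4, ss_i / 6)
  n0 <- (12 - (36 + 36) / 12) / 1
  vc <- ms[3]; vb <- (ms[2] - vc) / 2; va <- (ms[1] - ms[2]) / n0
  expect_equal(unname(am$components$var_comp),
               pmax(c(va, vb, vc), 0), tolerance = 1e-12)
})

test_that("AMOVA percentages sum to 100 and df sum to 2N - 1", {
  sim <- simulate_dataset(sim_config(
    n_localities = 3, n_transects = 1, n_points = 2, perchas_per_point = 2,
    ind_per_percha = 5, missing_rate = 0.05, seed = 6))
  am <- amova(sim$table, sim$hierarchy, level = "locality", n_perm = 49,
              seed = 3)
  expect_equal(sum(am$components$pct), 100, tolerance = 0.5)
  expect_equal(sum(am$components$df), 2 * length(sim$table$ind) - 1)
  expect_true(all(am$components$var_comp >= 0))
})

test_that("pairwise FST matrices are symmetric with zero diagonal and
           recover the simulated divergence", {
  sim <- simulate_dataset(sim_config(
    n_localities = 2, n_transects = 2, n_points = 5, perchas_per_point = 3,
    ind_per_percha = 7, cluster_divergence = 0.05, sib_clutch_rate = 0,
    selfing_rate = 0, null_allele_freq = 0, missing_rate = 0, seed = 8))
  pw <- pairwise_fst_permutation(sim$table, sim$hierarchy, level = "site",
                                 n_perm = 99, seed = 4)
  expect_equal(pw$fst, t(pw$fst))
  expect_equal(unname(diag(pw$fst)), rep(0, nrow(pw$fst)))
  # the two transects of one locality share a cluster: FST ~ 0
  expect_lt(pw$fst["L01T1", "L01T2"], 0.01)
  btw <- pw$fst["L01T1", "L02T1"]
  expect_gt(btw, 0.02)
  expect_true(pw$significant["L01T1", "L02T1"])
  expect_equal(min(pw$p, na.rm = TRUE) >= 1 / 100, TRUE)
})

test_that("ENA-corrected FST equals the uncorrected estimate without nulls
           and removes the upward null-allele bias", {
  sim <- simulate_dataset(sim_config(
    n_localities = 2, n_transects = 1, n_points = 5, perchas_per_point = 4,
    ind_per_percha = 8, cluster_divergence = 0.02, sib_clutch_rate = 0,
    selfing_rate = 0, null_allele_freq = 0, missing_rate = 0, seed = 12))
  plain <- ena_corrected_fst(sim$table, sim$hierarchy, level = "locality",
                             n_boot = 50, seed = 1, correct = FALSE)
  ena <- ena_corrected_fst(sim$table, sim$hierarchy, level = "locality",
                           n_boot = 50, seed = 1, correct = TRUE)
  expect_lt(abs(plain$fst[1, 2] - ena$fst[1, 2]), 0.01)
  expect_lte(ena$ci_lo[1, 2], ena$fst[1, 2])
  expect_gte(ena$ci_hi[1, 2], ena$fst[1, 2])

  # equal-frequency populations with strong nulls: uncorrected estimate
  # is biased upward relative to the ENA estimate (paired replicates)
  diffs <- vapply(1:6, function(r) {
    sim0 <- simulate_dataset(sim_config(
      n_localities = 2, n_transects = 1, n_points = 4, perchas_per_point = 4,
      ind_per_percha = 8, n_clusters = 1, cluster_divergence = 0,
      sib_clutch_rate = 0, selfing_rate = 0,
      null_allele_freq = rep(c(0.25, 0), each = 5), missing_rate = 0,
      seed = 300 + r))
    u <- ena_corrected_fst(sim0$table, sim0$hierarchy, level = "locality",
                           n_boot = 2, seed = 1, correct = FALSE)
    e <- ena_corrected_fst(sim0$table, sim0$hierarchy, level = "locality",
                           n_boot = 2, seed = 1, correct = TRUE)
    u$fst[1, 2] - e$fst[1, 2]
  }, 0)
  expect_gt(mean(diffs), 0)
})
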