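test_that("allele frequencies are simple observed-count ratios", {
  tab <- make_tab(list(list(c(100L, 100L)), list(c(100L, 102L))))
  ft <- allele_frequencies(tab, NULL, "global")
  expect_equal(ft$strata[[1]]$freq[[1]],
               c("100" = 0.75, "102" = 0.25))
  # all-missing locus gives an empty map
  tab2 <- make_tab(list(list(c(100L, 100L), NA), list(c(100L, 102L), NA)))
  ft2 <- allele_frequencies(tab2, NULL, "global")
  expect_length(ft2$strata[[1]]$freq[[2]], 0)
  expect_equal(unname(ft2$strata[[1]]$n_typed[2]), 0L)
})

test_that("FIS = 1 - Ho/uHe reproduces published-style arithmetic", {
  expect_equal(round(1 - 0.22 / 0.93, 2), 0.76)
  # computed from genotype data: construct a sample with known Ho and uHe
  # 9 heterozygotes of 12 individuals across 4 alleles
  g <- c(rep(list(list(c(1L, 2L))), 5), rep(list(list(c(3L, 4L))), 4),
         rep(list(list(c(1L, 1L))), 3))
  tab <- make_tab(g)
  ds <- diversity_summary(tab, flat_hier(tab$ind))
  ho <- 9 / 12
  p <- c(11, 5, 4, 4) / 24
  uhe <- (24 / 23) * (1 - sum(p^2))
  expect_equal(ds$per_locus$Ho, ho)
  expect_equal(ds$per_locus$uHe, uhe)
  expect_equal(ds$per_locus$FIS, 1 - ho / uhe)
})

test_that("monomorphic locus yields Ho = 0, uHe = 0, FIS = NA", {
  tab <- make_tab(rep(list(list(c(5L, 5L))), 6))
  ds <- diversity_summary(tab, flat_hier(tab$ind))
  expect_equal(ds$per_locus$Ho, 0)
  expect_equal(ds$per_locus$uHe, 0)
  expect_true(is.na(ds$per_locus$FIS))
})

test_that("private alleles are counted at the site level", {
  h <- hierarchy(sprintf("i%03d", 1:4), rep("A", 4), c("A1", "A1", "A2", "A2"),
                 rep(0L, 4), rep("q1", 4))
  tab <- make_tab(list(list(c(1L, 2L)), list(c(1L, 1L)),
                       list(c(1L, 3L)), list(c(3L, 4L))))
  ds <- diversity_summary(tab, h)
  pap <- stats::setNames(ds$private$PAP, ds$private$site)
  expect_equal(pap[["A1"]], 1L)  # allele 2 only in A1
  expect_equal(pap[["A2"]], 2L)  # alleles 3, 4 only in A2
})

test_that("PI and PIsibs match brute-force enumeration", {
  # two equifrequent alleles: closed-form check
  tab <- make_tab(list(list(c(1L, 1L), c(1L, 1L)), list(c(2L, 2L), c(2L, 2L))))
  ft <- allele_frequencies(tab, NULL, "global")
  pio <- probability_of_identity(ft)
  expect_equal(pio$per_locus$PI, c(0.375, 0.375))
  expect_equal(pio$per_locus$PIsibs, c(0.59375, 0.59375))
  expect_equal(pio$PI, 0.140625)

  # random frequency vectors against the parental-enumeration oracle
  set.seed(31)
  for (k in c(2, 3, 5)) {
    p <- as.numeric(rmultinom(1, 60, rep(1, k))) + 1
    p <- p / sum(p)
    oracle <- pi_enumerate(p)
    s2 <- sum(p^2); s4 <- sum(p^4)
    expect_equal(2 * s2^2 - s4, oracle$PI, tolerance = 1e-12)
    expect_equal(0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4, oracle$PIsibs,
                 tolerance = 1e-12)
  }

  # fixed single allele forces identity
  tab3 <- make_tab(rep(list(list(c(7L, 7L))), 3))
  pio3 <- probability_of_identity(allele_frequencies(tab3, NULL, "global"))
  expect_equal(pio3$PI, 1)
  expect_equal(pio3$PIsibs, 1)
})

test_that("PI <= PIsibs over random Dirichlet frequency vectors", {
  set.seed(8)
  for (r in 1:50) {
    k <- sample(2:20, 1)
    g <- rgamma(k, 0.5); p <- g / sum(g)
    s2 <- sum(p^2); s4 <- sum(p^4)
    pi_ <- 2 * s2^2 - s4
    pis <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
    expect_lte(pi_, pis)
  }
})

test_that("null-allele EM: clean HWE data give near-zero null frequency and
           the observed-data log-likelihood is monotone", {
  sim <- simulate_dataset(sim_config(
    n_localities = 1, n_transects = 1, n_points = 6, perchas_per_point = 5,
    ind_per_percha = 10, n_clusters = 1, sib_clutch_rate = 0,
    selfing_rate = 0, null_allele_freq = 0, missing_rate = 0, seed = 13))
  em <- null_allele_em(sim$table, level = "global")
  expect_lt(mean(em$null_freq), 0.03)
  expect_true(all(em$null_freq >= 0 & em$null_freq <= 1))

  # monotonicity: re-run EM step by step on one locus
  a <- sim$table$a[, 1]; b <- sim$table$b[, 1]
  lls <- vapply(c(1, 2, 5, 10, 50), function(maxit)
    finekin:::em_null_locus(a, b, tol = 0, max_iter = maxit)$loglik, 0)
  expect_true(all(diff(lls) >= -1e-9))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(2)
  p <- runif(40)
  expect_equal(bh_fdr(p), bh_naive(p), tolerance = 1e-12)
  expect_true(all(bh_fdr(p) >= p))
})
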