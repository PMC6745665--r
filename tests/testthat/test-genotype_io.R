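test_that("a toy GenAlEx CSV parses, with 0,0 read as missing", {
  csv <- c("2,2,1,2",
           "toy,,,A_A1_p00_q1",
           "Ind,Pop,L1,,L2,",
           "s1,A_A1_p00_q1,100,102,0,0",
           "s2,A_A1_p00_q1,100,100,140,142")
  f <- tempfile(fileext = ".csv"); writeLines(csv, f)
  x <- read_genalex(f)
  expect_equal(dim(x$table), c(2L, 2L))
  expect_true(is.na(x$table$a[1, 2]) && is.na(x$table$b[1, 2]))
  expect_equal(x$table$a[2, 1], 100L)
  expect_equal(x$hierarchy$point_m, c(0L, 0L))
  expect_equal(x$hierarchy$locality, c("A", "A"))
})

test_that("malformed files raise informative errors", {
  base <- c("2,3,1,3",
            "toy,,,A_A1_p00_q1",
            "Ind,Pop,L1,,L2,",
            "s1,A_A1_p00_q1,100,102,140,140",
            "s2,A_A1_p00_q1,100,100,140,142")
  f <- tempfile(fileext = ".csv")
  writeLines(base, f)  # declares 3 individuals, has 2
  expect_error(read_genalex(f), "format error.*2 data rows")

  bad <- base; bad[1] <- "2,2,1,2"; bad[3] <- "Ind,Pop,L1,,L2"
  bad[4] <- "s1,A_A1_p00_q1,100,102,140"
  writeLines(bad, f)
  expect_error(read_genalex(f), "format error")

  dup <- base; dup[1] <- "2,2,1,2"; dup[5] <- "s1,A_A1_p00_q1,100,100,140,142"
  writeLines(dup, f)
  expect_error(read_genalex(f), "duplicate individual")
})

test_that("write/read round-trips random synthetic tables exactly", {
  for (seed in c(1, 22)) {
    sim <- simulate_dataset(sim_config(
      n_localities = 2, n_transects = 1, n_points = 2,
      perchas_per_point = 2, ind_per_percha = 4,
      missing_rate = 0.1, null_allele_freq = 0.05, seed = seed))
    f <- tempfile(fileext = ".csv")
    write_genalex(sim$table, sim$hierarchy, f)
    rt <- read_genalex(f)
    i <- match(sim$table$ind, rt$table$ind)
    expect_identical(rt$table$a[i, ], sim$table$a)
    expect_identical(rt$table$b[i, ], sim$table$b)
    h <- rt$hierarchy[match(sim$hierarchy$individual,
                            rt$hierarchy$individual), ]
    rownames(h) <- NULL
    expect_equal(as.data.frame(h), as.data.frame(sim$hierarchy))
  }
})

test_that("long TSV dialect reads the same data", {
  sim <- simulate_dataset(sim_config(
    n_localities = 1, n_transects = 1, n_points = 2, perchas_per_point = 2,
    ind_per_percha = 3, missing_rate = 0.1, seed = 5))
  h <- sim$hierarchy
  d <- data.frame(individual = rep(sim$table$ind, each = 10),
                  locality = rep(h$locality, each = 10),
                  transect = rep(h$transect, each = 10),
                  point_m = rep(h$point_m, each = 10),
                  percha = rep(h$percha, each = 10),
                  locus = rep(sim$table$loci, times = length(sim$table$ind)),
                  allele_a = as.vector(t(ifelse(is.na(sim$table$a), 0L,
                                                sim$table$a))),
                  allele_b = as.vector(t(ifelse(is.na(sim$table$b), 0L,
                                                sim$table$b))))
  f <- tempfile(fileext = ".tsv")
  write.table(d, f, sep = "\t", row.names = FALSE, quote = FALSE)
  x <- read_genalex(f, dialect = "long_tsv")
  expect_identical(x$table$a, sim$table$a)
  expect_identical(x$table$b, sim$table$b)
})

test_that("half-missing genotypes are promoted to fully missing", {
  expect_warning(
    tab <- genotab(matrix(c(100L, NA), 1), matrix(c(102L, 104L), 1),
                   "s1", c("L1", "L2")),
    "half-missing")
  expect_true(is.na(tab$b[1, 2]))
})

test_that("locus names containing the separator are rejected on write", {
  tab <- make_tab(list(list(c(100L, 102L))), loci = "bad,name")
  expect_error(write_genalex(tab, flat_hier(tab$ind), tempfile()),
               "separator")
})

test_that("filter_by_missing applies the more-than-max rule exactly", {
  g <- lapply(1:3, function(i) {
    gl <- rep(list(c(100L, 102L)), 10)
    if (i == 1) gl[1:3] <- list(NA)  # 3 missing -> removed
    if (i == 2) gl[1:2] <- list(NA)  # 2 missing -> retained
    gl
  })
  tab <- make_tab(g)
  res <- filter_by_missing(tab, flat_hier(tab$ind))
  expect_equal(res$summary$n_total, 3L)
  expect_equal(res$summary$n_retained, 2L)
  expect_false("i001" %in% res$table$ind)
  expect_true(all(c("i002", "i003") %in% res$table$ind))

  # no-op on a complete table
  full <- make_tab(rep(list(rep(list(c(1L, 2L)), 10)), 4))
  res2 <- filter_by_missing(full)
  expect_equal(res2$summary$n_retained, res2$summary$n_total)

  # idempotent, monotone in the threshold
  again <- filter_by_missing(res$table, max_missing_loci = 2)
  expect_identical(again$table$ind, res$table$ind)
  stricter <- filter_by_missing(tab, max_missing_loci = 1)
  expect_lte(stricter$summary$n_retained, res$summary$n_retained)
})
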