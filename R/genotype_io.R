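#' Read a codominant genotype table with hierarchical sample metadata
#'
#' Two dialects are supported.
#'
#' `"genalex_csv"` is the GenAlEx codominant layout: three header rows
#' followed by one row per individual.  Row 1 holds the counts
#' `n_loci, n_individuals, n_pops, size_pop1, ..., size_popP`; row 2 holds a
#' dataset title in the first cell and the population names aligned with
#' their sizes from column 4 onwards; row 3 holds `Ind, Pop`, then each
#' locus name followed by one blank cell (loci occupy two allele columns).
#' Data rows are `id, pop, allele1a, allele1b, allele2a, ...` with `0`
#' coding a missing allele.  The population label encodes the hierarchy as
#' `locality_transect_pointcode_percha` (for example `ME_ME01_p10_A`),
#' where the point code is `p` followed by metres along the transect.
#'
#' `"long_tsv"` is a tab-separated long table with the columns
#' `individual, locality, transect, point_m, percha, locus, allele_a,
#' allele_b` and one row per individual x locus.
#'
#' A genotype with exactly one missing allele is promoted to fully missing
#' with a warning.
#'
#' @param path path to the input file.
#' @param dialect `"genalex_csv"` (default) or `"long_tsv"`.
#' @param sep separator between hierarchy fields inside the GenAlEx
#'   population label.
#' @return a list with elements `table` (a [genotab()]) and `hierarchy`
#'   (a [hierarchy()] data.frame).
#' @seealso [write_genalex()], [filter_by_missing()]
#' @export
read_genalex <- function(path, dialect = c("genalex_csv", "long_tsv"),
                         sep = "_") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "long_tsv") return(read_long_tsv(path))

  lines <- readLines(path)
  if (length(lines) < 3)
    stop("format error: expected 3 header rows, file has ", length(lines),
         " line(s)")
  cells <- lapply(lines, function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  hdr <- suppressWarnings(as.integer(cells[[1]]))
  if (length(hdr) < 3 || anyNA(hdr[1:3]))
    stop("format error: line 1 must start with n_loci,n_individuals,n_pops")
  n_loci <- hdr[1]; n_ind <- hdr[2]; n_pop <- hdr[3]
  if (length(hdr) < 3 + n_pop || anyNA(hdr[seq_len(n_pop) + 3]))
    stop("format error: line 1 lacks the ", n_pop, " population sizes")
  if (sum(hdr[seq_len(n_pop) + 3]) != n_ind)
    stop("format error: line 1 population sizes do not sum to the declared ",
         "individual count")

  h3 <- cells[[3]]
  # strsplit drops trailing empty fields; pad the locus header row
  if (length(h3) == 1 + 2 * n_loci) h3 <- c(h3, "")
  if (length(h3) != 2 + 2 * n_loci)
    stop("schema error: line 3 has ", length(h3) - 2,
         " allele columns for ", n_loci,
         " loci (need an even count, two per locus)")
  loci <- h3[seq(3, by = 2, length.out = n_loci)]
  if (any(loci == "")) stop("schema error: empty locus name on line 3")

  body <- cells[-(1:3)]
  body <- body[vapply(body, function(x) any(nzchar(x)), logical(1))]
  if (length(body) != n_ind)
    stop("format error: declared ", n_ind, " individuals but found ",
         length(body), " data rows")
  bad <- which(vapply(body, length, integer(1)) != 2 + 2 * n_loci)
  if (length(bad))
    stop("format error: data line ", bad[1] + 3, " has ",
         length(body[[bad[1]]]), " fields, expected ", 2 + 2 * n_loci)

  ids <- vapply(body, `[`, "", 1)
  pops <- vapply(body, `[`, "", 2)
  al <- t(vapply(body, function(x) {
    v <- suppressWarnings(as.integer(x[-(1:2)]))
    v
  }, integer(2 * n_loci)))
  if (anyNA(al)) stop("format error: non-integer allele value in body")
  al[al == 0L] <- NA_integer_
  a <- al[, seq(1, 2 * n_loci, 2), drop = FALSE]
  b <- al[, seq(2, 2 * n_loci, 2), drop = FALSE]
  tab <- genotab(a, b, ids, loci)

  parts <- strsplit(pops, sep, fixed = TRUE)
  nfield <- vapply(parts, length, integer(1))
  if (any(nfield != 4))
    stop("validation error: population label '", pops[nfield != 4][1],
         "' does not follow locality", sep, "transect", sep, "point", sep,
         "percha")
  pm <- vapply(parts, function(p) {
    suppressWarnings(as.integer(sub("^p", "", p[3])))
  }, integer(1))
  if (anyNA(pm))
    stop("validation error: point code must be 'p<metres>'")
  hier <- hierarchy(individual = ids,
                    locality = vapply(parts, `[`, "", 1),
                    transect = vapply(parts, `[`, "", 2),
                    point_m = pm,
                    percha = vapply(parts, `[`, "", 4))
  list(table = tab, hierarchy = hier)
}

read_long_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "locality", "transect", "point_m", "percha",
            "locus", "allele_a", "allele_b")
  if (!all(need %in% names(d)))
    stop("schema error: long TSV must have columns ",
         paste(need, collapse = ", "))
  ids <- unique(d$individual)
  loci <- unique(d$locus)
  a <- matrix(NA_integer_, length(ids), length(loci))
  b <- a
  ri <- match(d$individual, ids); ci <- match(d$locus, loci)
  aa <- as.integer(d$allele_a); bb <- as.integer(d$allele_b)
  aa[aa == 0L] <- NA_integer_; bb[bb == 0L] <- NA_integer_
  a[cbind(ri, ci)] <- aa; b[cbind(ri, ci)] <- bb
  tab <- genotab(a, b, ids, loci)
  first <- d[!duplicated(d$individual), ]
  hier <- hierarchy(first$individual, first$locality, first$transect,
                    first$point_m, first$percha)
  list(table = tab, hierarchy = align_hierarchy(tab, hier))
}

#' Write a genotype table in the GenAlEx CSV dialect
#'
#' Emits the same three-header-row layout that [read_genalex()] accepts;
#' missing alleles are written as `0`.  Individuals are grouped by
#' population label (locality_transect_point_percha) so that the declared
#' per-population sizes refer to contiguous row blocks.
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()] covering every individual in `table`.
#' @param path output path.
#' @param title dataset title placed in header row 2.
#' @param sep hierarchy-field separator used in the population label.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(table, hier, path, title = "finekin export",
                          sep = "_") {
  stopifnot(inherits(table, "genotab"))
  hier <- align_hierarchy(table, hier)
  if (any(grepl(",", table$loci, fixed = TRUE)))
    stop("locus name contains the field separator ','; rename the locus")
  pop <- paste(hier$locality, hier$transect,
               sprintf("p%02d", hier$point_m), hier$percha, sep = sep)
  if (any(grepl(",", pop, fixed = TRUE)))
    stop("hierarchy label contains the field separator ','")
  ord <- order(match(pop, unique(pop)))
  pop <- pop[ord]
  sizes <- table(factor(pop, levels = unique(pop)))
  n_loci <- length(table$loci)

  a <- table$a[ord, , drop = FALSE]; b <- table$b[ord, , drop = FALSE]
  a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
  inter <- matrix("", nrow(a), 2 * n_loci)
  if (nrow(a)) {
    inter[, seq(1, 2 * n_loci, 2)] <- a
    inter[, seq(2, 2 * n_loci, 2)] <- b
  }
  l1 <- paste(c(n_loci, length(table$ind), length(sizes), as.integer(sizes)),
              collapse = ",")
  l2 <- paste(c(title, "", "", names(sizes)), collapse = ",")
  h3 <- character(2 * n_loci)
  h3[seq(1, 2 * n_loci, 2)] <- table$loci
  l3 <- paste(c("Ind", "Pop", h3), collapse = ",")
  rows <- if (nrow(a))
    paste(table$ind[ord], pop, apply(inter, 1, paste, collapse = ","),
          sep = ",")
  else character(0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(l1, l2, l3, rows), con)
  invisible(path)
}

#' Filter individuals by number of missing loci
#'
#' Individuals with more than `max_missing_loci` fully missing loci are
#' removed (the default 2 keeps samples typed at eight or more of ten
#' loci).  Half-missing genotypes never occur inside a `genotab`, so only
#' fully missing loci are counted.
#'
#' @param table a [genotab()].
#' @param hier optional [hierarchy()]; if given it is subset in step and the
#'   per-site retained counts are tabulated.
#' @param max_missing_loci maximum tolerated number of missing loci.
#' @return list with `table` (filtered), `hierarchy` (filtered, or `NULL`),
#'   and `summary`: a list with `n_total`, `n_retained`, and `per_site`
#'   retained counts.
#' @export
filter_by_missing <- function(table, hier = NULL, max_missing_loci = 2) {
  stopifnot(inherits(table, "genotab"), max_missing_loci >= 0)
  keep <- n_missing_loci(table) <= max_missing_loci
  out <- table[keep, ]
  per_site <- NULL
  if (!is.null(hier)) {
    hier <- align_hierarchy(table, hier)[keep, , drop = FALSE]
    per_site <- as.data.frame(table(site = hier$transect),
                              stringsAsFactors = FALSE)
    names(per_site)[2] <- "n"
  }
  list(table = out, hierarchy = hier,
       summary = list(n_total = length(table$ind),
                      n_retained = length(out$ind),
                      per_site = per_site))
}
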