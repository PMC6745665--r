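#' Construct a codominant genotype table
#'
#' A `genotab` stores two-allele-per-locus genotypes for a set of diploid
#' individuals.  Alleles are integer fragment sizes in base pairs; a missing
#' genotype has both alleles `NA`.  Within each genotype the two alleles are
#' stored in ascending order, so a genotype is an unordered pair.
#'
#' @param a,b integer matrices (individuals x loci) holding the two alleles
#'   of each genotype.  `NA` marks missing data; a genotype must be either
#'   fully missing or fully present.
#' @param ind character vector of unique individual identifiers (rows).
#' @param loci character vector of unique locus names (columns).
#' @return an object of class `genotab`: a list with elements `ind`, `loci`,
#'   `a`, `b`.  The allele matrices carry `ind`/`loci` as dimnames and
#'   satisfy `a <= b` wherever typed.
#' @examples
#' g <- genotab(a = matrix(c(100L, 102L), 1), b = matrix(c(104L, 102L), 1),
#'              ind = "i1", loci = c("L1", "L2"))
#' n_missing_loci(g)
#' @export
genotab <- function(a, b, ind, loci) {
  a <- as.matrix(a); b <- as.matrix(b)
  storage.mode(a) <- "integer"; storage.mode(b) <- "integer"
  if (!identical(dim(a), dim(b)))
    stop("allele matrices 'a' and 'b' must have identical dimensions")
  if (nrow(a) != length(ind) || ncol(a) != length(loci))
    stop("allele matrix dimensions do not match 'ind'/'loci' lengths")
  if (anyDuplicated(ind))
    stop("duplicate individual ID: ",
         paste(unique(ind[duplicated(ind)]), collapse = ", "))
  if (anyDuplicated(loci)) stop("duplicate locus names")
  half <- xor(is.na(a), is.na(b))
  if (any(half)) {
    warning(sum(half), " half-missing genotype(s) promoted to fully missing")
    a[half] <- NA_integer_; b[half] <- NA_integer_
  }
  # canonical unordered storage: a <= b
  swap <- !is.na(a) & a > b
  if (any(swap)) {
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  dimnames(a) <- dimnames(b) <- list(ind, loci)
  structure(list(ind = as.character(ind), loci = as.character(loci),
                 a = a, b = b),
            class = "genotab")
}

#' @export
print.genotab <- function(x, ...) {
  cat("genotab: ", length(x$ind), " individuals x ", length(x$loci),
      " loci\n", sep = "")
  miss <- mean(is.na(x$a))
  cat(sprintf("missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotab <- function(x) c(length(x$ind), length(x$loci))

#' Subset a genotype table by individuals and/or loci
#'
#' @param x a [genotab()].
#' @param i individual index (integer, logical, or character IDs).
#' @param j locus index.
#' @param ... ignored.
#' @return a `genotab` restricted to the selected rows/columns.
#' @export
`[.genotab` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$ind)
  if (missing(j)) j <- seq_along(x$loci)
  if (is.character(i)) i <- match(i, x$ind)
  if (is.character(j)) j <- match(j, x$loci)
  genotab(x$a[i, j, drop = FALSE], x$b[i, j, drop = FALSE],
          x$ind[i], x$loci[j])
}

#' Number of missing loci per individual
#'
#' @param x a [genotab()].
#' @return named integer vector: per individual, the count of loci with a
#'   fully missing genotype.
#' @export
n_missing_loci <- function(x) {
  stopifnot(inherits(x, "genotab"))
  rowSums(is.na(x$a))
}

#' Construct / validate a sampling hierarchy
#'
#' The sampling design is nested: locality > transect > point (metres along
#' a 50 m transect, multiples of 10) > percha (a natural aggregate of
#' individuals collected within one metre of the point).
#'
#' @param individual,locality,transect,percha character vectors.
#' @param point_m integer metres along the transect; must lie in
#'   `{0, 10, 20, 30, 40, 50}`.
#' @return a data.frame of class `hierarchy` with one row per individual.
#' @export
hierarchy <- function(individual, locality, transect, point_m, percha) {
  point_m <- as.integer(point_m)
  if (anyDuplicated(individual))
    stop("duplicate individual ID in hierarchy")
  if (!all(point_m %in% seq(0L, 50L, 10L)))
    stop("point_m must be a multiple of 10 in [0, 50]")
  h <- data.frame(individual = as.character(individual),
                  locality = as.character(locality),
                  transect = as.character(transect),
                  point_m = point_m,
                  percha = as.character(percha),
                  stringsAsFactors = FALSE)
  class(h) <- c("hierarchy", "data.frame")
  h
}

# align a hierarchy to a genotab's individuals (every individual must have
# exactly one record); returns the reordered hierarchy
align_hierarchy <- function(tab, hier) {
  idx <- match(tab$ind, hier$individual)
  if (anyNA(idx))
    stop("hierarchy is missing individuals: ",
         paste(utils::head(tab$ind[is.na(idx)], 5), collapse = ", "))
  hier[idx, , drop = FALSE]
}

# stratum labels per individual for a grouping level
stratum_labels <- function(hier, level = c("site", "locality", "global",
                                           "point", "percha")) {
  level <- match.arg(level)
  switch(level,
         global   = rep("all", nrow(hier)),
         locality = hier$locality,
         site     = hier$transect,
         point    = paste(hier$transect, sprintf("p%02d", hier$point_m),
                          sep = "."),
         percha   = paste(hier$transect, sprintf("p%02d", hier$point_m),
                          hier$percha, sep = "."))
}
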