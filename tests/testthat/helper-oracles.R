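# Independent reference implementations used as oracles.  These are
# deliberately naive transliterations of the published formulas (loops,
# no shared code with the package internals).

# --- Lynch-Ritland relatedness, one pair, plain loop ----------------------
lr_pair_naive <- function(g1, g2, freqs) {
  # g1, g2: list per locus of c(a, b) or NULL if missing
  # freqs: list per locus of named frequency vectors
  directed <- function(ref, pro) {
    num <- den <- 0
    for (l in seq_along(freqs)) {
      if (is.null(ref[[l]]) || is.null(pro[[l]])) next
      p <- freqs[[l]]
      a <- as.character(ref[[l]][1]); b <- as.character(ref[[l]][2])
      c_ <- pro[[l]][1]; d_ <- pro[[l]][2]
      pa <- p[[a]]; pb <- p[[b]]
      Sab <- as.numeric(ref[[l]][1] == ref[[l]][2])
      Sac <- as.numeric(ref[[l]][1] == c_); Sad <- as.numeric(ref[[l]][1] == d_)
      Sbc <- as.numeric(ref[[l]][2] == c_); Sbd <- as.numeric(ref[[l]][2] == d_)
      denom <- (1 + Sab) * (pa + pb) - 4 * pa * pb
      if (denom <= 1e-12 || pa <= 0 || pb <= 0) next
      r <- (pa * (Sbc + Sbd) + pb * (Sac + Sad) - 4 * pa * pb) / denom
      w <- denom / (2 * pa * pb)
      num <- num + w * r
      den <- den + w
    }
    if (den > 0) num / den else NA_real_
  }
  mean(c(directed(g1, g2), directed(g2, g1)), na.rm = TRUE)
}

# --- Loiselle kinship, one pair, explicit allele-indicator sums -----------
loiselle_pair_naive <- function(g1, g2, freqs, n_typed) {
  num <- den <- 0
  for (l in seq_along(freqs)) {
    if (is.null(g1[[l]]) || is.null(g2[[l]])) next
    p <- freqs[[l]]
    if (sum(p * (1 - p)) <= 1e-12) next
    x1 <- x2 <- stats::setNames(numeric(length(p)), names(p))
    for (al in as.character(g1[[l]])) x1[al] <- x1[al] + 0.5
    for (al in as.character(g2[[l]])) x2[al] <- x2[al] + 0.5
    num <- num + sum((x1 - p) * (x2 - p)) +
      sum(p * (1 - p)) / (2 * n_typed[l] - 1)
    den <- den + sum(p * (1 - p))
  }
  if (den > 0) unname(num / den) else NA_real_
}

# --- probabilities of identity by brute-force enumeration -----------------
# PI: sum over unordered genotypes of P(g)^2.
# PIsibs: enumerate both parents' ordered genotypes, then the exact
# offspring genotype distribution, and sum P(both sibs get genotype g).
pi_enumerate <- function(p) {
  k <- length(p)
  gen <- list(); pg <- numeric(0)
  for (i in 1:k) for (j in i:k) {
    gen[[length(gen) + 1]] <- c(i, j)
    pg <- c(pg, if (i == j) p[i]^2 else 2 * p[i] * p[j])
  }
  PI <- sum(pg^2)
  PIsibs <- 0
  for (m1 in 1:k) for (m2 in 1:k) for (f1 in 1:k) for (f2 in 1:k) {
    pp <- p[m1] * p[m2] * p[f1] * p[f2]
    # offspring genotype distribution given parents
    off <- stats::setNames(numeric(length(gen)),
                           vapply(gen, paste, "", collapse = "."))
    for (am in c(m1, m2)) for (af in c(f1, f2)) {
      g <- sort(c(am, af))
      key <- paste(g, collapse = ".")
      off[key] <- off[key] + 0.25
    }
    PIsibs <- PIsibs + pp * sum(off^2)
  }
  list(PI = PI, PIsibs = PIsibs)
}

# --- one-locus full-sib likelihood ratio by parental enumeration ----------
sib_lr_enumerate <- function(g1, g2, p) {
  k <- length(p)
  num <- 0  # P(g1, g2 | full sibs)
  pg <- function(g) if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]]
  for (m1 in 1:k) for (m2 in 1:k) for (f1 in 1:k) for (f2 in 1:k) {
    pp <- p[m1] * p[m2] * p[f1] * p[f2]
    if (pp == 0) next
    p1 <- p2 <- 0
    for (am in c(m1, m2)) for (af in c(f1, f2)) {
      g <- sort(c(am, af))
      if (all(g == sort(g1))) p1 <- p1 + 0.25
      if (all(g == sort(g2))) p2 <- p2 + 0.25
    }
    num <- num + pp * p1 * p2
  }
  num / (pg(sort(g1)) * pg(sort(g2)))
}

# --- Benjamini-Hochberg step-up by definition -----------------------------
bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, m / r * p[o[r]])
    adj[o[r]] <- val
    prev <- val
  }
  adj
}

# --- AMOVA sums of squares from explicit pairwise allele distances --------
# allele copies with labels; squared distance 1 between distinct labels.
ss_pairwise_naive <- function(labels) {
  n <- length(labels)
  if (n < 2) return(0)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    s <- s + as.numeric(labels[i] != labels[j])
  s / n
}

# --- small helpers --------------------------------------------------------
# build a genotab from a list of individuals: list(locus -> c(a, b) or NA)
make_tab <- function(geno_list, loci = NULL) {
  n <- length(geno_list)
  L <- length(geno_list[[1]])
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  a <- b <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) for (l in seq_len(L)) {
    g <- geno_list[[i]][[l]]
    if (!is.null(g) && !anyNA(g)) { a[i, l] <- g[1]; b[i, l] <- g[2] }
  }
  genotab(a, b, sprintf("i%03d", seq_len(n)), loci)
}

flat_hier <- function(ids, locality = "A", transect = "A1") {
  hierarchy(ids, rep(locality, length(ids)), rep(transect, length(ids)),
            rep(0L, length(ids)), rep("q1", length(ids)))
}
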