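#' Pairwise geographic distances along transects
#'
#' Distance between two individuals on the same transect is the absolute
#' difference of their metres-along-transect positions; individuals at the
#' same point (including the same percha) are at 0 m, since sub-point
#' geometry is not recorded.  Pairs on different transects are `NA`
#' (masked for autocorrelation).
#'
#' @param hier a [hierarchy()].
#' @return symmetric matrix of distances in metres, `NA` off-transect.
#' @export
geographic_distances <- function(hier) {
  n <- nrow(hier)
  d <- abs(outer(hier$point_m, hier$point_m, "-"))
  same <- outer(hier$transect, hier$transect, "==")
  d[!same] <- NA_real_
  dimnames(d) <- list(hier$individual, hier$individual)
  d
}

#' Assign distances to half-open distance classes
#'
#' Classes are `(upper - width, upper]` labelled by their upper bound;
#' the first class is `[0, 0]` so that co-located pairs form their own
#' class.  With the default 10 m width over a 50 m transect this gives the
#' six classes 0, 10, 20, 30, 40, 50.
#'
#' @param d numeric distances (metres).
#' @param width class width (metres).
#' @return integer class labels (the class upper bounds).
#' @export
distance_class <- function(d, width = 10) {
  as.integer(width * ceiling(d / width))
}

#' Multilocus squared genetic distance (Smouse-Peakall)
#'
#' Per locus, genotypes are scored as allele-count vectors `y` and the
#' squared distance is `0.5 * sum((y1 - y2)^2)` (0 for identical
#' genotypes, 1 between a homozygote and a sharing heterozygote, up to 4
#' between distinct homozygotes).  Multilocus distance sums the per-locus
#' values over mutually typed loci, rescaled by `L / L_shared` so pairs
#' with missing loci stay comparable.
#'
#' @param table a [genotab()].
#' @return symmetric matrix of squared distances (0 diagonal).
#' @export
genetic_distance_sp <- function(table) {
  n <- length(table$ind)
  px <- pair_indices(n)
  d <- numeric(length(px$i))
  shared <- integer(length(px$i))
  for (l in seq_along(table$loci)) {
    a1 <- table$a[px$i, l]; b1 <- table$b[px$i, l]
    a2 <- table$a[px$j, l]; b2 <- table$b[px$j, l]
    ok <- !is.na(a1) & !is.na(a2)
    if (!any(ok)) next
    # 0.5 * sum (y1 - y2)^2 = 2 - matches/... derive from match counts:
    # sum y1.y2 = matches/1 counting allele-slot agreements
    m <- (a1 == a2) + (a1 == b2) + (b1 == a2) + (b1 == b2)
    hom1 <- a1 == b1; hom2 <- a2 == b2
    # sum y1^2: hom -> 4, het -> 2; cross term sum y1 y2 = m
    ss <- (2 + 2 * hom1) + (2 + 2 * hom2) - 2 * m
    d[ok] <- d[ok] + 0.5 * ss[ok]
    shared[ok] <- shared[ok] + 1L
  }
  L <- length(table$loci)
  d <- ifelse(shared > 0, d * L / shared, NA_real_)
  out <- matrix(0, n, n, dimnames = list(table$ind, table$ind))
  out[cbind(px$i, px$j)] <- d
  out[cbind(px$j, px$i)] <- d
  out
}

# double-centre a squared-distance matrix to covariance form
centre_sqdist <- function(D) {
  rm <- rowMeans(D); gm <- mean(D)
  -0.5 * (sweep(sweep(D, 1, rm), 2, rm) + gm)
}

# class-wise autocorrelation r from a covariance matrix and pair lists
r_by_class <- function(C, cls_pairs, perm = NULL) {
  idx <- if (is.null(perm)) seq_len(nrow(C)) else perm
  vapply(cls_pairs, function(pp) {
    if (!length(pp$i)) return(NA_real_)
    ii <- idx[pp$i]; jj <- idx[pp$j]
    num <- sum(C[cbind(ii, jj)])
    den <- 0.5 * sum(diag(C)[ii] + diag(C)[jj])
    if (den <= 0) NA_real_ else num / den
  }, 0)
}

#' Multilocus spatial autocorrelogram per transect
#'
#' Computes the multilocus autocorrelation coefficient r per geographic
#' distance class within each transect: the squared genetic distance
#' matrix ([genetic_distance_sp()]) is double-centred to covariance form
#' and r for a class is the ratio of the summed between-individual
#' covariances to the summed within-individual variances over the pairs
#' of that class.  The null 95% envelope around r = 0 comes from
#' permuting individuals among geographic positions; the 95% CI around
#' each observed r comes from bootstrapping pairs within the class.
#'
#' @param table a [genotab()].
#' @param hier a [hierarchy()].
#' @param width distance class width in metres (see [distance_class()]).
#' @param n_perm permutations for the null envelope.
#' @param n_boot bootstrap replicates for the r CIs.
#' @param seed RNG seed.
#' @return data.frame of class `autocorrelogram`: one row per transect x
#'   class with `n_pairs`, `r`, `env_lo`, `env_hi`, `boot_lo`, `boot_hi`;
#'   classes with fewer than 2 pairs have `NA` statistics.
#' @export
autocorrelogram <- function(table, hier, width = 10, n_perm = 9999,
                            n_boot = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hier <- align_hierarchy(table, hier)
  out <- list()
  for (tr in unique(hier$transect)) {
    ids <- hier$individual[hier$transect == tr]
    sub <- table[ids, ]
    h <- hier[match(ids, hier$individual), ]
    D <- genetic_distance_sp(sub)
    C <- centre_sqdist(D)
    G <- abs(outer(h$point_m, h$point_m, "-"))
    n <- length(ids)
    px <- pair_indices(n)
    cls <- distance_class(G[cbind(px$i, px$j)], width)
    ubs <- sort(unique(distance_class(c(0, max(h$point_m) -
                                          min(h$point_m)), width)))
    ubs <- seq(0, max(ubs), by = width)
    cls_pairs <- lapply(ubs, function(u) {
      w <- which(cls == u)
      list(i = px$i[w], j = px$j[w])
    })
    r_obs <- r_by_class(C, cls_pairs)
    perm_r <- matrix(NA_real_, n_perm, length(ubs))
    for (r in seq_len(n_perm))
      perm_r[r, ] <- r_by_class(C, cls_pairs, perm = sample.int(n))
    env <- apply(perm_r, 2, stats::quantile, probs = c(0.025, 0.975),
                 na.rm = TRUE)
    dC <- diag(C)
    for (ci in seq_along(ubs)) {
      pp <- cls_pairs[[ci]]
      np <- length(pp$i)
      if (np < 2) {
        out[[length(out) + 1L]] <- data.frame(
          transect = tr, class = ubs[ci], n_pairs = np, r = NA_real_,
          env_lo = NA_real_, env_hi = NA_real_,
          boot_lo = NA_real_, boot_hi = NA_real_)
        next
      }
      cij <- C[cbind(pp$i, pp$j)]
      dij <- 0.5 * (dC[pp$i] + dC[pp$j])
      bt <- vapply(seq_len(n_boot), function(r) {
        pick <- sample.int(np, replace = TRUE)
        sum(cij[pick]) / sum(dij[pick])
      }, 0)
      out[[length(out) + 1L]] <- data.frame(
        transect = tr, class = ubs[ci], n_pairs = np, r = r_obs[ci],
        env_lo = env[1, ci], env_hi = env[2, ci],
        boot_lo = stats::quantile(bt, 0.025, names = FALSE),
        boot_hi = stats::quantile(bt, 0.975, names = FALSE))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("autocorrelogram", "data.frame")
  res
}

#' Plot an autocorrelogram
#'
#' @param x result of [autocorrelogram()].
#' @param transect transect to plot (default the first).
#' @param ... passed to [plot()].
#' @export
plot.autocorrelogram <- function(x, transect = x$transect[1], ...) {
  d <- x[x$transect == transect, ]
  plot(d$class, d$r, type = "b", pch = 15, xlab = "distance class (m)",
       ylab = "autocorrelation r", main = transect, ...)
  graphics::lines(d$class, d$env_lo, lty = 2, col = "grey40")
  graphics::lines(d$class, d$env_hi, lty = 2, col = "grey40")
  graphics::arrows(d$class, d$boot_lo, d$class, d$boot_hi, angle = 90,
                   code = 3, length = 0.03)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
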