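## Genetic and geographic distance matrices, NJ trees, Mantel tests.

new_distance_matrix <- function(m, labels, metric) {
  dimnames(m) <- list(labels, labels)
  attr(m, "metric") <- metric
  class(m) <- c("msat_dist", "matrix")
  m
}

## per-population allele frequency matrices, one per locus
pop_freqs <- function(gm) {
  tabs <- allele_count_tables(gm)
  lapply(tabs, function(t) {
    rs <- rowSums(t)
    f <- t / ifelse(rs > 0, rs, 1)
    f[rs == 0, ] <- NA_real_
    f
  })
}

#' Cavalli-Sforza & Edwards chord distance between populations
#'
#' `D_C(x, y) = (2 / (pi * L)) * sum_loci sqrt(2 * (1 - sum_a
#' sqrt(x_a y_a)))` with the multi-locus normalization over the `L` loci
#' typed in both populations; loci untyped in either population are
#' skipped and `L` reduced accordingly.
#'
#' @param gm a [genotype_matrix()] with >= 2 populations
#' @return a square `msat_dist` matrix (metric `"D_C"`)
#' @export
chord_distance_matrix <- function(gm) {
  pops <- levels(gm$pop)
  if (length(pops) < 2L) stop("need at least two populations")
  fr <- pop_freqs(gm)
  P <- length(pops)
  d <- matrix(0, P, P)
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    acc <- 0; L <- 0L
    for (t in fr) {
      if (!ncol(t)) next
      x <- t[i, ]; y <- t[j, ]
      if (anyNA(x) || anyNA(y)) next
      s <- sum(sqrt(x * y))
      acc <- acc + sqrt(2 * max(0, 1 - s))
      L <- L + 1L
    }
    d[i, j] <- d[j, i] <- if (L > 0) 2 / (pi * L) * acc else NA_real_
  }
  new_distance_matrix(d, pops, "D_C")
}

## shared alleles between two diploid genotypes: sum over alleles of
## min(count in g1, count in g2), in {0, 1, 2}
shared_alleles <- function(x1, x2, y1, y2) {
  s <- (x1 == y1) + (x1 == y2) + (x2 == y1) + (x2 == y2)
  ## if either genotype is homozygous every match is double-counted
  ifelse(x1 == x2 | y1 == y2, s / 2, s)
}

#' Shared-allele distance between populations
#'
#' For two individuals, the per-locus proportion of shared alleles is
#' `(number of alleles shared)/2`; the individual-pair distance averages
#' this over loci typed in both. `D_AS` between populations is one minus
#' the mean over all cross-population individual pairs.
#'
#' @param gm a [genotype_matrix()] with >= 2 populations
#' @param loci optional integer vector of locus indices (used by the
#'   bootstrap; may repeat loci)
#' @return a square `msat_dist` matrix (metric `"D_AS"`)
#' @export
shared_allele_distance <- function(gm, loci = NULL) {
  pops <- levels(gm$pop)
  if (length(pops) < 2L) stop("need at least two populations")
  if (is.null(loci)) loci <- seq_len(n_loci(gm))
  P <- length(pops)
  idx <- lapply(pops, function(p) which(gm$pop == p))
  d <- matrix(0, P, P)
  a1 <- gm$a1[, loci, drop = FALSE]; a2 <- gm$a2[, loci, drop = FALSE]
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    tot <- 0; np <- 0L
    for (u in idx[[i]]) {
      x1 <- a1[u, ]; x2 <- a2[u, ]
      for (v in idx[[j]]) {
        y1 <- a1[v, ]; y2 <- a2[v, ]
        ok <- !is.na(x1) & !is.na(y1)
        if (!any(ok)) next
        sh <- shared_alleles(x1[ok], x2[ok], y1[ok], y2[ok])
        tot <- tot + mean(sh / 2)
        np <- np + 1L
      }
    }
    d[i, j] <- d[j, i] <- if (np > 0) 1 - tot / np else NA_real_
  }
  new_distance_matrix(d, pops, "D_AS")
}

#' Great-circle distance matrix between sites
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param sites a site table ([read_sites()]) or data frame with
#'   `site_code`, `latitude`, `longitude` in decimal degrees
#' @return a square `msat_dist` matrix in km (metric `"great_circle_km"`)
#' @export
great_circle_matrix <- function(sites) {
  if (anyNA(sites$latitude) || anyNA(sites$longitude))
    stop("missing coordinates")
  R <- 6371.0
  lat <- sites$latitude * pi / 180
  lon <- sites$longitude * pi / 180
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    h <- sin((lat[j] - lat[i]) / 2)^2 +
      cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
    d[i, j] <- d[j, i] <- 2 * R * asin(pmin(1, sqrt(h)))
  }
  new_distance_matrix(d, sites$site_code, "great_circle_km")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via \pkg{ape}.
#'
#' @param d a square `msat_dist` (or plain) distance matrix without `NA`
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(d) {
  m <- unclass(d)
  if (anyNA(m))
    stop("distance matrix has NA cells; prune the affected labels first")
  if (nrow(m) < 3L) stop("need at least three labels")
  ape::nj(stats::as.dist(m))
}

#' Bootstrap NJ tree on shared-allele distances
#'
#' Builds the NJ tree from the full-data `D_AS` matrix, then resamples
#' loci with replacement `n_boot` times; support of each internal edge is
#' the percentage of replicate trees containing the same bipartition,
#' stored in `node.label`.
#'
#' @param gm a [genotype_matrix()]
#' @param n_boot number of bootstrap replicates (>= 1)
#' @param seed integer seed
#' @return a `phylo` tree with bootstrap percentages as node labels
#' @export
bootstrap_nj <- function(gm, n_boot = 100L, seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  set.seed(as.integer(seed))
  main <- nj_tree(shared_allele_distance(gm))
  L <- n_loci(gm)
  reps <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    loci <- sample.int(L, L, replace = TRUE)
    reps[[b]] <- nj_tree(shared_allele_distance(gm, loci = loci))
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- round(100 * counts / n_boot, 1)
  main
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries; one matrix's labels
#' are permuted jointly over rows and columns `n_perm` times. One-tailed
#' (positive association): `p = (number of permuted r >= observed + 1) /
#' (n_perm + 1)`.
#'
#' @param dA,dB square distance matrices over the same labels, same order
#' @param n_perm number of permutations (>= 99; the isolation-by-distance
#'   convention is 999)
#' @param seed integer seed
#' @return list of class `mantel_result` with `r`, `p`, `n_perm`
#' @export
mantel_test <- function(dA, dB, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  A <- unclass(dA); B <- unclass(dB)
  if (!identical(dim(A), dim(B)))
    stop("matrices must have identical dimensions")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("matrix labels differ or are ordered differently")
  set.seed(as.integer(seed))
  lt <- lower.tri(A)
  a <- A[lt]; b <- B[lt]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r_obs <- stats::cor(a, b)
  n <- nrow(A)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    pp <- sample.int(n)
    r_p <- stats::cor(a, B[pp, pp][lt])
    if (r_p >= r_obs - 1e-12) hits <- hits + 1L
  }
  out <- list(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm)
  class(out) <- "mantel_result"
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%d permutations, one-tailed)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Write a distance matrix as square CSV
#' @param d a `msat_dist` matrix
#' @param path output path
#' @export
write_distance_csv <- function(d, path) {
  utils::write.csv(as.data.frame(unclass(d)), path)
  invisible(path)
}
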