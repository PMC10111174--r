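## Per-population diversity, F-statistics, HWE / LD tests, null-allele
## estimators.

## allele frequency list: per locus, a matrix pops x alleles of counts
allele_count_tables <- function(gm) {
  pops <- levels(gm$pop)
  lapply(seq_len(n_loci(gm)), function(j) {
    a <- c(gm$a1[, j], gm$a2[, j])
    p <- factor(rep(as.character(gm$pop), 2L), levels = pops)
    keep <- !is.na(a)
    if (!any(keep)) return(matrix(0L, length(pops), 0L,
                                  dimnames = list(pops, NULL)))
    tab <- table(p[keep], factor(a[keep]))
    m <- matrix(as.integer(tab), nrow = length(pops),
                dimnames = dimnames(tab))
    m
  })
}

## unbiased expected heterozygosity from an allele count vector
## (gene copies); Nei's small-sample correction n/(n-1) (1 - sum p^2)
unbiased_he <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

biased_he <- function(counts) {
  n <- sum(counts)
  if (n < 1) return(NA_real_)
  p <- counts / n
  1 - sum(p^2)
}

## per-locus x population H_O, H_E, typed counts
locuspop_stats <- function(gm, unbiased = TRUE) {
  pops <- levels(gm$pop)
  L <- n_loci(gm)
  ho <- he <- nt <- na_ <- matrix(NA_real_, length(pops), L,
                                  dimnames = list(pops, gm$loci$name))
  tabs <- allele_count_tables(gm)
  for (p in seq_along(pops)) {
    rows <- which(gm$pop == pops[p])
    for (j in seq_len(L)) {
      x1 <- gm$a1[rows, j]; x2 <- gm$a2[rows, j]
      typed <- !is.na(x1)
      nt[p, j] <- sum(typed)
      if (!any(typed)) next
      ho[p, j] <- mean(x1[typed] != x2[typed])
      cnt <- tabs[[j]][p, ]
      he[p, j] <- if (unbiased) unbiased_he(cnt) else biased_he(cnt)
      na_[p, j] <- sum(cnt > 0)
    }
  }
  list(ho = ho, he = he, n_typed = nt, n_alleles = na_, tabs = tabs)
}

#' Per-population diversity table
#'
#' For each population: number of genotyped individuals `n`, total number
#' of alleles over loci `N_A`, private alleles `P_A` (alleles seen in
#' exactly one population), mean observed (`H_O`) and expected (`H_E`)
#' heterozygosity over loci, and `F_IS = 1 - mean(H_O)/mean(H_E)`
#' (ratio of locus means). A final `Mean` row holds arithmetic column
#' means over populations with defined values. Loci with no typed call in
#' a population are skipped for that population's means.
#'
#' @param gm a [genotype_matrix()]
#' @param unbiased use Nei's small-sample correction for `H_E` (default)
#' @return data frame of class `diversity_table`
#' @export
population_diversity <- function(gm, unbiased = TRUE) {
  pops <- levels(gm$pop)
  if (length(pops) < 1L) stop("need at least one population")
  st <- locuspop_stats(gm, unbiased = unbiased)
  if (any(rowSums(st$n_typed, na.rm = TRUE) < 1))
    stop("a population has no typed individual at any locus")
  NA_tot <- rowSums(st$n_alleles, na.rm = TRUE)
  ## private alleles: per locus, alleles with presence in exactly one pop
  PA <- setNames(numeric(length(pops)), pops)
  for (tab in st$tabs) {
    if (!ncol(tab)) next
    pres <- tab > 0
    priv <- which(colSums(pres) == 1L)
    if (length(priv)) {
      owner <- apply(pres[, priv, drop = FALSE], 2, which)
      for (o in owner) PA[o] <- PA[o] + 1
    }
  }
  HO <- rowMeans(st$ho, na.rm = TRUE)
  HE <- rowMeans(st$he, na.rm = TRUE)
  FIS <- 1 - HO / HE
  n <- as.integer(table(gm$pop))
  out <- data.frame(pop = pops, n = n, N_A = as.integer(NA_tot),
                    P_A = as.integer(PA), H_O = HO, H_E = HE,
                    F_IS = FIS, row.names = NULL,
                    stringsAsFactors = FALSE)
  mean_row <- data.frame(pop = "Mean", n = NA_integer_,
                         N_A = as.integer(round(mean(out$N_A))),
                         P_A = as.integer(round(mean(out$P_A))),
                         H_O = mean(out$H_O, na.rm = TRUE),
                         H_E = mean(out$H_E, na.rm = TRUE),
                         F_IS = mean(out$F_IS, na.rm = TRUE),
                         stringsAsFactors = FALSE)
  res <- rbind(out, mean_row)
  class(res) <- c("diversity_table", "data.frame")
  res
}

#' Global F-statistics (Nei 1987 basic statistics)
#'
#' Per locus, from allele counts over `r` populations with harmonic mean
#' sample size `nbar` (typed individuals): observed heterozygosity `Ho`,
#' within-population gene diversity `Hs` (Nei & Chesser small-sample
#' correction), total gene diversity `Ht`. Overall values average the
#' per-locus components (ratio of means):
#' `Fis = 1 - Ho/Hs`, `Fst = (Ht - Hs)/Ht`, `Fit = 1 - Ho/Ht`.
#'
#' @param gm a [genotype_matrix()] with at least two populations
#' @return list of class `fstat_result` with `F_IS`, `F_ST`, `F_IT`,
#'   per-locus components, and a `monomorphic` flag
#' @export
global_fstats <- function(gm) {
  pops <- levels(gm$pop)
  r_all <- length(pops)
  if (r_all < 2L) stop("need at least two populations")
  L <- n_loci(gm)
  st <- locuspop_stats(gm, unbiased = FALSE)
  Ho <- Hs <- Ht <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    use <- which(st$n_typed[, j] > 0)
    if (length(use) < 2L) next
    tab <- st$tabs[[j]][use, , drop = FALSE]
    n_i <- st$n_typed[use, j]
    nbar <- length(use) / sum(1 / n_i)        # harmonic mean, individuals
    freq <- tab / rowSums(tab)
    ho_j <- mean(st$ho[use, j])
    hs_raw <- 1 - mean(rowSums(freq^2))
    hs_j <- nbar / (nbar - 1) * (hs_raw - ho_j / (2 * nbar))
    pbar <- colMeans(freq)
    ht_j <- 1 - sum(pbar^2) + hs_j / (nbar * length(use)) -
      ho_j / (2 * nbar * length(use))
    Ho[j] <- ho_j; Hs[j] <- hs_j; Ht[j] <- ht_j
  }
  ok <- !is.na(Ho)
  if (!any(ok)) stop("no locus typed in two or more populations")
  mHo <- mean(Ho[ok]); mHs <- mean(Hs[ok]); mHt <- mean(Ht[ok])
  mono <- mHt <= .Machine$double.eps
  out <- list(F_IS = if (mHs > 0) 1 - mHo / mHs else NA_real_,
              F_ST = if (!mono) (mHt - mHs) / mHt else NA_real_,
              F_IT = if (!mono) 1 - mHo / mHt else NA_real_,
              per_locus = data.frame(locus = gm$loci$name, Ho = Ho,
                                     Hs = Hs, Ht = Ht),
              Ho = mHo, Hs = mHs, Ht = mHt, monomorphic = mono)
  class(out) <- "fstat_result"
  out
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("F_IS = %.4f  F_ST = %.4f  F_IT = %.4f\n",
              x$F_IS, x$F_ST, x$F_IT))
  if (x$monomorphic) cat("warning: dataset monomorphic, F_ST undefined\n")
  invisible(x)
}

#' Hardy-Weinberg chi-square tests per population and locus
#'
#' Observed genotype counts are compared with Hardy-Weinberg expectations
#' using the chi-square statistic with Yates continuity correction,
#' `sum((|O - E| - 0.5)^2 / E)` over all genotype classes formed by the
#' alleles present. Degrees of freedom are `k(k+1)/2 - k` for `k` alleles.
#' Significance uses a Bonferroni-adjusted level
#' `alpha / (populations x loci)`. Monomorphic cells are recorded as `NA`.
#'
#' @param gm a [genotype_matrix()]
#' @param alpha nominal family-wise level (default 0.05)
#' @return data frame with `pop`, `locus`, `chi2`, `df`, `p`,
#'   `significant`, plus attributes `alpha_adjusted` and `n_tests`
#' @export
hwe_tests <- function(gm, alpha = 0.05) {
  pops <- levels(gm$pop)
  L <- n_loci(gm)
  n_tests <- length(pops) * L
  alpha_adj <- alpha / n_tests
  res <- vector("list", n_tests)
  k_ <- 1L
  for (p in pops) {
    rows <- which(gm$pop == p)
    for (j in seq_len(L)) {
      x1 <- gm$a1[rows, j]; x2 <- gm$a2[rows, j]
      typed <- !is.na(x1)
      x1 <- x1[typed]; x2 <- x2[typed]
      n <- length(x1)
      row <- data.frame(pop = p, locus = gm$loci$name[j],
                        chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                        significant = NA, stringsAsFactors = FALSE)
      if (n >= 1L) {
        alleles <- sort(unique(c(x1, x2)))
        k <- length(alleles)
        if (k >= 2L) {
          cnt <- table(factor(c(x1, x2), levels = alleles))
          freq <- as.numeric(cnt) / (2 * n)
          ## genotype classes
          gobs <- table(factor(paste(pmin(x1, x2), pmax(x1, x2)),
                               levels = {
                                 idx <- which(upper.tri(diag(k), diag = TRUE),
                                              arr.ind = TRUE)
                                 paste(alleles[idx[, 1]], alleles[idx[, 2]])
                               }))
          idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
          eexp <- ifelse(idx[, 1] == idx[, 2],
                         n * freq[idx[, 1]]^2,
                         2 * n * freq[idx[, 1]] * freq[idx[, 2]])
          chi2 <- sum((pmax(abs(as.numeric(gobs) - eexp) - 0.5, 0))^2 /
                        eexp)
          df <- k * (k + 1) / 2 - k
          pval <- stats::pchisq(chi2, df, lower.tail = FALSE)
          row$chi2 <- chi2; row$df <- as.integer(df); row$p <- pval
          row$significant <- pval < alpha_adj
        }
      }
      res[[k_]] <- row; k_ <- k_ + 1L
    }
  }
  out <- do.call(rbind, res)
  attr(out, "alpha_adjusted") <- alpha_adj
  attr(out, "n_tests") <- n_tests
  out
}

#' Linkage-disequilibrium permutation tests per population and locus pair
#'
#' For each population and locus pair, builds the contingency table of
#' unordered genotypes at locus A versus locus B over individuals typed at
#' both, uses its chi-square statistic, and permutes locus B genotypes
#' among individuals within the population. The p-value is
#' `(number of permuted statistics >= observed + 1) / (n_perm + 1)`.
#'
#' @param gm a [genotype_matrix()]
#' @param n_perm number of permutations (>= 100)
#' @param seed integer seed
#' @return data frame with `pop`, `locus1`, `locus2`, `chi2`, `p`
#' @export
ld_tests <- function(gm, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  set.seed(as.integer(seed))
  pops <- levels(gm$pop)
  L <- n_loci(gm)
  if (L < 2L) stop("need at least two loci")
  geno_code <- function(x1, x2)
    paste(pmin(x1, x2), pmax(x1, x2), sep = "/")
  chi2_of <- function(ga, gb) {
    tab <- table(ga, gb)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e, na.rm = TRUE)
  }
  res <- list(); k_ <- 1L
  for (p in pops) {
    rows <- which(gm$pop == p)
    for (j1 in seq_len(L - 1L)) for (j2 in (j1 + 1L):L) {
      typed <- !is.na(gm$a1[rows, j1]) & !is.na(gm$a1[rows, j2])
      row <- data.frame(pop = p, locus1 = gm$loci$name[j1],
                        locus2 = gm$loci$name[j2], chi2 = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE)
      if (sum(typed) >= 2L) {
        rr <- rows[typed]
        ga <- geno_code(gm$a1[rr, j1], gm$a2[rr, j1])
        gb <- geno_code(gm$a1[rr, j2], gm$a2[rr, j2])
        if (length(unique(ga)) > 1L && length(unique(gb)) > 1L) {
          obs <- chi2_of(ga, gb)
          hits <- 0L
          for (b in seq_len(n_perm))
            if (chi2_of(ga, sample(gb)) >= obs - 1e-12) hits <- hits + 1L
          row$chi2 <- obs
          row$p <- (hits + 1) / (n_perm + 1)
        }
      }
      res[[k_]] <- row; k_ <- k_ + 1L
    }
  }
  do.call(rbind, res)
}

#' Null-allele frequency estimators
#'
#' Per locus (over the whole dataset or per population): the Chakraborty
#' estimator `r = (H_E - H_O)/(H_E + H_O)` and the Brookfield (1) estimator
#' `r = (H_E - H_O)/(1 + H_E)`. Negative estimates are clamped to zero and
#' flagged. Monomorphic loci give `NA`.
#'
#' @param gm a [genotype_matrix()]
#' @param by `"dataset"` (default) or `"population"`
#' @param unbiased use unbiased `H_E`
#' @return data frame with `locus` (and `pop`), `H_O`, `H_E`,
#'   `r_chakraborty`, `r_brookfield`, `clamped`
#' @export
null_allele_estimates <- function(gm, by = c("dataset", "population"),
                                  unbiased = TRUE) {
  by <- match.arg(by)
  one <- function(sub, label) {
    st <- locuspop_stats(pool_pops(sub), unbiased = unbiased)
    ho <- st$ho[1, ]; he <- st$he[1, ]
    rc <- (he - ho) / (he + ho)
    rb <- (he - ho) / (1 + he)
    mono <- is.na(he) | he <= 0
    rc[mono] <- NA_real_; rb[mono] <- NA_real_
    clamped <- !is.na(rc) & (rc < 0 | rb < 0)
    rc <- pmax(rc, 0); rb <- pmax(rb, 0)
    data.frame(pop = label, locus = sub$loci$name, H_O = ho, H_E = he,
               r_chakraborty = rc, r_brookfield = rb, clamped = clamped,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (by == "dataset") return(one(gm, "all"))
  do.call(rbind, lapply(levels(gm$pop), function(p)
    one(subset_gm(gm, ind = which(gm$pop == p)), p)))
}

## collapse all populations into one (frequency pooling helper)
pool_pops <- function(gm) {
  g <- gm
  g$pop <- factor(rep("all", n_ind(gm)))
  g
}
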