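#' Individual heterozygosity indices (PHt, Hs_exp, IR, HL)
#'
#' Four per-individual indices used to compare variability between groups
#' in inbred populations:
#' * `PHt`: proportion of heterozygous loci among the individual's typed
#'   loci.
#' * `Hs_exp`: `PHt` standardized by the mean expected heterozygosity of
#'   the individual's typed loci.
#' * `IR` (internal relatedness): `(2H - sum f_i) / (2N - sum f_i)` with
#'   `H` = number of homozygous typed loci, `N` = number of typed loci and
#'   `sum f_i` = sum of reference frequencies of the alleles carried at
#'   homozygous loci (one term per homozygous locus).
#' * `HL` (homozygosity by locus): `sum(E_h) / (sum(E_h) + sum(E_j))`
#'   where `E_h`/`E_j` are the expected heterozygosities of the loci that
#'   are homozygous/heterozygous in the individual.
#'
#' Reference allele frequencies and locus `H_E` are computed over the
#' whole dataset by default, or within the individual's population.
#'
#' @param gm a [genotype_matrix()]
#' @param freq_scope `"dataset"` (default) or `"population"`
#' @return data frame with one row per individual: `ind`, `pop`,
#'   `n_typed`, `PHt`, `Hs_exp`, `IR`, `HL`; all-missing individuals get
#'   an `NA` row
#' @export
individual_heterozygosity <- function(gm,
                                      freq_scope = c("dataset",
                                                     "population")) {
  freq_scope <- match.arg(freq_scope)
  L <- n_loci(gm)
  n <- n_ind(gm)
  freq_for <- function(rows) {
    st <- locuspop_stats(pool_pops(subset_gm(gm, ind = rows)),
                         unbiased = TRUE)
    tabs <- lapply(st$tabs, function(t) {
      v <- t[1, ]
      if (sum(v) > 0) v / sum(v) else v
    })
    list(he = st$he[1, ], freqs = tabs)
  }
  if (freq_scope == "dataset") {
    ref <- freq_for(seq_len(n))
    ref_of <- function(i) ref
  } else {
    refs <- lapply(levels(gm$pop), function(p)
      freq_for(which(gm$pop == p)))
    names(refs) <- levels(gm$pop)
    ref_of <- function(i) refs[[as.character(gm$pop[i])]]
  }
  out <- data.frame(ind = gm$ind, pop = as.character(gm$pop),
                    n_typed = NA_integer_, PHt = NA_real_,
                    Hs_exp = NA_real_, IR = NA_real_, HL = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    x1 <- gm$a1[i, ]; x2 <- gm$a2[i, ]
    typed <- which(!is.na(x1))
    out$n_typed[i] <- length(typed)
    if (!length(typed)) next
    het <- x1[typed] != x2[typed]
    N <- length(typed); H <- sum(!het)
    out$PHt[i] <- mean(het)
    ref <- ref_of(i)
    he_typed <- ref$he[typed]
    mhe <- mean(he_typed, na.rm = TRUE)
    out$Hs_exp[i] <- if (is.finite(mhe) && mhe > 0) out$PHt[i] / mhe else
      NA_real_
    hom_loci <- typed[!het]
    sumf <- 0
    for (j in hom_loci) {
      fr <- ref$freqs[[j]]
      a <- as.character(x1[j])
      sumf <- sumf + if (a %in% names(fr)) fr[[a]] else 0
    }
    out$IR[i] <- if ((2 * N - sumf) > 0) (2 * H - sumf) / (2 * N - sumf)
      else NA_real_
    Eh <- sum(he_typed[!het], na.rm = TRUE)
    Ej <- sum(he_typed[het], na.rm = TRUE)
    out$HL[i] <- if (Eh + Ej > 0) Eh / (Eh + Ej) else NA_real_
  }
  out
}

#' Kruskal-Wallis test with post hoc Dunn comparisons
#'
#' Rank-based Kruskal-Wallis statistic with tie correction, followed by
#' pairwise Dunn z-tests on mean ranks with a multiplicity adjustment
#' (Bonferroni by default).
#'
#' @param values numeric vector of a per-individual index
#' @param groups group labels (>= 2 groups with >= 2 values each)
#' @param p_adjust method passed to [stats::p.adjust()]
#' @return list with `kw_chi2`, `df`, `p`, and a data frame `dunn` of
#'   pairwise `z`, `p_raw`, `p_adj`
#' @export
compare_groups <- function(values, groups, p_adjust = "bonferroni") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 values")
  n <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, groups, mean)
  ni <- as.numeric(table(groups))
  Hstat <- 12 / (n * (n + 1)) * sum(ni * (Rbar - (n + 1) / 2)^2)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- if (C > 0) Hstat / C else 0
  df <- nlevels(groups) - 1L
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  ## Dunn z statistics
  g <- levels(groups)
  pairs <- utils::combn(g, 2)
  sigma2 <- (n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1)))
  z <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    (Rbar[[i]] - Rbar[[j]]) /
      sqrt(sigma2 * (1 / ni[match(i, g)] + 1 / ni[match(j, g)]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                     p_raw = p_raw,
                     p_adj = stats::p.adjust(p_raw, method = p_adjust),
                     row.names = NULL, stringsAsFactors = FALSE)
  list(kw_chi2 = H, df = df, p = p, dunn = dunn)
}

#' Evanno delta-K from clustering run log-likelihoods
#'
#' Given mean log-likelihoods of replicate clustering runs at consecutive
#' `K`, computes `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| /
#' sd(L(K))`. Boundary `K` values and zero-sd rows are `NA`.
#'
#' @param loglik numeric matrix, runs in rows and `K` values in columns;
#'   column names (or `k_values`) give the `K` grid, which must be
#'   consecutive integers
#' @param k_values optional integer vector of `K` values
#' @return data frame of class `cluster_support` with `K`, `mean_L`,
#'   `sd_L`, `deltaK`
#' @export
evanno_delta_k <- function(loglik, k_values = NULL) {
  loglik <- as.matrix(loglik)
  if (is.null(k_values)) {
    k_values <- suppressWarnings(as.integer(colnames(loglik)))
    if (any(is.na(k_values))) k_values <- seq_len(ncol(loglik))
  }
  if (ncol(loglik) < 3L) stop("need >= 3 consecutive K values")
  if (nrow(loglik) < 2L) stop("need >= 2 runs per K")
  if (any(diff(k_values) != 1L)) stop("K values must be consecutive")
  mL <- colMeans(loglik)
  sL <- apply(loglik, 2, stats::sd)
  dK <- rep(NA_real_, length(k_values))
  for (i in 2:(length(k_values) - 1L)) {
    if (is.na(sL[i]) || sL[i] <= 0) next
    dK[i] <- abs(mL[i + 1] - 2 * mL[i] + mL[i - 1]) / sL[i]
  }
  out <- data.frame(K = k_values, mean_L = mL, sd_L = sL, deltaK = dK,
                    row.names = NULL)
  class(out) <- c("cluster_support", "data.frame")
  out
}
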