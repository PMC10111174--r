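## Shared fixtures and independent brute-force oracles.

## small deterministic genotype matrix builder
toy_gm <- function(genos, pop, loci_names = NULL) {
  ## genos: list of matrices n x 2 per locus (allele pairs)
  L <- length(genos)
  n <- nrow(genos[[1]])
  a1 <- sapply(genos, function(g) g[, 1])
  a2 <- sapply(genos, function(g) g[, 2])
  a1 <- matrix(as.integer(a1), n, L)
  a2 <- matrix(as.integer(a2), n, L)
  if (!is.null(loci_names)) colnames(a1) <- colnames(a2) <- loci_names
  genotype_matrix(a1, a2, pop = pop)
}

## random genotype matrix for property tests
random_gm <- function(n_pops = 3, n_per = 8, n_loci = 4, n_alleles = 5,
                      miss = 0, seed = 1) {
  set.seed(seed)
  n <- n_pops * n_per
  a1 <- matrix(sample.int(n_alleles, n * n_loci, replace = TRUE) + 9L,
               n, n_loci)
  a2 <- matrix(sample.int(n_alleles, n * n_loci, replace = TRUE) + 9L,
               n, n_loci)
  if (miss > 0) {
    hit <- sample(n * n_loci, round(miss * n * n_loci))
    a1[hit] <- NA_integer_; a2[hit] <- NA_integer_
  }
  pop <- rep(paste0("P", seq_len(n_pops)), each = n_per)
  genotype_matrix(a1, a2, pop = factor(pop, levels = unique(pop)))
}

## independent direct-count oracle for Nei (1987) basic statistics;
## plain nested loops over the raw allele matrices, no package helpers
oracle_fstats <- function(gm) {
  L <- ncol(gm$a1)
  pops <- levels(gm$pop)
  Ho_l <- Hs_l <- Ht_l <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    per_pop <- list()
    for (p in pops) {
      rows <- which(gm$pop == p)
      x1 <- gm$a1[rows, l]; x2 <- gm$a2[rows, l]
      ok <- !is.na(x1)
      if (sum(ok) == 0) next
      alle <- c(x1[ok], x2[ok])
      per_pop[[p]] <- list(n = sum(ok),
                           ho = sum(x1[ok] != x2[ok]) / sum(ok),
                           freq = table(alle) / length(alle))
    }
    if (length(per_pop) < 2) next
    r <- length(per_pop)
    ns <- sapply(per_pop, `[[`, "n")
    nbar <- r / sum(1 / ns)
    ho <- mean(sapply(per_pop, `[[`, "ho"))
    sum_p2 <- mean(sapply(per_pop, function(z) sum(z$freq^2)))
    hs <- nbar / (nbar - 1) * (1 - sum_p2 - ho / (2 * nbar))
    ## average frequencies over populations (allele union)
    all_alleles <- unique(unlist(lapply(per_pop, function(z)
      names(z$freq))))
    pbar <- sapply(all_alleles, function(a)
      mean(sapply(per_pop, function(z)
        if (a %in% names(z$freq)) z$freq[[a]] else 0)))
    ht <- 1 - sum(pbar^2) + hs / (nbar * r) - ho / (2 * nbar * r)
    Ho_l[l] <- ho; Hs_l[l] <- hs; Ht_l[l] <- ht
  }
  ok <- !is.na(Ho_l)
  mHo <- mean(Ho_l[ok]); mHs <- mean(Hs_l[ok]); mHt <- mean(Ht_l[ok])
  list(F_IS = 1 - mHo / mHs, F_ST = (mHt - mHs) / mHt,
       F_IT = 1 - mHo / mHt)
}

## independent per-locus chord distance evaluation
oracle_chord <- function(gm, p1, p2) {
  L <- ncol(gm$a1)
  acc <- 0; used <- 0
  for (l in seq_len(L)) {
    f <- list()
    for (p in c(p1, p2)) {
      rows <- which(gm$pop == p)
      alle <- c(gm$a1[rows, l], gm$a2[rows, l])
      alle <- alle[!is.na(alle)]
      if (!length(alle)) { f <- NULL; break }
      f[[p]] <- table(alle) / length(alle)
    }
    if (is.null(f)) next
    states <- union(names(f[[p1]]), names(f[[p2]]))
    s <- sum(sapply(states, function(a) {
      xa <- if (a %in% names(f[[p1]])) f[[p1]][[a]] else 0
      ya <- if (a %in% names(f[[p2]])) f[[p2]][[a]] else 0
      sqrt(xa * ya)
    }))
    acc <- acc + sqrt(2 * (1 - s))
    used <- used + 1
  }
  2 / (pi * used) * acc
}

## tiny single-population scenario for simulator tests
one_pop_scenario <- function() {
  scenario_spec("one", pops = "A", events = list(), ne = c(A = "Ne1"),
                founder_n = NULL)
}

## two isolated populations split at fixed t
split_scenario <- function(t_fix) {
  pr <- prior_spec(t_ranges = list(t1 = c(t_fix, t_fix)),
                   t_order = "t1")
  scenario_spec("split", pops = c("A", "B"),
                events = list(msatcoal:::div("B", "A", "t1")),
                ne = c(A = "NeX", B = "NeX"), founder_n = NULL,
                priors = pr)
}
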