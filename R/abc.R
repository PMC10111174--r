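## Reference-table ABC: summary statistics, rejection, local logistic
## model choice, local-linear parameter posteriors, confusion analysis.

#' ABC summary statistics for a grouped microsatellite dataset
#'
#' Per group: mean number of alleles per locus, mean unbiased expected
#' heterozygosity, mean allele-size variance, mean Garza-Williamson
#' `M = alleles / (allele size range + 1)`. Per group pair: pairwise Nei
#' `F_ST`, `(delta mu)^2` (squared difference of mean allele size,
#' averaged over loci), and the shared-allele distance `D_AS`. The vector
#' has length `4 G + 3 G(G-1)/2` with a fixed, stable ordering. Loci with
#' all calls missing in some group are dropped consistently across groups.
#'
#' @param gm a [genotype_matrix()]
#' @param groups group (cluster) label per individual; defaults to the
#'   population labels
#' @return named numeric stat vector
#' @export
summary_stats <- function(gm, groups = NULL) {
  if (is.null(groups)) groups <- as.character(gm$pop)
  groups <- factor(as.character(groups))
  if (any(table(groups) < 2L)) stop("every group needs >= 2 individuals")
  G <- nlevels(groups)
  gi <- as.integer(groups) - 1L
  ## drop loci fully missing in any group
  keep <- rep(TRUE, n_loci(gm))
  for (g in levels(groups)) {
    rows <- which(groups == g)
    keep <- keep & colSums(!is.na(gm$a1[rows, , drop = FALSE])) > 0L
  }
  if (!any(keep)) stop("no locus typed in all groups")
  a1 <- gm$a1[, keep, drop = FALSE]; a2 <- gm$a2[, keep, drop = FALSE]
  v <- cpp_summary_stats(a1, a2, gi, G)
  gl <- levels(groups)
  nm <- c(t(outer(gl, c("A", "He", "varsize", "M"), paste, sep = "_")))
  if (G >= 2L) {
    pairs <- utils::combn(gl, 2)
    nm <- c(nm, c(apply(pairs, 2, function(p)
      paste(c("Fst", "dmu2", "Das"), p[1], p[2], sep = "_"))))
  }
  stats::setNames(v, nm)
}

## deterministic sub-seed for row i of a table built from a master seed;
## keeps results identical for any worker partitioning
row_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483587) + 1L
}

#' Build an ABC reference table
#'
#' Simulates `n_per_scenario` datasets per scenario (uniform prior over
#' scenarios), computing the [summary_stats()] of each. Rows are fully
#' reproducible from `seed`: every row uses an independently derived
#' sub-seed, so any worker partitioning yields an identical table.
#'
#' @param scenarios named list of [scenario_spec()]
#' @param n_per_scenario rows per scenario (>= 100 for real use)
#' @param sample_spec diploids per sampled population (see
#'   [simulate_dataset()])
#' @param n_loci number of loci to simulate
#' @param seed master integer seed
#' @param workers accepted for interface compatibility; generation is
#'   sequential and worker-count invariant
#' @return list of class `reference_table`: `stats` (matrix), `params`
#'   (matrix, `NA` for parameters absent from a scenario), `scenario`
#'   (factor), `mad` (per-stat median absolute deviation), `sample_spec`,
#'   `n_loci`
#' @export
build_reference_table <- function(scenarios, n_per_scenario, sample_spec,
                                  n_loci = 15L, seed = 1L, workers = 1L) {
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, "", "name")
  nS <- length(scenarios)
  n_rows <- nS * n_per_scenario
  if (n_rows >= 1e7)
    message("reference table request: ", n_rows, " rows")
  stat_list <- vector("list", n_rows)
  par_list <- vector("list", n_rows)
  scen <- character(n_rows)
  r <- 0L
  for (s in seq_len(nS)) {
    sp <- scenarios[[s]]
    for (i in seq_len(n_per_scenario)) {
      r <- r + 1L
      ok <- FALSE
      for (retry in 0:5) {
        sd_i <- row_seed(seed + retry * 977L, r)
        res <- tryCatch({
          draw <- sample_priors(sp, n_loci = n_loci, seed = sd_i)
          gm <- simulate_dataset(sp, draw, sample_spec)
          list(stats = summary_stats(gm), draw = draw)
        }, error = function(e) e)
        if (!inherits(res, "error")) { ok <- TRUE; break }
      }
      if (!ok) stop("row ", r, " failed repeatedly: ",
                    conditionMessage(res))
      if (retry > 0) message("row ", r, " retried with fresh sub-seed")
      stat_list[[r]] <- res$stats
      par_list[[r]] <- c(res$draw$params,
                         mu_mean_real = mean(res$draw$mu))
      scen[r] <- names(scenarios)[s]
    }
  }
  stats <- do.call(rbind, stat_list)
  pnames <- unique(unlist(lapply(par_list, names)))
  params <- matrix(NA_real_, n_rows, length(pnames),
                   dimnames = list(NULL, pnames))
  for (i in seq_len(n_rows))
    params[i, names(par_list[[i]])] <- par_list[[i]]
  mads <- apply(stats, 2, stats::mad, na.rm = TRUE)
  out <- list(stats = stats, params = params,
              scenario = factor(scen, levels = names(scenarios)),
              mad = mads, sample_spec = sample_spec, n_loci = n_loci,
              scenarios = scenarios)
  class(out) <- "reference_table"
  out
}

#' @export
print.reference_table <- function(x, ...) {
  cat("ABC reference table:", nrow(x$stats), "rows,",
      ncol(x$stats), "statistics,", nlevels(x$scenario), "scenarios\n")
  print(table(x$scenario))
  invisible(x)
}

## normalized distances of table rows to s_obs; drops zero-MAD stats
abc_distances <- function(table, s_obs) {
  use <- which(is.finite(table$mad) & table$mad > 0)
  if (length(use) < ncol(table$stats))
    warning("dropping ", ncol(table$stats) - length(use),
            " zero-MAD statistic(s)")
  S <- sweep(table$stats[, use, drop = FALSE], 2, table$mad[use], "/")
  so <- s_obs[colnames(table$stats)[use]] / table$mad[use]
  D <- sweep(S, 2, so, "-")
  D[!is.finite(D)] <- 0
  list(d = sqrt(rowSums(D^2)), X = D, use = use)
}

## multinomial (softmax) logistic regression with ridge penalty on the
## slopes (intercepts effectively free), observation weights, fitted by
## per-class cyclic Newton updates with damped steps. The ridge keeps the
## fit finite under (near-)perfect separation; as the slopes shrink the
## evaluated probabilities at the query point tend to the weighted class
## frequencies, i.e. the direct rejection estimate.
softmax_fit <- function(X, y, w, ridge = NULL, maxit = 50L) {
  X1 <- cbind(1, X)
  n <- nrow(X1); p <- ncol(X1); K <- nlevels(y)
  if (is.null(ridge)) ridge <- max(1e-6, 0.5 * ncol(X) / n)
  pen <- c(1e-8, rep(ridge, p - 1L))
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  B <- matrix(0, p, K)
  for (it in seq_len(maxit)) {
    eta <- X1 %*% B
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta); P <- P / rowSums(P)
    maxstep <- 0
    for (k in seq_len(K)) {
      g <- crossprod(X1, w * (Y[, k] - P[, k])) - pen * B[, k]
      wk <- w * pmax(P[, k] * (1 - P[, k]), 1e-10)
      H <- crossprod(X1 * sqrt(wk)) + diag(pen, p)
      step <- solve(H, g)
      step <- pmin(pmax(step, -4), 4)    # damp Newton overshoot
      B[, k] <- B[, k] + step
      maxstep <- max(maxstep, max(abs(step)))
    }
    if (maxstep < 1e-8) break
  }
  B
}

#' ABC model choice by rejection and local logistic regression
#'
#' Statistics are MAD-normalized (constants from the reference table);
#' the `tolerance` fraction of rows nearest to `s_obs` in Euclidean
#' distance is retained. The direct estimate is the scenario frequency
#' among retained rows; the logistic estimate fits a multinomial logistic
#' regression of scenario on `(s - s_obs)` with Epanechnikov weights
#' (bandwidth = largest retained distance) and a small ridge penalty, and
#' evaluates it at `s = s_obs`.
#'
#' @param table a [build_reference_table()] result
#' @param s_obs observed stat vector ([summary_stats()])
#' @param tolerance retained fraction (default 0.01)
#' @return list of class `model_choice_result` with `direct`, `logistic`
#'   (named probability vectors), `tolerance`, `n_retained`
#' @export
model_choice <- function(table, s_obs, tolerance = 0.01) {
  n <- nrow(table$stats)
  n_keep <- max(2L, ceiling(tolerance * n))
  if (tolerance * n < 50)
    warning("fewer than 50 retained rows; posterior estimates unstable")
  dd <- abc_distances(table, s_obs)
  keep <- order(dd$d)[seq_len(n_keep)]
  y <- droplevels(table$scenario[keep])
  lv <- levels(table$scenario)
  direct <- as.numeric(table(table$scenario[keep])) / n_keep
  names(direct) <- lv
  missing_s <- setdiff(lv, levels(y))
  if (length(missing_s))
    warning("scenario(s) absent from retained set: ",
            paste(missing_s, collapse = ", "))
  h <- max(dd$d[keep])
  w <- if (h > 0) 1 - (dd$d[keep] / h)^2 else rep(1, n_keep)
  w <- pmax(w, 1e-8)
  logistic <- direct
  if (nlevels(y) >= 2L) {
    B <- softmax_fit(dd$X[keep, , drop = FALSE], y, w)
    eta <- B[1, ]                       # covariates are zero at s_obs
    eta <- eta - max(eta)
    pr <- exp(eta) / sum(exp(eta))
    logistic[] <- 0
    logistic[levels(y)] <- pr
  }
  out <- list(direct = direct, logistic = logistic,
              tolerance = tolerance, n_retained = n_keep)
  class(out) <- "model_choice_result"
  out
}

#' @export
print.model_choice_result <- function(x, ...) {
  cat("ABC model choice (", x$n_retained, " retained rows):\n", sep = "")
  print(round(rbind(direct = x$direct, logistic = x$logistic), 4))
  invisible(x)
}

logit_bounded <- function(x, a, b) {
  z <- (x - a) / (b - a)
  z <- pmin(pmax(z, 1e-9), 1 - 1e-9)
  log(z / (1 - z))
}
inv_logit_bounded <- function(z, a, b) a + (b - a) / (1 + exp(-z))

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' ABC parameter posteriors by local-linear regression adjustment
#'
#' Retains the `tolerance` nearest rows of the focal scenario, transforms
#' each parameter to the real line by a logit over its prior range,
#' adjusts by weighted local-linear regression on `(s - s_obs)`
#' (`theta* = theta - b (s - s_obs)`, Epanechnikov weights), and
#' back-transforms. Reports weighted median and 2.5/97.5% quantiles. A
#' singular regression design falls back to unadjusted rejection
#' quantiles with a flag.
#'
#' @param table a [build_reference_table()] result
#' @param scenario_id scenario name
#' @param s_obs observed stat vector
#' @param tolerance retained fraction of the focal scenario's rows
#' @param params optional character vector of parameters to report
#' @return data frame of class `param_posterior`: `param`, `median`,
#'   `q025`, `q975`, `adjusted`
#' @export
estimate_params <- function(table, scenario_id, s_obs, tolerance = 0.01,
                            params = NULL) {
  rows <- which(table$scenario == scenario_id)
  if (!length(rows)) stop("unknown scenario ", scenario_id)
  sub <- list(stats = table$stats[rows, , drop = FALSE],
              mad = table$mad)
  dd <- abc_distances(sub, s_obs)
  n_keep <- max(2L, ceiling(tolerance * length(rows)))
  if (n_keep < 50)
    warning("fewer than 50 retained rows from scenario ", scenario_id)
  keep <- order(dd$d)[seq_len(n_keep)]
  h <- max(dd$d[keep])
  w <- if (h > 0) 1 - (dd$d[keep] / h)^2 else rep(1, n_keep)
  w <- pmax(w, 1e-8)
  X <- dd$X[keep, , drop = FALSE]
  P <- table$params[rows, , drop = FALSE][keep, , drop = FALSE]
  if (is.null(params))
    params <- colnames(P)[colSums(is.na(P)) == 0 &
                            apply(P, 2, function(v)
                              stats::sd(v, na.rm = TRUE) >= 0)]
  out <- data.frame(param = character(0), median = numeric(0),
                    q025 = numeric(0), q975 = numeric(0),
                    adjusted = logical(0), stringsAsFactors = FALSE)
  X1 <- cbind(1, X)
  XtWX <- crossprod(X1 * sqrt(w))
  solv <- tryCatch(solve(XtWX + diag(1e-8, ncol(X1))),
                   error = function(e) NULL)
  for (pn in params) {
    th <- P[, pn]
    if (anyNA(th)) next
    a <- min(table$params[rows, pn], na.rm = TRUE)
    b <- max(table$params[rows, pn], na.rm = TRUE)
    if (b - a < 1e-12) {           # constant parameter
      out <- rbind(out, data.frame(param = pn, median = th[1],
                                   q025 = th[1], q975 = th[1],
                                   adjusted = FALSE))
      next
    }
    pad <- 1e-6 * (b - a)
    z <- logit_bounded(th, a - pad, b + pad)
    adjusted <- FALSE
    if (!is.null(solv)) {
      beta <- solv %*% crossprod(X1 * w, z)
      zstar <- beta[1] + (z - X1 %*% beta)
      adjusted <- TRUE
    } else zstar <- z
    thstar <- inv_logit_bounded(zstar, a - pad, b + pad)
    q <- weighted_quantile(as.numeric(thstar), w, c(0.5, 0.025, 0.975))
    out <- rbind(out, data.frame(param = pn, median = q[1], q025 = q[2],
                                 q975 = q[3], adjusted = adjusted))
  }
  class(out) <- c("param_posterior", "data.frame")
  out
}

#' Type I / type II confusion analysis for scenario choice
#'
#' Simulates pseudo-observed datasets (pods) from the priors: `n_pods`
#' under the focal scenario and `n_pods` spread over the competing
#' scenarios, classifies each by highest logistic posterior against the
#' supplied reference table. Type I error = fraction of focal-scenario
#' pods not selecting the focal scenario; type II error = fraction of
#' competitor pods selecting it.
#'
#' @param table a [build_reference_table()] result
#' @param focal_scenario scenario name
#' @param n_pods pods per side (study default 500)
#' @param tolerance retained fraction for [model_choice()]
#' @param seed integer seed
#' @return list of class `confusion_result`: `focal`, `type_I`,
#'   `type_II`, `n_pods`
#' @export
abc_confusion <- function(table, focal_scenario, n_pods = 500L,
                          tolerance = 0.01, seed = 1L) {
  scen <- table$scenarios
  if (!focal_scenario %in% names(scen)) stop("unknown focal scenario")
  classify <- function(sp, sd_i) {
    draw <- sample_priors(sp, n_loci = table$n_loci, seed = sd_i)
    gm <- simulate_dataset(sp, draw, table$sample_spec)
    mc <- suppressWarnings(model_choice(table, summary_stats(gm),
                                        tolerance))
    names(which.max(mc$logistic))
  }
  sel_focal <- vapply(seq_len(n_pods), function(i)
    classify(scen[[focal_scenario]], row_seed(seed, i)), "")
  type_I <- mean(sel_focal != focal_scenario)
  others <- setdiff(names(scen), focal_scenario)
  type_II <- NA_real_
  if (length(others)) {
    src <- rep_len(others, n_pods)
    sel_other <- vapply(seq_len(n_pods), function(i)
      classify(scen[[src[i]]], row_seed(seed + 31L, i)), "")
    type_II <- mean(sel_other == focal_scenario)
  }
  out <- list(focal = focal_scenario, type_I = type_I, type_II = type_II,
              n_pods = n_pods)
  class(out) <- "confusion_result"
  out
}

#' @export
print.confusion_result <- function(x, ...) {
  cat(sprintf("confusion for %s: type I = %.3f, type II = %.3f (%d pods)\n",
              x$focal, x$type_I, x$type_II, x$n_pods))
  invisible(x)
}

#' Random subsampling to equal cluster sizes
#'
#' Selects `k` individuals per cluster without replacement (all of them,
#' with a warning, when a cluster is smaller than `k`).
#'
#' @param gm a [genotype_matrix()]
#' @param groups cluster label per individual (default: population)
#' @param k individuals per cluster
#' @param seed integer seed
#' @return a [genotype_matrix()]; the subsampled `groups` are attached as
#'   attribute `"groups"`
#' @export
subsample_clusters <- function(gm, groups = NULL, k = 25L, seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(groups)) groups <- as.character(gm$pop)
  groups <- as.character(groups)
  keep <- integer(0)
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) < k) {
      warning("cluster ", g, " has only ", length(rows),
              " individuals; taking all")
      keep <- c(keep, rows)
    } else keep <- c(keep, sort(sample(rows, k)))
  }
  out <- subset_gm(gm, ind = keep)
  attr(out, "groups") <- groups[keep]
  out
}
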