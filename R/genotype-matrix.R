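#' Diploid microsatellite genotype matrix
#'
#' The central container of the package: diploid allele-length calls for
#' `n` individuals at `L` loci, with a population label per individual.
#' Alleles are stored as integer repeat-length codes exactly as read from
#' file (no binning). A missing genotype is a single sentinel for the whole
#' call: both allele slots are `NA` together; half-missing calls are
#' rejected.
#'
#' @param a1,a2 integer matrices (`n x L`) holding the two allele copies of
#'   each call. `NA` in both marks a missing genotype.
#' @param pop character or factor of length `n`: population label per
#'   individual.
#' @param ind optional character vector of individual ids (defaults to
#'   `ind_1..ind_n`).
#' @param loci optional data frame describing the loci with columns
#'   `name`, `motif_length`, `state_min`, `state_max`. Defaults to
#'   single-unit motifs with the observed allele range padded to width 40.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `a1`, `a2`, `pop` (factor), `ind`, `loci`.
#' @examples
#' gm <- genotype_matrix(
#'   a1 = matrix(c(1L, 1L, 2L, 1L), 2, 2),
#'   a2 = matrix(c(1L, 2L, 2L, 1L), 2, 2),
#'   pop = c("A", "A")
#' )
#' n_loci(gm)
#' @export
genotype_matrix <- function(a1, a2, pop, ind = NULL, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("a1 and a2 must have identical dimensions")
  n <- nrow(a1); L <- ncol(a1)
  if (n < 1L) stop("genotype matrix needs at least one individual")
  if (L < 1L) stop("genotype matrix needs at least one locus")
  if (length(pop) != n) stop("pop must have one label per individual")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing genotypes are not allowed (individual ",
         which(half, arr.ind = TRUE)[1, 1], ", locus ",
         which(half, arr.ind = TRUE)[1, 2], ")")
  if (is.null(ind)) ind <- paste0("ind_", seq_len(n))
  if (length(ind) != n) stop("ind must have length nrow(a1)")
  if (is.null(loci)) {
    loci <- default_loci(a1, a2)
  } else {
    loci <- as.data.frame(loci)
    req <- c("name", "motif_length", "state_min", "state_max")
    if (!all(req %in% names(loci)))
      stop("loci must have columns ", paste(req, collapse = ", "))
    if (nrow(loci) != L) stop("loci table must have one row per locus")
    if (any(loci$state_max - loci$state_min < 1L))
      stop("locus state ranges must span at least 2 states")
  }
  bad <- which((!is.na(a1) & (a1 < rep(loci$state_min, each = n) |
                              a1 > rep(loci$state_max, each = n))) |
               (!is.na(a2) & (a2 < rep(loci$state_min, each = n) |
                              a2 > rep(loci$state_max, each = n))))
  if (length(bad))
    stop("allele state outside the declared locus state range")
  dimnames(a1) <- dimnames(a2) <- list(ind, loci$name)
  pop_f <- if (is.factor(pop)) pop else factor(as.character(pop))
  structure(list(a1 = a1, a2 = a2, pop = pop_f,
                 ind = as.character(ind), loci = loci),
            class = "genotype_matrix")
}

default_loci <- function(a1, a2, width = 40L) {
  L <- ncol(a1)
  lo <- pmin(suppressWarnings(apply(a1, 2, min, na.rm = TRUE)),
             suppressWarnings(apply(a2, 2, min, na.rm = TRUE)))
  hi <- pmax(suppressWarnings(apply(a1, 2, max, na.rm = TRUE)),
             suppressWarnings(apply(a2, 2, max, na.rm = TRUE)))
  lo[!is.finite(lo)] <- 1; hi[!is.finite(hi)] <- 2
  pad <- pmax(0L, width - (as.integer(hi) - as.integer(lo) + 1L))
  data.frame(name = if (!is.null(colnames(a1))) colnames(a1) else
               paste0("loc_", seq_len(L)),
             motif_length = 1L,
             state_min = pmax(1L, as.integer(lo) - pad %/% 2L),
             state_max = as.integer(hi) + (pad - pad %/% 2L),
             stringsAsFactors = FALSE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_ind(x), "individuals,",
      nlevels(x$pop), "populations,", n_loci(x), "loci\n")
  mf <- mean(is.na(x$a1))
  cat(sprintf("missing genotypes: %.1f%%\n", 100 * mf))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`
#' @export
n_ind <- function(gm) nrow(gm$a1)

#' @rdname genotype_matrix
#' @export
n_loci <- function(gm) ncol(gm$a1)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param gm a `genotype_matrix`
#' @param ind integer or logical index over individuals
#' @param loci integer or logical index over loci
#' @return a `genotype_matrix`
#' @export
subset_gm <- function(gm, ind = NULL, loci = NULL) {
  if (is.null(ind)) ind <- seq_len(n_ind(gm))
  if (is.null(loci)) loci <- seq_len(n_loci(gm))
  genotype_matrix(gm$a1[ind, loci, drop = FALSE],
                  gm$a2[ind, loci, drop = FALSE],
                  pop = droplevels(gm$pop[ind]),
                  ind = gm$ind[ind],
                  loci = gm$loci[loci, , drop = FALSE])
}

#' Combine two genotype matrices over the same loci
#' @param x,y `genotype_matrix` objects with identical locus tables
#' @return a `genotype_matrix`
#' @export
rbind_gm <- function(x, y) {
  if (!identical(x$loci$name, y$loci$name))
    stop("locus sets differ")
  genotype_matrix(rbind(x$a1, y$a1), rbind(x$a2, y$a2),
                  pop = c(as.character(x$pop), as.character(y$pop)),
                  ind = make.unique(c(x$ind, y$ind)),
                  loci = x$loci)
}

#' Validate a genotype matrix and summarize completeness
#'
#' Report-only check: per-population sample sizes, per-locus missing call
#' counts, and the overall missing fraction
#' (missing calls / (individuals x loci)).
#'
#' @param gm a `genotype_matrix`
#' @return a list of class `gm_validation` with elements `n_ind`, `n_loci`,
#'   `pop_sizes`, `locus_missing`, `missing_fraction`.
#' @export
validate_gm <- function(gm) {
  miss <- is.na(gm$a1)
  out <- list(n_ind = n_ind(gm), n_loci = n_loci(gm),
              pop_sizes = table(gm$pop),
              locus_missing = colSums(miss),
              missing_fraction = mean(miss))
  class(out) <- "gm_validation"
  out
}

#' @export
print.gm_validation <- function(x, ...) {
  cat("genotype validation:", x$n_ind, "individuals x", x$n_loci, "loci\n")
  cat(sprintf("overall missing fraction: %.4f\n", x$missing_fraction))
  invisible(x)
}

## per-locus allele count table for one set of rows; names are allele states
locus_allele_counts <- function(gm, locus, rows = seq_len(n_ind(gm))) {
  a <- c(gm$a1[rows, locus], gm$a2[rows, locus])
  a <- a[!is.na(a)]
  if (!length(a)) return(integer(0))
  table(a)
}
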