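#' Mutation model for microsatellite simulation
#'
#' Generalized stepwise model: mutations change the allele state by a
#' magnitude `k >= 1` with `P(k) = (1 - P) P^(k-1)` and equiprobable sign;
#' `P = 0` is the strict single-step model. Steps that would leave the
#' declared state range are handled by resampling the step (default) or
#' reflecting off the boundary.
#'
#' @param mu per-locus mutation rates (per generation)
#' @param gsm_p geometric parameter `P` in `[0, 1)`
#' @param state_range integer length-2 inclusive range of allelic states
#' @param boundary `"resample"` or `"reflect"`
#' @return list of class `mutation_model`
#' @export
mutation_model <- function(mu, gsm_p = 0.22, state_range = c(1L, 40L),
                           boundary = c("resample", "reflect")) {
  boundary <- match.arg(boundary)
  if (gsm_p < 0 || gsm_p >= 1) stop("gsm_p must be in [0, 1)")
  if (diff(state_range) < 1L) stop("state range must span >= 2 states")
  structure(list(mu = mu, gsm_p = gsm_p,
                 state_range = as.integer(state_range),
                 boundary = boundary),
            class = "mutation_model")
}

## Resolve a scenario + draw into the flat event/size arrays the C++
## simulator consumes.
resolve_scenario <- function(spec, draw) {
  allpops <- c(spec$pops, spec$ancestors)
  pid <- function(x) match(x, allpops) - 1L
  pars <- draw$params
  ev <- list(time = numeric(0), type = integer(0), a = integer(0),
             b = integer(0), c = integer(0), ra = numeric(0))
  sz <- data.frame(pop = integer(0), time = numeric(0), ne = numeric(0))
  for (p in allpops)
    sz <- rbind(sz, data.frame(pop = pid(p), time = 0,
                               ne = pars[[spec$ne[[p]]]]))
  push_ev <- function(time, type, a, b, c = -1L, ra = 0) {
    ev$time <<- c(ev$time, time); ev$type <<- c(ev$type, type)
    ev$a <<- c(ev$a, a); ev$b <<- c(ev$b, b); ev$c <<- c(ev$c, c)
    ev$ra <<- c(ev$ra, ra)
  }
  for (e in spec$events) {
    tt <- pars[[e$t]]
    if (is.null(tt) || is.na(tt)) stop("draw lacks parameter ", e$t)
    src <- if (e$type == "divergence") e$child else e$target
    if (e$type == "divergence") {
      push_ev(tt, 0L, pid(e$child), pid(e$parent))
    } else {
      push_ev(tt, 1L, pid(e$target), pid(e$srcA), pid(e$srcB),
              pars[[e$ra]])
    }
    if (!is.null(spec$founder_n)) {
      t_bn <- max(0, tt - spec$db)
      sz <- rbind(sz, data.frame(pop = pid(src), time = t_bn,
                                 ne = pars[[spec$founder_n]]))
      if (t_bn > 0) push_ev(t_bn, 2L, pid(src), pid(src))
    }
  }
  o <- order(ev$time, seq_along(ev$time))
  sz <- sz[order(sz$pop, sz$time), ]
  list(n_pops = length(allpops),
       ev_time = ev$time[o], ev_type = ev$type[o], ev_a = ev$a[o],
       ev_b = ev$b[o], ev_c = ev$c[o], ev_ra = ev$ra[o],
       sz_pop = sz$pop, sz_time = sz$time, sz_ne = sz$ne)
}

#' Simulate a microsatellite dataset under a demographic scenario
#'
#' Backward-in-time coalescent in discrete generations (geometric waiting
#' times, pairwise coalescence probability `k(k-1)/2 / (2 Ne)` per
#' generation), with divergence, pulse admixture, and founder bottlenecks
#' of size `N` for `db` generations immediately before each founding event
#' (looking backward). Mutations are Poisson on branches under the
#' [mutation_model()]; the root allele is the mid-range state. Diploid
#' genotypes pair consecutive simulated gene copies.
#'
#' @param spec a [scenario_spec()]
#' @param draw a [sample_priors()] draw (or a compatible list)
#' @param sample_spec named integer vector: diploid individuals per
#'   sampled population, in `spec$pops` order when unnamed
#' @param mut a [mutation_model()]; defaults to the draw's per-locus rates
#'   with `P = draw$gsm_p` on 40 states
#' @param seed optional integer seed
#' @return a [genotype_matrix()] with populations named as in `spec$pops`
#' @export
simulate_dataset <- function(spec, draw, sample_spec,
                             mut = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(mut))
    mut <- mutation_model(draw$mu, gsm_p = draw$gsm_p)
  if (is.null(names(sample_spec))) names(sample_spec) <- spec$pops
  if (!all(names(sample_spec) %in% spec$pops))
    stop("sample_spec names must be sampled populations")
  n_dip <- as.integer(sample_spec[spec$pops])
  n_dip[is.na(n_dip)] <- 0L
  if (any(n_dip < 0L) || sum(n_dip) < 1L)
    stop("need at least one sampled individual")
  rs <- resolve_scenario(spec, draw)
  sm <- cpp_simulate_msat(n_dip, rs$n_pops, rs$ev_time, rs$ev_type,
                          rs$ev_a, rs$ev_b, rs$ev_c, rs$ev_ra,
                          rs$sz_pop, rs$sz_time, rs$sz_ne,
                          mut$mu, mut$gsm_p,
                          mut$state_range[1], mut$state_range[2],
                          as.integer(floor(mean(mut$state_range))),
                          if (mut$boundary == "resample") 0L else 1L)
  odd <- seq(1L, nrow(sm), by = 2L)
  a1 <- sm[odd, , drop = FALSE]
  a2 <- sm[odd + 1L, , drop = FALSE]
  pop <- factor(rep(spec$pops, n_dip), levels = spec$pops[n_dip > 0])
  L <- ncol(a1)
  loci <- data.frame(name = paste0("loc_", seq_len(L)),
                     motif_length = 1L,
                     state_min = mut$state_range[1],
                     state_max = mut$state_range[2])
  colnames(a1) <- colnames(a2) <- loci$name
  genotype_matrix(a1, a2, pop = pop, loci = loci)
}
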