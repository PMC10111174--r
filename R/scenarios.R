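## Declarative demographic scenarios with priors.

#' Prior specification for demographic parameters
#'
#' Defaults follow the study design for a post-glacial colonization
#' setting: all effective sizes `Ne` uniform on \[10, 1500\]; founder
#' counts `N` uniform on \[1, 100\]; divergence/admixture times (in
#' generations) `t1` on \[10, 500\], `t2` on \[100, 500\], `t3` on
#' \[100, 1000\], `t4` and `t5` on \[500, 3000\] subject to the full order
#' chain `t5 > t4 > t3 > t2 > t1`; admixture rate `ra` uniform on
#' \[0.001, 0.999\]; mean mutation rate uniform on \[1e-4, 1e-3\] with
#' per-locus rates Gamma-distributed (shape 2) around the mean, truncated
#' to \[1e-5, 1e-2\]; geometric step parameter `P = 0.22`.
#'
#' @param ne_range,n_range,ra_range,mu_mean_range,mu_locus_range numeric
#'   length-2 ranges
#' @param t_ranges named list of length-2 ranges for the time parameters
#' @param t_order character vector of time parameters from largest to
#'   smallest (order constraints)
#' @param gsm_p geometric distribution parameter of the mutation model
#' @param mu_shape shape of the per-locus Gamma
#' @return list of class `prior_spec`
#' @export
prior_spec <- function(ne_range = c(10, 1500),
                       n_range = c(1, 100),
                       t_ranges = list(t1 = c(10, 500), t2 = c(100, 500),
                                       t3 = c(100, 1000),
                                       t4 = c(500, 3000),
                                       t5 = c(500, 3000)),
                       t_order = c("t5", "t4", "t3", "t2", "t1"),
                       ra_range = c(0.001, 0.999),
                       mu_mean_range = c(1e-4, 1e-3),
                       mu_locus_range = c(1e-5, 1e-2),
                       gsm_p = 0.22, mu_shape = 2) {
  stopifnot(all(vapply(t_ranges, length, 1L) == 2L))
  out <- list(ne_range = ne_range, n_range = n_range,
              t_ranges = t_ranges, t_order = t_order,
              ra_range = ra_range, mu_mean_range = mu_mean_range,
              mu_locus_range = mu_locus_range, gsm_p = gsm_p,
              mu_shape = mu_shape)
  class(out) <- "prior_spec"
  out
}

#' Declarative demographic scenario
#'
#' A backward-in-time model over sampled populations plus optional
#' unsampled ancestors. Events (processed backward, earliest first):
#' * `div(child, parent, t)` — all lineages of `child` move to `parent`
#'   at time parameter `t`; the child receives a founder bottleneck of
#'   size parameter `N` for `db` generations just before `t` (backward).
#' * `admix(target, srcA, srcB, t, ra)` — each lineage of `target` moves
#'   to `srcA` with probability `ra`, else `srcB`; same bottleneck rule.
#'
#' @param name scenario label
#' @param pops character vector of sampled population labels
#' @param ancestors character vector of unsampled populations
#' @param events list of event lists, each with `type`
#'   (`"divergence"`/`"admixture"`), `t` (time parameter name), and
#'   `child`/`parent` or `target`/`srcA`/`srcB` and `ra`
#' @param ne named character vector mapping every population (sampled and
#'   ancestral) to its size parameter name
#' @param founder_n name of the founder-count parameter (`NULL` disables
#'   founder bottlenecks)
#' @param db bottleneck duration in generations (no printed prior exists;
#'   fixed at 5 by default)
#' @param priors a [prior_spec()]
#' @return list of class `scenario_spec`
#' @export
scenario_spec <- function(name, pops, ancestors = character(0), events,
                          ne, founder_n = "N", db = 5,
                          priors = prior_spec()) {
  out <- list(name = name, pops = pops, ancestors = ancestors,
              events = events, ne = ne, founder_n = founder_n, db = db,
              priors = priors)
  class(out) <- "scenario_spec"
  errs <- validate_scenario(out)
  if (length(errs)) stop("invalid scenario '", name, "': ",
                         paste(errs, collapse = "; "))
  out
}

div <- function(child, parent, t)
  list(type = "divergence", child = child, parent = parent, t = t)
admix <- function(target, srcA, srcB, t, ra = "ra")
  list(type = "admixture", target = target, srcA = srcA, srcB = srcB,
       t = t, ra = ra)

#' Validate a scenario specification
#'
#' Checks population/parameter references, time-ordering feasibility
#' (event times must be realizable under the prior order constraints when
#' an event depends on another), and connectivity (every sampled
#' population reaches a common ancestor).
#'
#' @param spec a [scenario_spec()] (or the raw list before construction)
#' @return character vector of error messages; empty when valid
#' @export
validate_scenario <- function(spec) {
  errs <- character(0)
  allpops <- c(spec$pops, spec$ancestors)
  if (anyDuplicated(allpops)) errs <- c(errs, "duplicate population label")
  for (ev in spec$events) {
    refs <- switch(ev$type,
                   divergence = c(ev$child, ev$parent),
                   admixture = c(ev$target, ev$srcA, ev$srcB),
                   {errs <- c(errs, paste("unknown event type", ev$type));
                     character(0)})
    if (!all(refs %in% allpops))
      errs <- c(errs, paste("event references unknown population:",
                            paste(setdiff(refs, allpops), collapse = ",")))
    if (!ev$t %in% names(spec$priors$t_ranges))
      errs <- c(errs, paste("unknown time parameter", ev$t))
  }
  if (!all(spec$pops %in% names(spec$ne)) ||
      !all(spec$ancestors %in% names(spec$ne)))
    errs <- c(errs, "every population needs a size parameter in 'ne'")
  ## connectivity: process events in prior-implied time order (smallest
  ## first); track which populations can still hold lineages
  ord <- spec$priors$t_order
  rank_of <- function(t) match(t, rev(ord))  # t1 smallest
  ev_rank <- vapply(spec$events, function(e) rank_of(e$t), 1)
  if (anyNA(ev_rank)) {
    errs <- c(errs, "event time not in prior ordering")
    return(errs)
  }
  evs <- spec$events[order(ev_rank, seq_along(spec$events))]
  live <- spec$pops   # populations currently able to hold lineages
  dead <- character(0) # populations whose outgoing merge already happened
  for (ev in evs) {
    src <- if (ev$type == "divergence") ev$child else ev$target
    dst <- if (ev$type == "divergence") ev$parent else c(ev$srcA, ev$srcB)
    if (src %in% dead)
      errs <- c(errs, paste("population", src,
                            "merges twice (second event unreachable)"))
    if (any(dst %in% dead))
      errs <- c(errs, paste("lineages delivered into",
                            paste(intersect(dst, dead), collapse = ","),
                            "after it merged away"))
    if (src %in% live) {
      live <- setdiff(live, src)
      live <- union(live, dst)
    }
    dead <- union(dead, src)
  }
  if (length(live) > 1L)
    errs <- c(errs, paste("scenario is not connected; remaining lineages",
                          "in:", paste(live, collapse = ",")))
  if (length(live) < 1L && length(spec$pops))
    errs <- c(errs, "all populations merged away")
  errs
}

#' Draw demographic parameters from a scenario's priors
#'
#' Uniform draws within each range; the time-order constraints are
#' enforced by rejection sampling over the joint draw of all time
#' parameters. Per-locus mutation rates are Gamma(shape, mean = drawn
#' mean rate), truncated to the per-locus range.
#'
#' @param spec a [scenario_spec()]
#' @param n_loci number of loci (for the per-locus mutation rates)
#' @param seed optional integer seed (`NULL` leaves the RNG state alone)
#' @return list of class `parameter_draw`: named numeric `params`
#'   (`Ne*`, `N`, `t*`, `ra`, `mu_mean`), numeric `mu` (length `n_loci`),
#'   `gsm_p`
#' @export
sample_priors <- function(spec, n_loci = 15L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  pr <- spec$priors
  tn <- names(pr$t_ranges)
  for (k in 1:10000) {
    tv <- vapply(pr$t_ranges, function(r) stats::runif(1, r[1], r[2]),
                 numeric(1))
    ok <- TRUE
    ord <- pr$t_order
    for (i in seq_len(length(ord) - 1L))
      if (!(tv[[ord[i]]] > tv[[ord[i + 1L]]])) { ok <- FALSE; break }
    if (ok) break
    if (k == 10000) stop("infeasible time-order constraints")
  }
  ne_names <- unique(unname(spec$ne))
  nev <- vapply(ne_names, function(x)
    stats::runif(1, pr$ne_range[1], pr$ne_range[2]), numeric(1))
  params <- c(tv, nev)
  if (!is.null(spec$founder_n))
    params[[spec$founder_n]] <- stats::runif(1, pr$n_range[1],
                                             pr$n_range[2])
  ra_names <- unique(vapply(Filter(function(e) e$type == "admixture",
                                   spec$events),
                            function(e) e$ra, ""))
  for (rn in ra_names)
    params[[rn]] <- stats::runif(1, pr$ra_range[1], pr$ra_range[2])
  mu_mean <- stats::runif(1, pr$mu_mean_range[1], pr$mu_mean_range[2])
  params[["mu_mean"]] <- mu_mean
  mu <- stats::rgamma(n_loci, shape = pr$mu_shape,
                      scale = mu_mean / pr$mu_shape)
  mu <- pmin(pmax(mu, pr$mu_locus_range[1]), pr$mu_locus_range[2])
  out <- list(params = unlist(params), mu = mu, gsm_p = pr$gsm_p)
  class(out) <- "parameter_draw"
  out
}

#' Library of colonization scenarios
#'
#' Ten declarative scenarios over five sampled clusters `I`-`V` and one
#' unsampled ancestor `ANC`, covering three hypothesis families:
#' * gradual south-to-north stepping stone (scenario 1);
#' * origin in the most diverse cluster(s) `II` / `II`+`III`
#'   (scenarios 2-6);
#' * independent introductions with admixture creating cluster `II`
#'   (scenarios 7-10). Scenario 9: `I` splits from the ancestor at `t4`,
#'   `III` at `t3`, `II` arises by admixture of `I` and `III` at `t2`
#'   simultaneously with `IV` diverging from `III`, and `V` diverges from
#'   `IV` at `t1`.
#'
#' Scenarios 2-8 and 10 are configurable templates for their hypothesis
#' families rather than exact reproductions.
#'
#' @param priors a [prior_spec()]
#' @param db bottleneck duration in generations
#' @return named list of [scenario_spec()] objects
#' @export
scenario_library <- function(priors = prior_spec(), db = 5) {
  ne5 <- c(I = "Ne1", II = "Ne2", III = "Ne3", IV = "Ne4", V = "Ne5",
           ANC = "NeA")
  mk <- function(name, events)
    scenario_spec(name, pops = c("I", "II", "III", "IV", "V"),
                  ancestors = "ANC", events = events, ne = ne5,
                  founder_n = "N", db = db, priors = priors)
  list(
    scenario1 = mk("scenario1", list(
      div("V", "IV", "t1"), div("IV", "III", "t2"), div("III", "II", "t3"),
      div("II", "I", "t4"), div("I", "ANC", "t5"))),
    scenario2 = mk("scenario2", list(
      div("V", "IV", "t1"), div("IV", "III", "t2"), div("III", "II", "t3"),
      div("I", "II", "t4"), div("II", "ANC", "t5"))),
    scenario3 = mk("scenario3", list(
      div("V", "IV", "t1"), div("IV", "III", "t2"), div("I", "II", "t3"),
      div("III", "II", "t4"), div("II", "ANC", "t5"))),
    scenario4 = mk("scenario4", list(
      div("V", "IV", "t1"), div("I", "II", "t2"), div("IV", "III", "t3"),
      div("III", "II", "t4"), div("II", "ANC", "t5"))),
    scenario5 = mk("scenario5", list(
      div("V", "IV", "t1"), div("IV", "II", "t2"), div("I", "III", "t3"),
      div("III", "II", "t4"), div("II", "ANC", "t5"))),
    scenario6 = mk("scenario6", list(
      div("I", "II", "t1"), div("V", "IV", "t2"), div("IV", "III", "t3"),
      div("II", "III", "t4"), div("III", "ANC", "t5"))),
    scenario7 = mk("scenario7", list(
      div("V", "IV", "t1"), div("IV", "III", "t2"),
      admix("II", "I", "III", "t3"), div("III", "ANC", "t4"),
      div("I", "ANC", "t5"))),
    scenario8 = mk("scenario8", list(
      div("V", "III", "t1"), admix("II", "I", "III", "t2"),
      div("IV", "III", "t2"), div("III", "ANC", "t3"),
      div("I", "ANC", "t4"))),
    scenario9 = mk("scenario9", list(
      div("V", "IV", "t1"), admix("II", "I", "III", "t2"),
      div("IV", "III", "t2"), div("III", "ANC", "t3"),
      div("I", "ANC", "t4"))),
    scenario10 = mk("scenario10", list(
      div("V", "IV", "t1"), admix("II", "I", "IV", "t2"),
      div("IV", "III", "t3"), div("III", "I", "t4"),
      div("I", "ANC", "t5")))
  )
}
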