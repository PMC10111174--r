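test_that("zero mutation rate gives a monomorphic founder-state dataset", {
  sp <- one_pop_scenario()
  mut <- mutation_model(rep(0, 10), gsm_p = 0.22)
  draw <- list(params = c(Ne1 = 200), mu = mut$mu, gsm_p = 0.22)
  gm <- simulate_dataset(sp, draw, c(A = 20), mut = mut, seed = 5)
  expect_true(all(gm$a1 == 20L))          # mid-range founder state
  dt <- population_diversity(gm)
  expect_equal(dt$H_O[1], 0)
  expect_equal(dt$H_E[1], 0)
})

test_that("allele states never leave the declared range (property)", {
  sp <- one_pop_scenario()
  for (s in 1:6) {
    mut <- mutation_model(rep(5e-3, 8), gsm_p = 0.5,
                          state_range = c(1L, 10L),
                          boundary = if (s %% 2) "resample" else "reflect")
    draw <- list(params = c(Ne1 = 800), mu = mut$mu, gsm_p = 0.5)
    gm <- simulate_dataset(sp, draw, c(A = 25), mut = mut, seed = s)
    expect_true(all(gm$a1 >= 1 & gm$a1 <= 10))
    expect_true(all(gm$a2 >= 1 & gm$a2 <= 10))
  }
})

test_that("equilibrium heterozygosity matches the strict-SMM closed
           form", {
  sp <- one_pop_scenario()
  mut <- mutation_model(rep(1e-3, 150), gsm_p = 0)
  draw <- list(params = c(Ne1 = 1000), mu = mut$mu, gsm_p = 0)
  he <- vapply(1:3, function(s) {
    gm <- simulate_dataset(sp, draw, c(A = 50), mut = mut, seed = s)
    population_diversity(gm)$H_E[1]
  }, 1)
  expect_equal(mean(he), 1 - 1 / sqrt(1 + 8 * 1000 * 1e-3),
               tolerance = 0.04)
})

test_that("within-population allele-size variance approaches 2 Ne mu", {
  sp <- one_pop_scenario()
  mut <- mutation_model(rep(2e-4, 300), gsm_p = 0,
                        state_range = c(1L, 60L))
  draw <- list(params = c(Ne1 = 500), mu = mut$mu, gsm_p = 0)
  v <- vapply(1:3, function(s) {
    gm <- simulate_dataset(sp, draw, c(A = 40), mut = mut, seed = 10 + s)
    summary_stats(gm)[["A_varsize"]]
  }, 1)
  expect_equal(mean(v), 2 * 500 * 2e-4, tolerance = 0.35)
})

test_that("divergence accumulates (delta mu)^2 at rate 2 mu t", {
  sp <- split_scenario(500)
  mut <- mutation_model(rep(5e-4, 300), gsm_p = 0,
                        state_range = c(1L, 80L))
  v <- vapply(1:3, function(s) {
    draw <- list(params = c(NeX = 100, t1 = 500), mu = mut$mu,
                 gsm_p = 0)
    gm <- simulate_dataset(sp, draw, c(A = 50, B = 50), mut = mut,
                           seed = s)
    summary_stats(gm)[["dmu2_A_B"]]
  }, 1)
  expect_equal(mean(v), 2 * 5e-4 * 500, tolerance = 0.2)
})

test_that("admixture rate moves the admixed population toward source A", {
  pr <- prior_spec(t_ranges = list(t1 = c(200, 200), t2 = c(400, 400),
                                   t3 = c(2000, 2000)),
                   t_order = c("t3", "t2", "t1"))
  sp <- scenario_spec("adm", pops = c("A", "B", "T"), ancestors = "ANC",
                      events = list(msatcoal:::admix("T", "A", "B", "t1"),
                                    msatcoal:::div("B", "A", "t2"),
                                    msatcoal:::div("A", "ANC", "t3")),
                      ne = c(A = "Ne1", B = "Ne1", T = "Ne1",
                             ANC = "Ne1"),
                      founder_n = NULL, priors = pr)
  mut <- mutation_model(rep(2e-3, 40), gsm_p = 0.22)
  gap <- vapply(c(0.1, 0.5, 0.9), function(ra) {
    d <- vapply(1:4, function(s) {
      draw <- list(params = c(Ne1 = 300, t1 = 200, t2 = 400, t3 = 2000,
                              ra = ra), mu = mut$mu, gsm_p = 0.22)
      gm <- simulate_dataset(sp, draw, c(A = 15, B = 15, T = 15),
                             mut = mut, seed = 40 * ra + s)
      dc <- chord_distance_matrix(gm)
      dc["T", "A"] - dc["T", "B"]
    }, 1)
    mean(d)
  }, 1)
  ## higher ra -> T closer to A relative to B
  expect_true(gap[1] > gap[2] && gap[2] > gap[3])
})

test_that("founder bottlenecks reduce diversity in the founded
           population", {
  pr <- prior_spec(t_ranges = list(t1 = c(50, 50), t3 = c(3000, 3000)),
                   t_order = c("t3", "t1"))
  mk <- function(founder_n) scenario_spec("bn", pops = c("A", "B"),
    events = list(msatcoal:::div("B", "A", "t1")),
    ne = c(A = "NeA", B = "NeB"), founder_n = founder_n, db = 20,
    priors = pr)
  mut <- mutation_model(rep(1e-3, 60), gsm_p = 0)
  he_of <- function(sp, params, s) {
    draw <- list(params = params, mu = mut$mu, gsm_p = 0)
    gm <- simulate_dataset(sp, draw, c(A = 20, B = 20), mut = mut,
                           seed = s)
    population_diversity(gm)$H_E[2]
  }
  base <- c(NeA = 1000, NeB = 1000, t1 = 50)
  he_free <- mean(vapply(1:5, function(s)
    he_of(mk(NULL), base, s), 1))
  he_bn <- mean(vapply(1:5, function(s)
    he_of(mk("N"), c(base, N = 2), s), 1))
  expect_lt(he_bn, he_free)
})

test_that("disconnected specs fail at simulation time too", {
  ## construct an unchecked spec directly to exercise the C++ guard
  sp <- one_pop_scenario()
  sp$pops <- c("A", "B")
  sp$ne <- c(A = "Ne1", B = "Ne1")
  draw <- list(params = c(Ne1 = 100), mu = rep(1e-3, 3), gsm_p = 0)
  expect_error(simulate_dataset(sp, draw, c(A = 5, B = 5)),
               "disconnected")
})
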