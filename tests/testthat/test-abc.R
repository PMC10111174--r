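test_that("summary statistics: trivial values and vector shape", {
  block <- rbind(c(10, 20), c(10, 10), c(20, 20), c(10, 20))
  big <- block[rep(1:4, 25), ]
  gm <- toy_gm(list(rbind(big, big), rbind(big, big)),
               pop = rep(c("A", "B"), each = 100))
  s <- summary_stats(gm)
  expect_length(s, 4 * 2 + 3 * 1)
  expect_lt(abs(s[["Fst_A_B"]]), 0.005)
  expect_equal(s[["dmu2_A_B"]], 0, tolerance = 1e-12)
  ## groups fixed for alleles 10 and 20 -> (delta mu)^2 = 100
  gm2 <- toy_gm(list(rbind(matrix(10, 3, 2), matrix(20, 3, 2))),
                pop = rep(c("A", "B"), each = 3))
  expect_equal(summary_stats(gm2)[["dmu2_A_B"]], 100)
  expect_equal(summary_stats(gm2)[["Das_A_B"]], 1)
  ## vector length for G = 5
  g5 <- random_gm(n_pops = 5, n_per = 4, seed = 1)
  expect_length(summary_stats(g5), 4 * 5 + 3 * 10)
})

test_that("summary stats drop loci missing in a group consistently", {
  a1 <- rbind(c(1L, 5L), c(1L, 6L), c(2L, NA), c(2L, NA))
  gm <- genotype_matrix(a1, a1, pop = c("A", "A", "B", "B"))
  s <- summary_stats(gm)          # locus 2 untyped in B -> dropped
  expect_equal(s[["A_A"]], 1)     # one locus left, 1 allele in A
  expect_error(summary_stats(subset_gm(gm, ind = c(1, 3)),
                             groups = c("A", "B")), ">= 2")
})

test_that("reference tables are reproducible and balanced", {
  lib <- scenario_library()[c("scenario1", "scenario9")]
  ss <- c(I = 4L, II = 4L, III = 4L, IV = 4L, V = 4L)
  t1 <- build_reference_table(lib, 30L, ss, n_loci = 5L, seed = 99L)
  t2 <- build_reference_table(lib, 30L, ss, n_loci = 5L, seed = 99L)
  expect_identical(t1$stats, t2$stats)
  expect_identical(t1$params, t2$params)
  expect_equal(as.numeric(table(t1$scenario)), c(30, 30))
  t3 <- build_reference_table(lib, 30L, ss, n_loci = 5L, seed = 100L)
  expect_false(identical(t1$stats, t3$stats))
})

test_that("model choice: normalization, separation, invariance", {
  set.seed(2)
  ## synthetic two-scenario table with separable stats
  n <- 600
  stats <- rbind(matrix(rnorm(n * 3, 0), n, 3),
                 matrix(rnorm(n * 3, 6), n, 3))
  colnames(stats) <- c("s1", "s2", "s3")
  tab <- list(stats = stats,
              params = matrix(runif(2 * n), 2 * n, 1,
                              dimnames = list(NULL, "p1")),
              scenario = factor(rep(c("a", "b"), each = n)),
              mad = apply(stats, 2, mad))
  class(tab) <- "reference_table"
  s_obs <- c(s1 = 0, s2 = 0, s3 = 0)
  mc <- suppressWarnings(model_choice(tab, s_obs, tolerance = 0.1))
  expect_equal(sum(mc$direct), 1, tolerance = 1e-9)
  expect_equal(sum(mc$logistic), 1, tolerance = 1e-9)
  expect_gt(mc$logistic[["a"]], 0.95)
  ## direct and logistic agree on well-separated toys
  expect_lt(abs(mc$logistic[["a"]] - mc$direct[["a"]]), 0.15)
  ## affine rescaling of a stat (jointly with s_obs) changes nothing
  tab2 <- tab
  tab2$stats[, 2] <- 100 * tab2$stats[, 2] + 7
  tab2$mad <- apply(tab2$stats, 2, mad)
  mc2 <- suppressWarnings(model_choice(tab2, c(s1 = 0, s2 = 7, s3 = 0),
                                       tolerance = 0.1))
  expect_equal(mc2$logistic, mc$logistic, tolerance = 1e-6)
  ## zero-MAD statistic dropped with warning
  tab3 <- tab
  tab3$stats <- cbind(tab3$stats, s4 = 1)
  tab3$mad <- c(tab3$mad, s4 = 0)
  expect_warning(model_choice(tab3, c(s_obs, s4 = 1), tolerance = 0.1),
                 "zero-MAD")
})

test_that("an exactly matching retained point wins at tiny tolerance", {
  set.seed(3)
  n <- 500
  stats <- matrix(rnorm(2 * n * 2), 2 * n, 2,
                  dimnames = list(NULL, c("s1", "s2")))
  stats[777, ] <- c(40, -40)           # unique extreme point, scenario b
  tab <- list(stats = stats, params = matrix(0, 2 * n, 0),
              scenario = factor(rep(c("a", "b"), each = n)),
              mad = apply(stats, 2, mad))
  class(tab) <- "reference_table"
  mc <- suppressWarnings(model_choice(tab, c(s1 = 40, s2 = -40),
                                      tolerance = 0.004))
  expect_equal(names(which.max(mc$logistic)), "b")
})

test_that("parameter estimation: constants, bounds, known-truth toy", {
  set.seed(4)
  n <- 2000
  theta <- runif(n, 10, 50)
  stats <- cbind(s1 = theta + rnorm(n, 0, 1), s2 = rnorm(n))
  tab <- list(stats = stats,
              params = cbind(t1 = theta, fixed = rep(7, n)),
              scenario = factor(rep("a", n)),
              mad = apply(stats, 2, mad))
  class(tab) <- "reference_table"
  post <- estimate_params(tab, "a", c(s1 = 30, s2 = 0), tolerance = 0.1)
  r <- post[post$param == "t1", ]
  expect_gt(r$median, 27); expect_lt(r$median, 33)
  expect_true(r$q025 <= r$median && r$median <= r$q975)
  expect_true(r$q025 >= 10 - 1e-6 && r$q975 <= 50 + 1e-6)
  rc <- post[post$param == "fixed", ]
  expect_equal(rc$median, 7)
  expect_equal(rc$q025, 7)
})

test_that("confusion at chance level for identical scenario specs", {
  ## two copies of the same generating process: selection is a coin flip
  set.seed(5)
  lib <- scenario_library()["scenario1"]
  lib$copy <- lib$scenario1
  lib$copy$name <- "copy"
  ss <- c(I = 4L, II = 4L, III = 4L, IV = 4L, V = 4L)
  tab <- build_reference_table(lib, 150L, ss, n_loci = 5L, seed = 6L)
  cf <- suppressWarnings(abc_confusion(tab, "scenario1", n_pods = 40L,
                                       tolerance = 0.2, seed = 8L))
  expect_gt(cf$type_I, 0.25); expect_lt(cf$type_I, 0.75)
  expect_gt(cf$type_II, 0.25); expect_lt(cf$type_II, 0.75)
  expect_equal(cf$n_pods, 40L)
})

test_that("cluster subsampling is seeded and respects k", {
  gm <- random_gm(n_pops = 3, n_per = 10, seed = 7)
  s1 <- subsample_clusters(gm, k = 5L, seed = 3)
  s2 <- subsample_clusters(gm, k = 5L, seed = 3)
  expect_identical(s1$ind, s2$ind)
  expect_equal(as.numeric(table(s1$pop)), rep(5, 3))
  ## k equal to the cluster size is the identity subset
  s3 <- subsample_clusters(gm, k = 10L, seed = 3)
  expect_equal(n_ind(s3), 30L)
  expect_warning(subsample_clusters(gm, k = 11L, seed = 3), "only")
})
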