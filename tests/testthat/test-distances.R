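test_that("chord distance: closed forms and oracle agreement", {
  ## identical frequency profiles -> 0
  block <- rbind(c(1, 2), c(1, 1), c(2, 2), c(1, 2))
  gm <- toy_gm(list(rbind(block, block)), pop = rep(c("A", "B"), each = 4))
  dc <- chord_distance_matrix(gm)
  expect_equal(dc["A", "B"], 0, tolerance = 1e-12)
  ## one locus, fixed different alleles -> (2/pi) * sqrt(2)
  gm2 <- toy_gm(list(rbind(matrix(1, 4, 2), matrix(9, 4, 2))),
                pop = rep(c("A", "B"), each = 4))
  expect_equal(chord_distance_matrix(gm2)["A", "B"], 2 * sqrt(2) / pi,
               tolerance = 1e-12)
  ## random 4-population toy vs brute-force oracle
  for (s in 1:5) {
    g <- random_gm(n_pops = 4, n_per = 6, n_loci = 3, seed = 200 + s,
                   miss = 0.05)
    d <- chord_distance_matrix(g)
    for (i in 1:3) for (j in (i + 1):4) {
      pi_ <- levels(g$pop)[i]; pj <- levels(g$pop)[j]
      expect_equal(d[pi_, pj], oracle_chord(g, pi_, pj),
                   tolerance = 1e-12)
    }
  }
})

test_that("shared-allele distance: hand counts and bounds", {
  ## identical monomorphic populations -> 0
  gm0 <- toy_gm(list(matrix(1, 4, 2)), pop = rep(c("A", "B"), each = 2))
  expect_equal(shared_allele_distance(gm0)["A", "B"], 0)
  ## disjoint fixed alleles at all loci -> 1
  gm1 <- toy_gm(list(rbind(matrix(1, 2, 2), matrix(9, 2, 2)),
                     rbind(matrix(2, 2, 2), matrix(8, 2, 2))),
                pop = rep(c("A", "B"), each = 2))
  expect_equal(shared_allele_distance(gm1)["A", "B"], 1)
  ## two individuals, one shared allele at one of two loci -> 0.75
  gm2 <- toy_gm(list(rbind(c(1, 2), c(2, 3)), rbind(c(4, 4), c(5, 6))),
                pop = c("A", "B"))
  expect_equal(shared_allele_distance(gm2)["A", "B"], 1 - (0.5 + 0) / 2)
  ## homozygote vs heterozygote carrying that allele share exactly one
  gm3 <- toy_gm(list(rbind(c(1, 1), c(1, 2))), pop = c("A", "B"))
  expect_equal(shared_allele_distance(gm3)["A", "B"], 1 - 1 / 2)
})

test_that("distance matrices satisfy symmetry/diagonal/nonnegativity", {
  for (s in 1:5) {
    g <- random_gm(n_pops = 4, n_per = 5, seed = 300 + s, miss = 0.05)
    for (d in list(chord_distance_matrix(g), shared_allele_distance(g))) {
      m <- unclass(d)
      expect_equal(m, t(m))
      expect_equal(unname(diag(m)), rep(0, 4))
      expect_true(all(m >= 0, na.rm = TRUE))
    }
  }
})

test_that("great-circle distances match closed forms", {
  st <- data.frame(site_code = c("a", "b", "c", "d"),
                   latitude = c(0, 1, 0, 0),
                   longitude = c(0, 0, 0, 180))
  d <- great_circle_matrix(st)
  expect_equal(d["a", "b"], 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], pi * 6371, tolerance = 1e-6)
  st$latitude[1] <- NA
  expect_error(great_circle_matrix(st), "missing")
})

test_that("NJ recovers additive trees; three-point case is exact", {
  ## additive 4-taxon matrix with split (A,B)|(C,D)
  m <- matrix(c(0, 2, 7, 8,
                2, 0, 7, 8,
                7, 7, 0, 3,
                8, 8, 3, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(m)
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")) ||
                ape::is.monophyletic(ape::unroot(tr), c("C", "D")))
  ## 3 taxa: branch lengths solve the three-point equations
  m3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr3 <- nj_tree(m3)
  x <- (3 + 5 - 6) / 2
  expect_equal(sort(tr3$edge.length), sort(c(x, 3 - x, 5 - x)),
               tolerance = 1e-12)
  m[1, 2] <- NA; m[2, 1] <- NA
  expect_error(nj_tree(m), "prune")
})

test_that("bootstrap support is low without signal", {
  ## all loci share the same frequency profile: no stable topology
  set.seed(5)
  base <- matrix(sample(1:4, 40, TRUE), 20, 2)
  gm <- toy_gm(list(base, base, base, base),
               pop = rep(c("A", "B", "C", "D", "E"), each = 4))
  tr <- bootstrap_nj(gm, n_boot = 50, seed = 3)
  expect_true(all(tr$node.label <= 100))
  expect_equal(ape::Ntip(tr), 5L)
})

test_that("Mantel test: identity, affine invariance, error cases", {
  set.seed(6)
  n <- 8
  a <- matrix(runif(n * n), n, n); a <- a + t(a); diag(a) <- 0
  rownames(a) <- colnames(a) <- letters[1:n]
  mt <- mantel_test(a, a, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)
  mt2 <- mantel_test(a, 3 * a + 1 - diag(n), n_perm = 99, seed = 1)
  expect_equal(mt2$r, 1, tolerance = 1e-12)
  expect_error(mantel_test(a, matrix(0, n, n,
    dimnames = dimnames(a)), n_perm = 99), "constant")
  expect_error(mantel_test(a, a[c(2, 1, 3:8), c(2, 1, 3:8)],
                           n_perm = 99), "labels")
})

test_that("Mantel agrees with vegan and is null-calibrated", {
  skip_if_not_installed("vegan")
  set.seed(9)
  n <- 10
  a <- as.matrix(dist(runif(n))); rownames(a) <- colnames(a) <- letters[1:n]
  b <- as.matrix(dist(runif(n))); rownames(b) <- colnames(b) <- letters[1:n]
  mt <- mantel_test(a, b, n_perm = 199, seed = 4)
  vg <- vegan::mantel(as.dist(a), as.dist(b), permutations = 199)
  expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-10)
  ## null calibration over replicates
  set.seed(10)
  ps <- replicate(300, {
    x <- as.matrix(dist(runif(7))); y <- as.matrix(dist(runif(7)))
    dimnames(x) <- dimnames(y) <- NULL
    mantel_test(x, y, n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  expect_true(all(ps > 0 & ps <= 1))
  expect_gt(mean(ps), 0.42)
  expect_lt(mean(ps), 0.58)
  expect_lt(mean(ps <= 0.05), 0.12)
})
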