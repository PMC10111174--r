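test_that("genotype_matrix enforces its invariants", {
  a1 <- matrix(c(1L, 2L), 2, 1); a2 <- matrix(c(1L, NA), 2, 1)
  expect_error(genotype_matrix(a1, a2, pop = c("A", "A")),
               "half-missing")
  expect_error(genotype_matrix(matrix(1L, 2, 1), matrix(1L, 2, 1),
                               pop = "A"), "one label per individual")
  gm <- toy_gm(list(cbind(c(1, 1, 2), c(1, 2, 2))), pop = rep("A", 3))
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(n_ind(gm), 3L)
  expect_equal(n_loci(gm), 1L)
})

test_that("GenePop write/read round-trips and parses toy files", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy data", "locA", "locB", "Pop",
               "a1 , 001002 003003", "a2 , 002002 003004",
               "a3 , 001001 000000", "Pop",
               "b1 , 005005 003003", "b2 , 005006 004004",
               "b3 , 006006 003004"), f)
  gm <- read_genepop(f)
  expect_equal(n_ind(gm), 6L)
  expect_equal(nlevels(gm$pop), 2L)
  expect_equal(n_loci(gm), 2L)
  expect_true(is.na(gm$a1[3, 2]) && is.na(gm$a2[3, 2]))
  expect_equal(unname(gm$a1[1, 1]), 1L)
  f2 <- withr::local_tempfile(fileext = ".gen")
  write_genepop(gm, f2)
  gm2 <- read_genepop(f2)
  expect_equal(gm2$a1, gm$a1)
  expect_equal(gm2$a2, gm$a2)
  expect_equal(as.character(gm2$pop), as.character(gm$pop))
})

test_that("GenePop parser reports malformed input precisely", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("bad", "locA", "locB", "Pop",
               "a1 , 001002"), f)                  # locus count mismatch
  expect_error(read_genepop(f), "expected 2 genotypes")
  writeLines(c("bad", "locA", "Pop", "a1 , 001000"), f)
  expect_error(read_genepop(f), "half-missing")
  writeLines(c("bad", "locA"), f)
  expect_error(read_genepop(f), "Pop")
})

test_that("writer refuses overflow and empty matrices", {
  gm <- toy_gm(list(cbind(150L, 150L)), pop = "A")
  expect_error(write_genepop(gm, tempfile(), dialect = "2-digit"),
               "does not fit")
  f <- withr::local_tempfile(fileext = ".gen")
  expect_silent(write_genepop(gm, f))              # minimal valid file
  expect_equal(n_ind(read_genepop(f)), 1L)
})

test_that("round-trip identity holds for random matrices (property)", {
  for (s in 1:5) {
    gm <- random_gm(n_pops = 4, n_per = 6, n_loci = 5, miss = 0.05,
                    seed = s)
    f <- withr::local_tempfile(fileext = ".gen")
    write_genepop(gm, f)
    gm2 <- read_genepop(f)
    expect_equal(unname(gm2$a1), unname(gm$a1))
    expect_equal(unname(gm2$a2), unname(gm$a2))
    vr <- validate_gm(gm2)
    expect_true(vr$missing_fraction >= 0 && vr$missing_fraction <= 1)
    expect_equal(sum(vr$pop_sizes), n_ind(gm2))
  }
})

test_that("CSV genotype dialect round-trips with configurable columns", {
  gm <- random_gm(seed = 9, miss = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotypes_csv(gm, f)
  gm2 <- read_genotypes_csv(f)
  expect_equal(unname(gm2$a1), unname(gm$a1))
  expect_equal(as.character(gm2$pop), as.character(gm$pop))
})

test_that("coordinate strings parse to decimal degrees", {
  expect_equal(parse_dms(c("60°31′", "21°15′")),
               c(60 + 31 / 60, 21.25), tolerance = 1e-12)
  expect_equal(parse_dms("0°00′"), 0)
  expect_equal(parse_dms("60d31m"), 60 + 31 / 60)
  expect_equal(parse_dms("-12.5"), -12.5)
  expect_error(parse_dms("sixty degrees"), "cannot parse")
})

test_that("site table reader validates and converts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_code,latitude,longitude",
               "A,60d31m,21d15m", "B,55.93,11.77"), f)
  st <- read_sites(f)
  expect_equal(st$latitude[1], 60 + 31 / 60, tolerance = 1e-12)
  writeLines(c("site_code,latitude,longitude",
               "A,95.0,10"), f)
  expect_error(read_sites(f), "latitude")
  writeLines(c("site_code,latitude,longitude", "A,10,10", "A,11,11"), f)
  expect_error(read_sites(f), "unique")
})

test_that("validation report counts missingness exactly", {
  gm <- random_gm(n_pops = 2, n_per = 5, n_loci = 10, miss = 0, seed = 3)
  expect_equal(validate_gm(gm)$missing_fraction, 0)
  a1 <- gm$a1; a2 <- gm$a2
  a1[1:5] <- NA; a2[1:5] <- NA
  gm2 <- genotype_matrix(a1, a2, pop = as.character(gm$pop))
  expect_equal(validate_gm(gm2)$missing_fraction, 5 / 100)
})

test_that("the shipped survey table loads: 16 sites, codes Vuo..Ror", {
  st <- survey_population_table()
  expect_equal(nrow(st), 16L)
  expect_equal(st$site_code[1], "Vuo")
  expect_equal(st$site_code[16], "Ror")
  expect_equal(st$latitude[1], 60 + 31 / 60, tolerance = 1e-12)
  expect_equal(sum(st$n), 329L)
})
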