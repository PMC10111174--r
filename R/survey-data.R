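#' Published per-population summary table of the emulated survey
#'
#' The printed population overview shipped with the package: site codes,
#' coordinates, sample sizes, allele counts, private alleles, observed and
#' expected heterozygosity and inbreeding coefficients for the 16 coastal
#' populations, plus the default five-cluster assignment (`cluster_id`;
#' `NA` for the three small, poorly genotyped sites). Used as an input
#' table for calibration checks and as the source of default sample
#' sizes.
#'
#' @return a `site_table` data frame with one row per population
#' @export
survey_population_table <- function() {
  path <- system.file("extdata", "survey_populations.csv",
                      package = "msatcoal")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "survey_populations.csv")
  read_sites(path)
}
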