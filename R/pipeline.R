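## End-to-end orchestration with seeded stages and a run manifest.

derive_seed <- function(seed, stage) {
  ## fixed per-stage derivation so stage results do not depend on the
  ## execution order of other stages
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 69621 + h) %% 2147483587) + 1L
}

#' Pipeline configuration
#'
#' @param outdir output directory
#' @param seed master seed; every stage derives its own sub-seed
#' @param genepop optional input GenePop path (`NULL` generates synthetic
#'   data)
#' @param sites optional input site CSV
#' @param stages character vector from
#'   `c("synth", "diversity", "distances", "abc", "inbreed")`
#' @param synth a [synth_config()] (used when no input file is given)
#' @param n_perm,n_boot,tolerance,n_per_scenario,abc_samples,chain
#'   stage parameters; `chain` is a list with `n_iter`, `burnin`, `thin`
#' @return list of class `run_config`
#' @export
run_config <- function(outdir, seed = 1L, genepop = NULL, sites = NULL,
                       stages = c("synth", "diversity", "distances",
                                  "abc", "inbreed"),
                       synth = NULL, n_perm = 999L, n_boot = 100L,
                       tolerance = 0.05, n_per_scenario = 300L,
                       abc_samples = c(I = 10L, II = 10L, III = 10L,
                                       IV = 10L, V = 10L),
                       chain = list(n_iter = 4000L, burnin = 1000L,
                                    thin = 4L)) {
  out <- as.list(environment())
  class(out) <- "run_config"
  out
}

#' Run the pipeline end-to-end
#'
#' Stages execute in dependency order (io/synth, diversity,
#' distances/IBD, ABC, inbreeding); each writes its outputs under
#' `cfg$outdir` and records status, parameters, seed and output MD5
#' checksums in the run manifest (`manifest.json`). Stages not listed in
#' `cfg$stages` are marked `"skipped"`.
#'
#' @param cfg a [run_config()]
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "msatcoal",
                   version = as.character(utils::packageVersion("msatcoal")),
                   seed = cfg$seed, stages = list())
  outputs <- character(0)
  note <- function(stage, status, params = NULL, files = character(0)) {
    manifest$stages[[stage]] <<- list(
      status = status, seed = derive_seed(cfg$seed, stage),
      params = params,
      outputs = as.list(tools::md5sum(files)))
    outputs <<- c(outputs, files)
  }
  want <- function(s) s %in% cfg$stages
  gm <- NULL; sites <- NULL
  ## --- io / synth -------------------------------------------------
  if (!is.null(cfg$genepop)) {
    gm <- read_genepop(cfg$genepop)
    if (!is.null(cfg$sites)) sites <- read_sites(cfg$sites)
    note("synth", "input", params = list(genepop = cfg$genepop))
  } else if (want("synth")) {
    sc <- cfg$synth
    if (is.null(sc)) sc <- synth_config(seed = derive_seed(cfg$seed,
                                                           "synth"))
    syn <- generate_study_like(sc)
    gm <- syn$gm; sites <- syn$sites
    gp <- file.path(cfg$outdir, "synthetic.genepop")
    sp <- file.path(cfg$outdir, "synthetic_sites.csv")
    write_genepop(gm, gp)
    utils::write.csv(as.data.frame(sites), sp, row.names = FALSE)
    note("synth", "ok", params = list(seed = sc$seed), files = c(gp, sp))
  } else note("synth", "skipped")
  if (is.null(gm)) {
    manifest$stages[["error"]] <- "no input data and synth disabled"
    return(invisible(manifest))
  }
  vr <- validate_gm(gm)
  ## --- diversity --------------------------------------------------
  if (want("diversity")) {
    dt <- population_diversity(gm)
    fs <- global_fstats(gm)
    f <- file.path(cfg$outdir, "diversity.csv")
    utils::write.csv(as.data.frame(dt), f, row.names = FALSE)
    f2 <- file.path(cfg$outdir, "fstats.json")
    jsonlite::write_json(list(F_IS = fs$F_IS, F_ST = fs$F_ST,
                              F_IT = fs$F_IT,
                              missing_fraction = vr$missing_fraction),
                         f2, auto_unbox = TRUE, digits = NA)
    note("diversity", "ok", files = c(f, f2))
  } else note("diversity", "skipped")
  ## --- distances / IBD --------------------------------------------
  if (want("distances")) {
    sd_d <- derive_seed(cfg$seed, "distances")
    dc <- chord_distance_matrix(gm)
    f <- file.path(cfg$outdir, "chord_distance.csv")
    write_distance_csv(dc, f)
    files <- f
    if (!is.null(sites)) {
      gg <- great_circle_matrix(sites)
      mt <- mantel_test(dc, gg, n_perm = cfg$n_perm, seed = sd_d)
      f2 <- file.path(cfg$outdir, "mantel.json")
      jsonlite::write_json(list(r = mt$r, p = mt$p, n_perm = mt$n_perm),
                           f2, auto_unbox = TRUE, digits = NA)
      files <- c(files, f2)
    }
    tr <- bootstrap_nj(gm, n_boot = cfg$n_boot, seed = sd_d)
    f3 <- file.path(cfg$outdir, "nj_das.nwk")
    ape::write.tree(tr, f3)
    note("distances", "ok", params = list(n_perm = cfg$n_perm,
                                          n_boot = cfg$n_boot),
         files = c(files, f3))
  } else note("distances", "skipped")
  ## --- ABC --------------------------------------------------------
  if (want("abc")) {
    sd_a <- derive_seed(cfg$seed, "abc")
    lib <- scenario_library()[c("scenario1", "scenario9")]
    tab <- build_reference_table(lib, cfg$n_per_scenario,
                                 cfg$abc_samples, n_loci = n_loci(gm),
                                 seed = sd_a)
    cl <- if (!is.null(sites) && "cluster_id" %in% names(sites))
      stats::setNames(sites$cluster_id, sites$site_code) else NULL
    gma <- gm
    groups <- as.character(gma$pop)
    if (!is.null(cl) && all(!is.na(match(groups, names(cl))))) {
      groups <- unname(cl[groups])
      keep <- which(!is.na(groups))
      gma <- subset_gm(gm, ind = keep)
      groups <- groups[keep]
    }
    s_obs <- summary_stats(gma, groups)
    mc <- suppressWarnings(model_choice(tab, s_obs,
                                        tolerance = cfg$tolerance))
    f <- file.path(cfg$outdir, "abc_model_choice.json")
    jsonlite::write_json(list(direct = as.list(mc$direct),
                              logistic = as.list(mc$logistic),
                              tolerance = mc$tolerance),
                         f, auto_unbox = TRUE, digits = NA)
    note("abc", "ok", params = list(n_per_scenario = cfg$n_per_scenario,
                                    tolerance = cfg$tolerance),
         files = f)
  } else note("abc", "skipped")
  ## --- inbreeding -------------------------------------------------
  if (want("inbreed")) {
    sd_i <- derive_seed(cfg$seed, "inbreed")
    ip <- gibbs_inbreeding_null(gm, n_iter = cfg$chain$n_iter,
                                burnin = cfg$chain$burnin,
                                thin = cfg$chain$thin, seed = sd_i)
    f <- file.path(cfg$outdir, "inbreeding.json")
    jsonlite::write_json(list(F_mean = ip$F_mean,
                              F_hpd = as.list(ip$F_hpd),
                              null_freq = as.list(ip$null_freq),
                              DIC = ip$DIC),
                         f, auto_unbox = TRUE, digits = NA)
    note("inbreed", "ok", params = cfg$chain, files = f)
  } else note("inbreed", "skipped")
  mf <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Command-line interface
#'
#' Subcommands: `synth`, `stats`, `distances`, `mantel`, `tree`,
#' `abc-table`, `abc-choose`, `abc-confusion`, `inbreed`, `run`. Data go
#' to files (`--out`), logs to stderr. Returns 0 on success, 1 on user
#' error, 2 on internal error.
#'
#' @param argv character vector of arguments (excluding the program name)
#' @return integer exit status, invisibly
#' @export
msat_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() message(
    "usage: msatcoal <synth|stats|distances|mantel|tree|abc-table|",
    "abc-choose|abc-confusion|inbreed|run> [options]")
  if (!length(argv)) { usage(); return(invisible(1L)) }
  cmd <- argv[1]
  rest <- argv[-1]
  opts <- list(optparse::make_option("--input", type = "character",
                                     default = NULL),
               optparse::make_option("--sites", type = "character",
                                     default = NULL),
               optparse::make_option("--out", type = "character",
                                     default = "."),
               optparse::make_option("--seed", type = "integer",
                                     default = 1L),
               optparse::make_option("--n-perm", type = "integer",
                                     default = 999L, dest = "n_perm"),
               optparse::make_option("--n-boot", type = "integer",
                                     default = 100L, dest = "n_boot"),
               optparse::make_option("--tolerance", type = "double",
                                     default = 0.01),
               optparse::make_option("--n-pods", type = "integer",
                                     default = 500L, dest = "n_pods"),
               optparse::make_option("--n-per-scenario", type = "integer",
                                     default = 500L,
                                     dest = "n_per_scenario"))
  o <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = opts),
                         args = rest),
    error = function(e) e)
  if (inherits(o, "error")) { usage(); return(invisible(1L)) }
  status <- tryCatch({
    need_input <- function() {
      if (is.null(o$input)) stop("--input is required", call. = FALSE)
      read_genepop(o$input)
    }
    switch(cmd,
      synth = {
        dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
        syn <- generate_study_like(synth_config(seed = o$seed))
        write_genepop(syn$gm, file.path(o$out, "synthetic.genepop"))
        utils::write.csv(as.data.frame(syn$sites),
                         file.path(o$out, "synthetic_sites.csv"),
                         row.names = FALSE)
        0L
      },
      stats = {
        gm <- need_input()
        utils::write.csv(as.data.frame(population_diversity(gm)),
                         file.path(o$out, "diversity.csv"),
                         row.names = FALSE)
        0L
      },
      distances = {
        gm <- need_input()
        write_distance_csv(chord_distance_matrix(gm),
                           file.path(o$out, "chord_distance.csv"))
        write_distance_csv(shared_allele_distance(gm),
                           file.path(o$out, "das_distance.csv"))
        0L
      },
      mantel = {
        if (is.null(o$sites)) stop("--sites is required", call. = FALSE)
        st <- read_sites(o$sites)
        if (is.null(o$input)) stop("--input is required", call. = FALSE)
        gm <- read_genepop(o$input, pop_names = st$site_code)
        mt <- mantel_test(chord_distance_matrix(gm),
                          great_circle_matrix(st),
                          n_perm = o$n_perm, seed = o$seed)
        jsonlite::write_json(list(r = mt$r, p = mt$p,
                                  n_perm = mt$n_perm),
                             file.path(o$out, "mantel.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      tree = {
        gm <- need_input()
        tr <- bootstrap_nj(gm, n_boot = o$n_boot, seed = o$seed)
        ape::write.tree(tr, file.path(o$out, "nj_das.nwk"))
        0L
      },
      `abc-table` = ,
      `abc-choose` = ,
      `abc-confusion` = {
        lib <- scenario_library()[c("scenario1", "scenario9")]
        tab <- build_reference_table(lib, o$n_per_scenario,
                                     c(I = 10L, II = 10L, III = 10L,
                                       IV = 10L, V = 10L),
                                     seed = o$seed)
        if (cmd == "abc-table") {
          utils::write.csv(cbind(scenario = as.character(tab$scenario),
                                 as.data.frame(tab$stats)),
                           file.path(o$out, "reference_table.csv"),
                           row.names = FALSE)
        } else if (cmd == "abc-choose") {
          gm <- need_input()
          mc <- suppressWarnings(
            model_choice(tab, summary_stats(gm), o$tolerance))
          jsonlite::write_json(list(direct = as.list(mc$direct),
                                    logistic = as.list(mc$logistic)),
                               file.path(o$out, "model_choice.json"),
                               auto_unbox = TRUE, digits = NA)
        } else {
          cf <- abc_confusion(tab, "scenario9", n_pods = o$n_pods,
                              tolerance = o$tolerance, seed = o$seed)
          jsonlite::write_json(list(type_I = cf$type_I,
                                    type_II = cf$type_II),
                               file.path(o$out, "confusion.json"),
                               auto_unbox = TRUE, digits = NA)
        }
        0L
      },
      inbreed = {
        gm <- need_input()
        ip <- gibbs_inbreeding_null(gm, n_iter = 4000L, burnin = 1000L,
                                    thin = 4L, seed = o$seed)
        jsonlite::write_json(list(F_mean = ip$F_mean,
                                  F_hpd = as.list(ip$F_hpd)),
                             file.path(o$out, "inbreeding.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      run = {
        run_pipeline(run_config(outdir = o$out, seed = o$seed,
                                genepop = o$input, sites = o$sites))
        0L
      },
      { usage(); 1L })
  }, error = function(e) {
    if (grepl("is required", conditionMessage(e))) {
      message("error: ", conditionMessage(e)); 1L
    } else {
      message("internal error: ", conditionMessage(e)); 2L
    }
  })
  invisible(status)
}
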