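#' Run the full delimitation pipeline
#'
#' Config-driven end-to-end run mirroring the analysis order of a
#' SNP-based species-delimitation study: filter -> ordinate -> hybrid
#' classification -> fixed-difference delimitation (with hybrids excluded)
#' -> heterozygosity -> kinship -> morphometrics. Each stage writes CSV
#' output under `out_dir` and the run ends with a JSON manifest listing
#' every emitted file with its checksum, the configuration hash, the seed
#' and package version.
#'
#' Individuals whose posterior probability of any non-parental class
#' exceeds 0.5 are treated as putative hybrids and excluded from
#' delimitation and diversity automatically.
#'
#' The single `seed` is forked deterministically into independent per-stage
#' seeds, so disabling one stage does not perturb another's randomness.
#'
#' @param config a run configuration: an R list or a YAML file path. Keys:
#'   `simulate` (logical or a list of [sim_config()] arguments) or `input`
#'   (list with `dart_csv`, optional `populations_csv` with columns
#'   id,population, optional `morph_csv`); optional per-stage blocks
#'   `filtering`, `ordination` (k), `delimitation` (alpha, tolerance,
#'   n_sim, exclude_individuals), `diversity` (reps), `hybrids` (burnin,
#'   sweeps, enabled), `relatedness` (threshold_mads); `stages` (character
#'   subset to run).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (mandatory: every stochastic stage draws from
#'   it).
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_full_analysis <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  has_sim <- !is.null(config$simulate) && !isFALSE(config$simulate)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    stop("exactly one of 'simulate' or 'input' must be present")

  all_stages <- c("filter", "pcoa", "hybrids", "delimit", "diversity",
                  "kin", "morph")
  stages <- config$stages %||% all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) stop("unknown stage(s): ",
                            paste(unknown, collapse = ", "))
  set.seed(seed)
  stage_seeds <- stats::setNames(
    sample.int(.Machine$integer.max, length(all_stages) + 1), # +1: simulate
    c("simulate", all_stages))
  results <- list()
  emitted <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    emitted <<- c(emitted, path)
    path
  }
  log_stage <- function(...) message("[snpdelim] ", ...)

  # ---- input ----
  morph <- NULL
  if (has_sim) {
    set.seed(stage_seeds[["simulate"]])
    sim_args <- if (is.list(config$simulate)) config$simulate else list()
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_study(scfg)
    gm <- sim$gm
    morph <- sim$morph
    results$truth <- sim$truth
    emit(as.data.frame(sim$truth$individuals), "sim_individuals.csv")
  } else {
    pops <- "unknown"
    if (!is.null(config$input$populations_csv)) {
      ptab <- utils::read.csv(config$input$populations_csv)
      pops <- stats::setNames(as.character(ptab$population),
                              as.character(ptab$id))
    }
    gm <- read_dart_csv(config$input$dart_csv, populations = pops)
    if (!is.null(config$input$morph_csv))
      morph <- morph_table(utils::read.csv(config$input$morph_csv))
  }

  # ---- filter ----
  if ("filter" %in% stages) {
    log_stage("filter: ", n_loci(gm), " loci, ", n_individuals(gm),
              " individuals in")
    fcfg <- do.call(filter_config, config$filtering %||% list())
    fl <- run_filter_pipeline(gm, fcfg)
    gm <- fl$gm
    results$filter <- fl$report
    emit(as.data.frame(fl$report), "filter_report.csv")
  }

  # ---- pcoa ----
  if ("pcoa" %in% stages) {
    log_stage("pcoa")
    ord <- pcoa(genetic_distance(gm),
                k = config$ordination$k %||% NULL,
                populations = gm$populations)
    results$pcoa <- ord
    emit(data.frame(id = rownames(ord$coordinates),
                    population = unname(gm$populations),
                    ord$coordinates), "pcoa_coordinates.csv")
    emit(scree(ord), "pcoa_scree.csv")
  }

  # ---- hybrids ----
  hybrid_ids <- character(0)
  if ("hybrids" %in% stages) {
    log_stage("hybrids")
    set.seed(stage_seeds[["hybrids"]])
    hcfg <- config$hybrids %||% list()
    hp <- classify_hybrids(gm, burnin = hcfg$burnin %||% 10000,
                           sweeps = hcfg$sweeps %||% 10000)
    results$hybrids <- hp
    emit(assignment_table(hp), "hybrid_assignments.csv")
    nonpar <- hp$posterior[, !(colnames(hp$posterior) %in% c("P0", "P1")),
                           drop = FALSE]
    hybrid_ids <- rownames(hp$posterior)[apply(nonpar, 1, max) > 0.5]
  }

  # ---- delimit ----
  otus <- NULL
  if ("delimit" %in% stages) {
    log_stage("delimit (", length(hybrid_ids), " putative hybrid(s)",
              " excluded)")
    set.seed(stage_seeds[["delimit"]])
    dcfg <- config$delimitation %||% list()
    excl <- unique(c(hybrid_ids,
                     unlist(dcfg$exclude_individuals) %||% character(0)))
    fd <- amalgamate_otus(gm,
                          alpha = dcfg$alpha %||% 0.05,
                          tolerance = dcfg$tolerance %||% 0,
                          n_sim = dcfg$n_sim %||% 1000,
                          exclude = excl)
    results$delimitation <- fd
    otus <- fd$otus
    m <- fd$percents
    m[upper.tri(m)] <- fd$mean_n[upper.tri(m)]
    emit(data.frame(population = rownames(m), round(m, 2),
                    check.names = FALSE), "fixed_differences.csv")
    emit(data.frame(population = names(fd$otus), otu = unname(fd$otus)),
         "otu_assignment.csv")
    gm_no_hyb <- drop_individuals(gm, excl)
    aft_otu <- allele_frequencies(
      gm_no_hyb, grouping = unname(otus[gm_no_hyb$populations]))
    pa <- private_allele_matrix(aft_otu)
    emit(data.frame(otu = rownames(pa), pa, check.names = FALSE),
         "private_alleles.csv")
  }

  # ---- diversity ----
  if ("diversity" %in% stages) {
    log_stage("diversity")
    set.seed(stage_seeds[["diversity"]])
    gm_div <- drop_individuals(gm, hybrid_ids)
    grouping <- if (!is.null(otus)) unname(otus[gm_div$populations]) else
      gm_div$populations
    gm_grp <- gm_div
    gm_grp$populations <- stats::setNames(grouping, individual_ids(gm_div))
    he <- expected_heterozygosity(gm_grp)
    emit(data.frame(group = names(he), he = unname(he)),
         "heterozygosity.csv")
    reps <- config$diversity$reps %||% 10000
    groups <- names(he)
    tests <- list()
    if (length(groups) > 1) {
      for (i in seq_len(length(groups) - 1))
        for (j in seq(i + 1, length(groups))) {
          tt <- heterozygosity_randomization_test(gm_grp, groups[i],
                                                  groups[j], reps = reps)
          tests[[length(tests) + 1]] <-
            data.frame(groupA = groups[i], groupB = groups[j],
                       heA = tt$he[1], heB = tt$he[2],
                       delta_he = tt$delta_he, pvalue = tt$pvalue,
                       reps = reps)
        }
    }
    results$diversity <- list(he = he, tests = do.call(rbind, tests))
    if (length(tests)) emit(results$diversity$tests,
                            "heterozygosity_tests.csv")
  }

  # ---- kin ----
  if ("kin" %in% stages) {
    log_stage("kin")
    scan <- pairwise_inconsistency_null(gm)
    flags <- detect_parent_offspring(
      scan, threshold_mads = config$relatedness$threshold_mads %||% 5)
    scan$pairs$flagged <- paste(scan$pairs$idA, scan$pairs$idB) %in%
      paste(flags$idA, flags$idB)
    results$kin <- list(scan = scan, flags = flags)
    emit(scan$pairs, "kinship_pairs.csv")
  }

  # ---- morph ----
  if ("morph" %in% stages && !is.null(morph)) {
    log_stage("morph")
    results$morph <- list(
      summary = region_summary(morph),
      sex_screen = sex_effect_screen(morph),
      tukey = tukey_kramer(morph),
      cva = cva(morph),
      pca = pca_morph(morph))
    emit(results$morph$summary, "morph_summary.csv")
    emit(results$morph$tukey, "morph_tukey.csv")
    emit(data.frame(id = morph$id, region = morph$region,
                    results$morph$cva$scores), "morph_cva_scores.csv")
  }

  # ---- manifest ----
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  cfg_file <- tempfile(fileext = ".json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    package = "snpdelim",
    version = as.character(utils::packageVersion("snpdelim")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = stages,
    files = lapply(stats::setNames(emitted, basename(emitted)),
                   function(f) list(md5 = unname(tools::md5sum(f)))))
  unlink(cfg_file)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  results$manifest <- manifest
  invisible(results)
}
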