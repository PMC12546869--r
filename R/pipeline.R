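#' Assemble a pipeline run configuration
#'
#' A validated list of input paths, reader-profile names, thresholds and
#' output settings consumed by [run_pipeline()]. The configuration
#' round-trips unchanged through JSON serialization in the run manifest.
#'
#' @param stages stages to execute, any of `"targets"`, `"simulate"`,
#'   `"occupancy"`, `"methyl"`, `"silac"`, `"growth"`, `"enrich"`, `"de"`.
#' @param out_dir output directory.
#' @param seed root seed for the `"simulate"` stage.
#' @param xic_path,methyl_path,silac_path,growth_path,de_path,
#'   annotation_path,study_path,background_path input file paths for the
#'   corresponding stages (stages without inputs are skipped with an error
#'   naming the stage).
#' @param xic_profile,silac_profile,growth_profile,de_profile reader
#'   profile names.
#' @param fc_threshold,q_threshold,p_threshold decision thresholds.
#' @param charges inclusion-list charge states.
#' @param window,od_floor growth-curve estimator settings.
#' @return a list of class `run_config`.
#' @export
run_config <- function(stages = "targets", out_dir = tempfile("ptmrun"),
                       seed = 1, xic_path = NULL, methyl_path = NULL,
                       silac_path = NULL, growth_path = NULL,
                       de_path = NULL, annotation_path = NULL,
                       study_path = NULL, background_path = NULL,
                       xic_profile = "default", silac_profile = "default",
                       growth_profile = "default", de_profile = "default",
                       fc_threshold = 0.8, q_threshold = 0.05,
                       p_threshold = 0.05, charges = c(2, 3), window = 6,
                       od_floor = 0.02) {
  known <- c("targets", "simulate", "occupancy", "methyl", "silac",
             "growth", "enrich", "de")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stop("unknown stage: ", bad[[1L]])
  stopifnot(fc_threshold > 0, q_threshold > 0, p_threshold > 0,
            window >= 2)
  cfg <- list(stages = stages, out_dir = out_dir, seed = seed,
              xic_path = xic_path, methyl_path = methyl_path,
              silac_path = silac_path, growth_path = growth_path,
              de_path = de_path, annotation_path = annotation_path,
              study_path = study_path, background_path = background_path,
              xic_profile = xic_profile, silac_profile = silac_profile,
              growth_profile = growth_profile, de_profile = de_profile,
              fc_threshold = fc_threshold, q_threshold = q_threshold,
              p_threshold = p_threshold, charges = charges,
              window = window, od_floor = od_floor)
  structure(cfg, class = "run_config")
}

#' Execute the analysis pipeline
#'
#' Runs the requested stages, writes their tidy CSV outputs to
#' `config$out_dir`, logs record counts through every filter, and writes a
#' machine-readable run manifest (`manifest.json`: configuration, package
#' version, seed, MD5 hash of every output file). Any stage error aborts
#' with a message naming the stage. Identical configuration and seed
#' produce identical outputs and hashes.
#'
#' @param config a [run_config()].
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    outputs[[name]] <<- path
    path
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  need <- function(path, stage) {
    if (is.null(path)) stop("no input path configured")
    if (!file.exists(path)) stop("input file not found: ", path)
    path
  }

  for (stage in config$stages) {
    switch(stage,
      targets = run_stage("targets", function() {
        lst <- h3k36_inclusion_list(charges = config$charges)
        path <- file.path(config$out_dir, "inclusion_list.csv")
        write_inclusion_list(lst, path)
        outputs[["inclusion_list"]] <<- path
        message("targets: wrote ", nrow(lst), " PRM targets")
      }),
      simulate = run_stage("simulate", function() {
        s <- config$seed
        write_scenario(gen_xic_table(theta = c(0.1, 0.5, 0.9), seed = s),
                       config$out_dir, "sim_xic")
        write_scenario(gen_methyl_profiles(c(0.7, 0.2, 0.05, 0.05),
                                           seed = s),
                       config$out_dir, "sim_methyl")
        write_scenario(gen_silac_experiment(seed = s), config$out_dir,
                       "sim_silac")
        write_scenario(gen_growth_curves(c(90, 90, 120), noise_sd = 0.02,
                                         seed = s),
                       config$out_dir, "sim_growth")
        sims <- list.files(config$out_dir, pattern = "^sim_",
                           full.names = TRUE)
        for (f in sims) outputs[[basename(f)]] <<- f
        message("simulate: wrote ", length(sims), " files (seed ", s, ")")
      }),
      occupancy = run_stage("occupancy", function() {
        x <- read_xic_table(need(config$xic_path), config$xic_profile)
        message("occupancy: ", nrow(x), " records in")
        occ <- phospho_occupancy(x)
        emit(occ, "occupancy")
        emit(summarize_occupancy(occ,
                                 by = c("group_id", "form_id",
                                        "site_labels", "form_class",
                                        "sample")),
             "occupancy_summary")
        message("occupancy: ", nrow(occ), " fractions out")
      }),
      methyl = run_stage("methyl", function() {
        x <- read_xic_table_methyl(need(config$methyl_path))
        stoich <- methyl_stoichiometry(x)
        emit(stoich, "methyl_stoichiometry")
        emit(summarize_occupancy(stoich, by = c("sample", "state")),
             "methyl_summary")
        message("methyl: ", nrow(stoich), " state fractions out")
      }),
      silac = run_stage("silac", function() {
        x <- read_silac_table(need(config$silac_path),
                              config$silac_profile)
        message("silac: ", nrow(x), " protein rows in")
        filt <- filter_proteins(x, verbose = TRUE)
        oriented <- normalize_and_orient(filt)
        res <- differential_abundance(oriented,
                                      fc_threshold = config$fc_threshold,
                                      q_threshold = config$q_threshold)
        emit(oriented, "silac_oriented")
        emit(res, "silac_differential")
        message("silac: ", sum(res$call != "unchanged"),
                " differential calls")
      }),
      growth = run_stage("growth", function() {
        x <- read_growth_table(need(config$growth_path),
                               config$growth_profile)
        fits <- fit_doubling_times(x, window = config$window,
                                   od_floor = config$od_floor)
        emit(fits, "doubling_times")
        emit(compare_doubling_times(fits), "doubling_time_summary")
        message("growth: ", nrow(fits), " curves fitted")
      }),
      enrich = run_stage("enrich", function() {
        study <- readLines(need(config$study_path), warn = FALSE)
        background <- readLines(need(config$background_path),
                                warn = FALSE)
        ann <- read_annotations(need(config$annotation_path))
        res <- hypergeometric_enrichment(study, background, ann)
        emit(res, "enrichment")
        message("enrich: ", nrow(res), " terms tested, ",
                sum(res$q_value < config$p_threshold), " significant")
      }),
      de = run_stage("de", function() {
        x <- read_de_table(need(config$de_path), config$de_profile)
        res <- classify_de(x, fc_threshold = config$fc_threshold,
                           p_threshold = config$p_threshold)
        emit(res, "de_classified")
        message("de: ", sum(res$call == "up"), " up, ",
                sum(res$call == "down"), " down of ", nrow(res))
      })
    )
  }

  manifest <- list(
    config = unclass(config),
    package = "ptmstoich",
    version = as.character(utils::packageVersion("ptmstoich")),
    seed = config$seed,
    files = as.list(tools::md5sum(unlist(outputs)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  outputs[["manifest"]] <- manifest_path
  invisible(outputs)
}

# methyl-profile XIC reader: form_id/area/sample/replicate (+charge)
read_xic_table_methyl <- function(path) {
  x <- .read_delim_auto(path)
  needed <- c("form_id", "area", "sample", "replicate")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    stop("input lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  x$area <- as.numeric(x$area)
  x
}
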