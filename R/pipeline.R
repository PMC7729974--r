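# End-to-end orchestration: simulate (or load) -> frequency filter ->
# overlap -> paired origin screen -> biomarker panel -> run summary.
# One YAML/list config, two named seeds (data, model), and a JSON summary
# listing every output file with its MD5 hash so identical configs can be
# verified to reproduce identical artifacts.

#' Read a pipeline run configuration
#'
#' @param path YAML file; see [run_pipeline()] for the recognised fields.
#' @return the configuration as a nested list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

#' Run the full peptidome comparison pipeline
#'
#' Stages, in dependency order: obtain a cohort (either simulated from
#' `config$simulation`, or loaded from the file paths in `config$input`;
#' exactly one of the two must be present), detection-frequency filter per
#' fluid, two-fluid overlap (global Venn partition, per-bin trajectory, mass
#' summary), paired origin screen, and - when the sample table carries
#' discovery/validation outcome labels - Wilcoxon candidate selection,
#' random-forest training, cutoff optimisation and validation. All stage
#' outputs are written as CSV under `output_dir` plus a `run_summary.json`
#' with parameters, seeds and per-file MD5 hashes.
#'
#' @param config nested list or YAML path ([read_run_config()]). Fields:
#'   `simulation` (arguments of [simulation_config()], optional `puv` block
#'   with the four arm sizes of [generate_puv_cohort()]) or `input`
#'   (`abundance_af`, `abundance_fu`, `catalog`, `samples` paths);
#'   `filter$min_freq`; `screen$alpha`, `screen$min_detected_pairs`;
#'   `panel$alpha`, `panel$n_trees`, `panel$seed`, `panel$optimize_cutoff`.
#' @param output_dir directory for stage outputs (created).
#' @param verbose log stage progress to stderr.
#' @return the run summary (list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config, output_dir, verbose = FALSE) {
  if (is.character(config) && length(config) == 1) config <- read_run_config(config)
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    abort_config("exactly one of `simulation` and `input` must be configured.")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  # --- stage 1: cohort ------------------------------------------------------
  stage <- "cohort"
  cohort <- tryCatch({
    if (has_sim) {
      sim <- config$simulation
      puv <- sim$puv
      sim$puv <- NULL
      cfg <- do.call(simulation_config, sim)
      say("simulating cohort (data seed %d)", cfg$seed)
      if (is.null(puv)) generate_cohort(cfg) else {
        do.call(generate_puv_cohort, c(list(config = cfg), puv))
      }
    } else {
      say("loading cohort from input paths")
      inp <- config$input
      trip <- read_peptidome(inp$abundance_af, inp$catalog, inp$samples,
                             layout = inp$layout %||% "wide")
      samples <- assign_ga_bins(trip$samples)
      structure(list(catalog = trip$catalog, samples = samples,
                     af = trip$abundance,
                     fu = read_abundance(inp$abundance_fu, inp$layout %||% "wide"),
                     truth = NULL, config = NULL),
                class = "peptidome_cohort")
    }
  }, error = function(e) {
    abort(sprintf("stage '%s' failed: %s (check the simulation/input block)",
                  stage, conditionMessage(e)), class = "fetopep_stage_error")
  })
  write_cohort(cohort, file.path(output_dir, "cohort"))

  # --- stage 2: frequency filter -------------------------------------------
  min_freq <- config$filter$min_freq %||% 0.5
  af_samples <- cohort$samples[cohort$samples$fluid == "AF", ]
  fu_samples <- cohort$samples[cohort$samples$fluid == "FU", ]
  af_f <- frequency_filter(cohort$af, af_samples, min_freq)
  fu_f <- frequency_filter(cohort$fu, fu_samples, min_freq)
  say("filter kept %d AF and %d FU peptides (min_freq %.2f)",
      length(peptide_ids(af_f)), length(peptide_ids(fu_f)), min_freq)
  write_abundance(af_f, file.path(output_dir, "filtered_af.csv"))
  write_abundance(fu_f, file.path(output_dir, "filtered_fu.csv"))

  # --- stage 3: overlap -----------------------------------------------------
  venn <- venn_partition(af_f, fu_f)
  by_bin <- overlap_by_bin(cohort$af, cohort$fu, cohort$samples,
                           min_freq = min_freq)
  mass <- dplyr::bind_rows(
    AF = mass_summary(cohort$catalog, peptide_ids(af_f)),
    FU = mass_summary(cohort$catalog, peptide_ids(fu_f)),
    .id = "fluid"
  )
  readr::write_csv(tidy(venn), file.path(output_dir, "venn_partition.csv"),
                   progress = FALSE)
  readr::write_csv(by_bin, file.path(output_dir, "overlap_by_bin.csv"),
                   progress = FALSE)
  readr::write_csv(mass, file.path(output_dir, "mass_summary.csv"),
                   progress = FALSE)
  say("overlap: %d common of %d AF / %d FU peptides",
      venn$n_common, venn$n_af_total, venn$n_fu_total)

  # --- stage 4: origin screen ----------------------------------------------
  screen <- NULL
  n_pairs <- length(intersect(af_samples$patient_id, fu_samples$patient_id))
  if (n_pairs >= 3 && length(venn$common_ids) > 0) {
    screen <- paired_origin_screen(
      cohort$af, cohort$fu, cohort$samples, ids = venn$common_ids,
      alpha = config$screen$alpha %||% 0.05,
      min_detected_pairs = config$screen$min_detected_pairs %||% 3
    )
    readr::write_csv(screen, file.path(output_dir, "origin_screen.csv"),
                     progress = FALSE)
    say("origin screen: %d FU-origin peptides of %d common",
        sum(screen$selected), nrow(screen))
  } else {
    say("origin screen skipped (needs >= 3 AF/FU pairs and a common set)")
  }

  # --- stage 5: biomarker panel --------------------------------------------
  panel <- NULL
  has_cohorts <- all(c("discovery", "validation") %in% cohort$samples$cohort)
  if (!is.null(screen) && has_cohorts) {
    fu_origin <- screen$catalog_id[screen$selected]
    if (length(fu_origin)) {
      cand <- select_candidates(cohort$af, cohort$samples, fu_origin,
                                alpha = config$panel$alpha %||% 0.05)
      chosen <- cand$catalog_id[cand$selected]
      if (length(chosen) >= 1) {
        model_seed <- config$panel$seed %||% 42L
        model <- train_classifier(cohort$af, cohort$samples, chosen,
                                  n_trees = config$panel$n_trees %||% 1000,
                                  seed = model_seed)
        if (isTRUE(config$panel$optimize_cutoff)) {
          tr <- subset_cohort(cohort$af, cohort$samples, "discovery")
          trs <- panel_score(model, tr)
          model$cutoff <- optimize_cutoff(
            trs$score,
            cohort$samples$outcome[match(trs$sample_id, cohort$samples$sample_id)]
          )
        }
        report <- validate_panel(model, cohort$af, cohort$samples)
        panel <- list(candidates = cand, model = model, report = report)
        readr::write_csv(cand, file.path(output_dir, "panel_candidates.csv"),
                         progress = FALSE)
        readr::write_csv(report$scores, file.path(output_dir, "panel_scores.csv"),
                         progress = FALSE)
        readr::write_csv(tidy(report), file.path(output_dir, "panel_validation.csv"),
                         progress = FALSE)
        say("panel: %d peptides, sensitivity %.0f%%, specificity %.1f%%, AUC %.2f",
            length(chosen), report$sensitivity_pct, report$specificity_pct,
            report$auc)
      }
    }
  }

  # --- summary --------------------------------------------------------------
  files <- list.files(output_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "run_summary.json"]
  hashes <- tools::md5sum(files)
  summary <- list(
    package_version = as.character(utils::packageVersion("fetopep")),
    seeds = list(
      data = if (has_sim) (config$simulation$seed %||% 1L) else NULL,
      model = config$panel$seed %||% 42L
    ),
    parameters = list(
      min_freq = min_freq,
      screen_alpha = config$screen$alpha %||% 0.05,
      panel_alpha = config$panel$alpha %||% 0.05
    ),
    results = list(
      n_af_peptides = venn$n_af_total,
      n_fu_peptides = venn$n_fu_total,
      n_common = venn$n_common,
      pct_of_af_number = venn$pct_of_af_number,
      pct_of_af_abundance = venn$pct_of_af_abundance,
      n_fu_origin = if (!is.null(screen)) sum(screen$selected) else NULL,
      panel = if (!is.null(panel)) unclass(glance(panel$report)) else NULL
    ),
    files = lapply(seq_along(files), function(i) {
      list(path = sub(paste0("^", output_dir, "/?"), "", files[i]),
           md5 = unname(hashes[i]))
    })
  )
  jsonlite::write_json(summary, file.path(output_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
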