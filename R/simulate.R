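# Seeded synthetic two-fluid peptidome cohorts with known ground truth.
#
# The generator emulates the structure of a CE-MS peptidome comparison of
# amniotic fluid (AF) and fetal urine (FU): shared and fluid-specific
# peptides, log-normal abundances declining with gestational age, detection
# probabilities that rise with gestational age in AF up to the 29-31 WA bin
# and then plateau, paired AF/FU samples from the same fetus with a planted
# cross-fluid correlated peptide subset (Gaussian copula on the log scale),
# and an outcome-associated peptide subset with a multiplicative abundance
# shift in ESRD fetuses.

#' Simulation configuration
#'
#' Defaults mirror the design of the motivating two-fluid cohort: 1831
#' shared, 837 AF-only and 1426 FU-only peptides; 216 AF and 64 FU samples of
#' which 16 are AF/FU pairs from the same fetus; a 67-peptide planted
#' cross-fluid correlated subset; 7 outcome-associated peptides with a strong
#' (8-fold) abundance shift.
#'
#' @param n_peptides_shared,n_peptides_af_only,n_peptides_fu_only peptide
#'   counts per origin class.
#' @param n_af_samples,n_fu_samples,n_paired sample counts; `n_paired` AF/FU
#'   pairs share a `patient_id` and a gestational age.
#' @param ga_range gestational-age range in weeks of amenorrhea.
#' @param log_abundance_mean,log_abundance_sd log-scale location of
#'   per-peptide baseline abundance and the spread used both across peptides
#'   and as per-cell noise.
#' @param ga_trend multiplicative abundance factor per gestational bin
#'   (< 1 = decline with gestational age).
#' @param detection_prob either a single probability in (0, 1] used
#'   everywhere, or a list with elements `AF` and `FU`, each a length-8
#'   vector of per-bin detection probabilities. The default rises with
#'   gestational age in AF up to the sixth (29-31 WA) bin then plateaus, and
#'   is flat in FU except for a late rise.
#' @param corr_subset_size number of shared peptides planted with
#'   cross-fluid correlation in paired samples.
#' @param corr_strength target Spearman correlation in (0, 1] for the
#'   planted subset; the Gaussian-copula coefficient is calibrated as
#'   `2*sin(pi*corr_strength/6)` so the population rank correlation equals
#'   `corr_strength`.
#' @param n_outcome_peptides,outcome_effect_size outcome-associated peptides
#'   (drawn from the correlated subset) and their multiplicative abundance
#'   shift in ESRD samples.
#' @param frac_sequenced fraction of catalog peptides given an amino-acid
#'   sequence and parent-protein annotation.
#' @param seed integer seed; the full cohort is reproducible from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_peptides_shared = 1831,
                              n_peptides_af_only = 837,
                              n_peptides_fu_only = 1426,
                              n_af_samples = 216,
                              n_fu_samples = 64,
                              n_paired = 16,
                              ga_range = c(11, 39),
                              log_abundance_mean = log(1000),
                              log_abundance_sd = 0.8,
                              ga_trend = 0.9,
                              detection_prob = NULL,
                              corr_subset_size = 67,
                              corr_strength = 0.95,
                              n_outcome_peptides = 7,
                              outcome_effect_size = 8,
                              frac_sequenced = 0.23,
                              seed = 1L) {
  cfg <- list(
    n_peptides_shared = check_scalar_count(n_peptides_shared, "n_peptides_shared"),
    n_peptides_af_only = check_scalar_count(n_peptides_af_only, "n_peptides_af_only"),
    n_peptides_fu_only = check_scalar_count(n_peptides_fu_only, "n_peptides_fu_only"),
    n_af_samples = check_scalar_count(n_af_samples, "n_af_samples", min = 1),
    n_fu_samples = check_scalar_count(n_fu_samples, "n_fu_samples", min = 1),
    n_paired = check_scalar_count(n_paired, "n_paired"),
    ga_range = as.numeric(ga_range),
    log_abundance_mean = log_abundance_mean,
    log_abundance_sd = log_abundance_sd,
    ga_trend = ga_trend,
    detection_prob = detection_prob %||% list(
      AF = c(0.55, 0.60, 0.65, 0.70, 0.75, 0.85, 0.85, 0.85),
      FU = c(0.70, 0.70, 0.70, 0.70, 0.70, 0.70, 0.70, 0.80)
    ),
    corr_subset_size = check_scalar_count(corr_subset_size, "corr_subset_size"),
    corr_strength = corr_strength,
    n_outcome_peptides = check_scalar_count(n_outcome_peptides, "n_outcome_peptides"),
    outcome_effect_size = outcome_effect_size,
    frac_sequenced = frac_sequenced,
    seed = check_scalar_count(seed, "seed")
  )
  if (cfg$corr_subset_size > cfg$n_peptides_shared) {
    abort_config("corr_subset_size cannot exceed n_peptides_shared.")
  }
  if (cfg$n_outcome_peptides > max(cfg$corr_subset_size, cfg$n_peptides_shared)) {
    abort_config("n_outcome_peptides cannot exceed the correlated subset.")
  }
  if (cfg$n_paired > min(cfg$n_af_samples, cfg$n_fu_samples)) {
    abort_config("n_paired cannot exceed min(n_af_samples, n_fu_samples).")
  }
  if (!is.numeric(cfg$ga_range) || length(cfg$ga_range) != 2 ||
      cfg$ga_range[1] >= cfg$ga_range[2]) {
    abort_config("ga_range must be an increasing pair of weeks.")
  }
  if (cfg$corr_strength <= 0 || cfg$corr_strength > 1) {
    abort_config("corr_strength must lie in (0, 1].")
  }
  dp <- if (is.list(cfg$detection_prob)) unlist(cfg$detection_prob) else cfg$detection_prob
  if (any(dp <= 0 | dp > 1)) abort_config("detection_prob values must lie in (0, 1].")
  if (cfg$ga_trend <= 0) abort_config("ga_trend must be positive.")
  structure(cfg, class = "simulation_config")
}

detection_prob_for <- function(cfg, fluid, bin_idx) {
  dp <- cfg$detection_prob
  if (is.list(dp)) {
    v <- dp[[fluid]]
    v[pmin(bin_idx, length(v))]
  } else {
    rep(dp, length(bin_idx))
  }
}

PROTEIN_POOL <- c(
  "Collagen alpha-1(I) chain" = 0.40,
  "Collagen alpha-1(III) chain" = 0.20,
  "Collagen alpha-2(I) chain" = 0.15,
  "Insulin-like growth factor II" = 0.02,
  "Insulin-like growth factor-binding protein 7" = 0.02,
  "Fibrinogen alpha chain" = 0.03,
  "Osteopontin" = 0.02,
  "Apolipoprotein A-I" = 0.02,
  "Hemoglobin subunit beta" = 0.02,
  "Thymosin beta-4" = 0.02,
  "Inter-alpha-trypsin inhibitor heavy chain H4" = 0.02,
  "Uromodulin" = 0.08
)

simulate_catalog <- function(cfg) {
  n <- cfg$n_peptides_shared + cfg$n_peptides_af_only + cfg$n_peptides_fu_only
  ids <- sprintf("pep%05d", seq_len(n))
  mass <- rlnorm(n, meanlog = log(2400), sdlog = 0.42)
  mass <- pmax(mass, 805)
  mt <- runif(n, 19, 45)
  sequenced <- runif(n) < cfg$frac_sequenced
  seqs <- rep(NA_character_, n)
  prots <- rep(NA_character_, n)
  if (any(sequenced)) {
    lens <- pmax(7L, as.integer(round(mass[sequenced] / 110)))
    seqs[sequenced] <- vapply(
      lens,
      function(L) paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
      character(1)
    )
    prots[sequenced] <- sample(names(PROTEIN_POOL), sum(sequenced),
                               replace = TRUE, prob = PROTEIN_POOL)
  }
  tibble::tibble(
    catalog_id = ids, mass_da = mass, migration_time = mt,
    sequence = seqs, protein_name = prots
  )
}

simulate_samples <- function(cfg) {
  n_af <- cfg$n_af_samples
  n_fu <- cfg$n_fu_samples
  af_ids <- sprintf("AF%03d", seq_len(n_af))
  fu_ids <- sprintf("FU%03d", seq_len(n_fu))
  # paired samples share a fetus: same patient and gestational age
  pat_af <- sprintf("PT%04d", seq_len(n_af))
  pat_fu <- sprintf("PT%04d", n_af + seq_len(n_fu))
  if (cfg$n_paired > 0) pat_fu[seq_len(cfg$n_paired)] <- pat_af[seq_len(cfg$n_paired)]
  ga_af <- runif(n_af, cfg$ga_range[1], min(cfg$ga_range[2] + 1, 40) - 1e-9)
  ga_fu <- runif(n_fu, cfg$ga_range[1], min(cfg$ga_range[2] + 1, 40) - 1e-9)
  if (cfg$n_paired > 0) ga_fu[seq_len(cfg$n_paired)] <- ga_af[seq_len(cfg$n_paired)]
  samples <- tibble::tibble(
    sample_id = c(af_ids, fu_ids),
    fluid = rep(c("AF", "FU"), c(n_af, n_fu)),
    gestational_age_wa = c(ga_af, ga_fu),
    patient_id = c(pat_af, pat_fu),
    diagnosis = "CAKUT",
    outcome = NA_character_,
    cohort = NA_character_
  )
  assign_ga_bins(samples)
}

#' Generate a synthetic two-fluid peptidome cohort
#'
#' Abundances are log-normal with a monotone multiplicative decline across
#' gestational bins; detection is independent Bernoulli thinning after the
#' abundance draw (a non-detect zeroes the cell); fluid-specific peptides
#' never appear in the other fluid's matrix. For the planted correlated
#' subset, paired AF and FU log-noise is coupled through a Gaussian copula
#' calibrated to the target Spearman correlation. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param outcome_design optional tibble with columns `sample_rank`
#'   (`"paired"` or `"unpaired"` AF slot index), `outcome`
#'   (`"ESRD"`/`"noESRD"`) and `cohort` (`"discovery"`/`"validation"`);
#'   normally supplied via [generate_puv_cohort()].
#' @return a `peptidome_cohort` list: `catalog`, `samples`, `af`, `fu`
#'   (samples-by-peptides wide tibbles), `truth` (per-peptide origin class
#'   and outcome flag) and `config`.
#' @examples
#' cfg <- simulation_config(
#'   n_peptides_shared = 20, n_peptides_af_only = 5, n_peptides_fu_only = 5,
#'   n_af_samples = 12, n_fu_samples = 10, n_paired = 6,
#'   corr_subset_size = 4, n_outcome_peptides = 0, seed = 7
#' )
#' cohort <- generate_cohort(cfg)
#' dim(cohort$af)
#' @export
generate_cohort <- function(config, outcome_design = NULL) {
  cfg <- if (inherits(config, "simulation_config")) config else do.call(simulation_config, config)

  set.seed(cfg$seed)
  catalog <- simulate_catalog(cfg)

  set.seed(cfg$seed + 1L)
  samples <- simulate_samples(cfg)

  n_sh <- cfg$n_peptides_shared
  n_ao <- cfg$n_peptides_af_only
  n_fo <- cfg$n_peptides_fu_only
  origin <- rep(c("shared-uncorrelated", "AF-only", "FU-only"), c(n_sh, n_ao, n_fo))
  corr_idx <- seq_len(cfg$corr_subset_size)
  origin[corr_idx] <- "shared-correlated"
  outcome_flag <- rep(FALSE, nrow(catalog))
  if (cfg$n_outcome_peptides > 0) {
    pool <- if (cfg$corr_subset_size > 0) corr_idx else seq_len(n_sh)
    outcome_flag[pool[seq_len(cfg$n_outcome_peptides)]] <- TRUE
  }
  truth <- tibble::tibble(
    catalog_id = catalog$catalog_id,
    origin_class = origin,
    outcome_associated = outcome_flag
  )

  if (!is.null(outcome_design)) {
    samples <- apply_outcome_design(samples, outcome_design, cfg)
  }

  af_rows <- which(samples$fluid == "AF")
  fu_rows <- which(samples$fluid == "FU")
  af_pep <- which(origin != "FU-only")
  fu_pep <- which(origin != "AF-only")

  baseline <- NULL
  set.seed(cfg$seed + 2L)
  baseline <- rnorm(nrow(catalog), cfg$log_abundance_mean, cfg$log_abundance_sd)

  bin_idx <- as.integer(samples$ga_bin)
  trend <- log(cfg$ga_trend) * (bin_idx - 1L)

  set.seed(cfg$seed + 3L)
  z_fu <- matrix(rnorm(length(fu_rows) * length(fu_pep)),
                 nrow = length(fu_rows),
                 dimnames = list(samples$sample_id[fu_rows], catalog$catalog_id[fu_pep]))
  set.seed(cfg$seed + 4L)
  z_af <- matrix(rnorm(length(af_rows) * length(af_pep)),
                 nrow = length(af_rows),
                 dimnames = list(samples$sample_id[af_rows], catalog$catalog_id[af_pep]))

  # couple paired noise for the planted correlated subset (copula on log scale)
  if (cfg$n_paired > 0 && cfg$corr_subset_size > 0) {
    rho <- 2 * sin(pi * cfg$corr_strength / 6)
    corr_ids <- catalog$catalog_id[corr_idx]
    af_sub <- samples[af_rows, ]
    fu_sub <- samples[fu_rows, ]
    paired_pat <- intersect(af_sub$patient_id, fu_sub$patient_id)
    a <- match(paired_pat, af_sub$patient_id)
    f <- match(paired_pat, fu_sub$patient_id)
    z_af[a, corr_ids] <- rho * z_fu[f, corr_ids] +
      sqrt(1 - rho^2) * z_af[a, corr_ids]
  }

  build_matrix <- function(rows, pep, z, fluid) {
    logm <- matrix(baseline[pep], nrow = length(rows), ncol = length(pep),
                   byrow = TRUE)
    logm <- logm + trend[rows] + cfg$log_abundance_sd * z
    esrd <- which(!is.na(samples$outcome[rows]) & samples$outcome[rows] == "ESRD")
    flagged <- which(outcome_flag[pep])
    if (length(esrd) && length(flagged)) {
      logm[esrd, flagged] <- logm[esrd, flagged] + log(cfg$outcome_effect_size)
    }
    x <- exp(logm)
    p <- detection_prob_for(cfg, fluid, bin_idx[rows])
    det <- matrix(rbinom(length(x), 1L, rep(p, times = length(pep))),
                  nrow = length(rows))
    x * det
  }

  set.seed(cfg$seed + 5L)
  fu_m <- build_matrix(fu_rows, fu_pep, z_fu, "FU")
  set.seed(cfg$seed + 6L)
  af_m <- build_matrix(af_rows, af_pep, z_af, "AF")
  dimnames(af_m) <- list(samples$sample_id[af_rows], catalog$catalog_id[af_pep])
  dimnames(fu_m) <- list(samples$sample_id[fu_rows], catalog$catalog_id[fu_pep])

  structure(
    list(
      catalog = catalog,
      samples = samples,
      af = matrix_to_abundance(af_m),
      fu = matrix_to_abundance(fu_m),
      truth = truth,
      config = cfg
    ),
    class = "peptidome_cohort"
  )
}

apply_outcome_design <- function(samples, design, cfg) {
  af <- which(samples$fluid == "AF")
  paired_pat <- samples$patient_id[af][seq_len(cfg$n_paired)]
  n_pairs_needed <- sum(design$sample_rank == "paired")
  n_unpaired_needed <- sum(design$sample_rank == "unpaired")
  if (n_pairs_needed > cfg$n_paired) {
    abort_config("outcome design needs more paired patients than n_paired provides.")
  }
  if (n_unpaired_needed > length(af) - cfg$n_paired) {
    abort_config("outcome design needs more unpaired AF samples than available.")
  }
  paired_slots <- af[seq_len(cfg$n_paired)]
  unpaired_slots <- af[cfg$n_paired + seq_len(length(af) - cfg$n_paired)]
  k_p <- 0L; k_u <- 0L
  for (i in seq_len(nrow(design))) {
    slot <- if (design$sample_rank[i] == "paired") {
      k_p <- k_p + 1L; paired_slots[k_p]
    } else {
      k_u <- k_u + 1L; unpaired_slots[k_u]
    }
    samples$outcome[slot] <- design$outcome[i]
    samples$cohort[slot] <- design$cohort[i]
    samples$diagnosis[slot] <- "PUV"
    # outcome travels with the fetus: mirror onto the paired FU sample
    mate <- which(samples$fluid == "FU" &
                    samples$patient_id == samples$patient_id[slot])
    if (length(mate)) {
      samples$outcome[mate] <- design$outcome[i]
      samples$cohort[mate] <- design$cohort[i]
      samples$diagnosis[mate] <- "PUV"
    }
  }
  samples
}

#' Generate a synthetic PUV outcome cohort
#'
#' Adds discovery/validation cohort assignment and ESRD/noESRD outcome labels
#' to a generated cohort, mirroring a proof-of-concept prognosis design:
#' discovery fetuses are unpaired AF samples, validation fetuses are AF/FU
#' pairs (matched samples), and outcome-associated peptides carry their
#' abundance shift in both fluids of an ESRD fetus.
#'
#' @param config a [simulation_config()]; `n_paired` must cover the
#'   validation arm.
#' @param n_discovery_esrd,n_discovery_noesrd,n_validation_esrd,n_validation_noesrd
#'   arm sizes; the defaults 6/8 and 8/8 reproduce a 14-patient training and
#'   16-patient validation design.
#' @return a `peptidome_cohort`, see [generate_cohort()].
#' @export
generate_puv_cohort <- function(config,
                                n_discovery_esrd = 6,
                                n_discovery_noesrd = 8,
                                n_validation_esrd = 8,
                                n_validation_noesrd = 8) {
  for (n in c(n_discovery_esrd, n_discovery_noesrd,
              n_validation_esrd, n_validation_noesrd)) {
    check_scalar_count(n, "arm size", min = 1)
  }
  design <- tibble::tibble(
    sample_rank = rep(c("unpaired", "paired"),
                      c(n_discovery_esrd + n_discovery_noesrd,
                        n_validation_esrd + n_validation_noesrd)),
    outcome = c(rep("ESRD", n_discovery_esrd), rep("noESRD", n_discovery_noesrd),
                rep("ESRD", n_validation_esrd), rep("noESRD", n_validation_noesrd)),
    cohort = rep(c("discovery", "validation"),
                 c(n_discovery_esrd + n_discovery_noesrd,
                   n_validation_esrd + n_validation_noesrd))
  )
  generate_cohort(config, outcome_design = design)
}

#' @export
print.peptidome_cohort <- function(x, ...) {
  cat("<peptidome_cohort>\n")
  cat(sprintf("  catalog : %d peptides (%d sequenced)\n",
              nrow(x$catalog), sum(!is.na(x$catalog$sequence))))
  cat(sprintf("  samples : %d AF, %d FU (%d paired fetuses)\n",
              sum(x$samples$fluid == "AF"), sum(x$samples$fluid == "FU"),
              x$config$n_paired))
  cat(sprintf("  truth   : %s\n",
              paste(sprintf("%s=%d", names(table(x$truth$origin_class)),
                            table(x$truth$origin_class)), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to a directory of delimited files
#'
#' Writes `catalog.csv`, `samples.csv`, `abundance_af.csv`,
#' `abundance_fu.csv` (wide layout) and `ground_truth.csv`.
#'
#' @param cohort a `peptidome_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$catalog, file.path(dir, "catalog.csv"), progress = FALSE)
  readr::write_csv(cohort$samples, file.path(dir, "samples.csv"), progress = FALSE)
  write_abundance(cohort$af, file.path(dir, "abundance_af.csv"))
  write_abundance(cohort$fu, file.path(dir, "abundance_fu.csv"))
  if (!is.null(cohort$truth)) {
    readr::write_csv(cohort$truth, file.path(dir, "ground_truth.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return a `peptidome_cohort` (without a `config`; `truth` only if present).
#' @export
read_cohort <- function(dir) {
  af <- read_peptidome(file.path(dir, "abundance_af.csv"),
                       file.path(dir, "catalog.csv"),
                       file.path(dir, "samples.csv"),
                       total_ratio_warn = Inf)
  fu <- read_abundance(file.path(dir, "abundance_fu.csv"))
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) read_delim_quiet(truth_path)
  samples <- af$samples
  if (!"ga_bin" %in% names(samples) ||
      !is.factor(samples$ga_bin)) {
    samples <- assign_ga_bins(samples)
  }
  structure(
    list(catalog = af$catalog, samples = samples,
         af = af$abundance, fu = fu, truth = truth, config = NULL),
    class = "peptidome_cohort"
  )
}
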