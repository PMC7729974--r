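# Outcome biomarker panel: Wilcoxon candidate selection on a discovery
# cohort, random-forest scoring (vote-fraction difference, natural cutoff 0),
# Youden-optimal cutoff, and validation with exact binomial confidence
# intervals and DeLong AUC inference.

OUTCOME_LEVELS <- c("noESRD", "ESRD")

outcome_factor <- function(x) {
  bad <- !is.na(x) & !x %in% OUTCOME_LEVELS
  if (any(bad)) abort_data("outcome labels must be 'ESRD' or 'noESRD'.")
  factor(x, levels = OUTCOME_LEVELS)
}

subset_cohort <- function(abundance, samples, cohort) {
  keep <- samples$sample_id[!is.na(samples$cohort) & samples$cohort == cohort]
  abundance[abundance$sample_id %in% keep, , drop = FALSE]
}

#' Select outcome-associated candidate peptides (Wilcoxon)
#'
#' Compares, per candidate peptide, abundances between ESRD and noESRD
#' samples of the discovery cohort with a two-sided Wilcoxon rank-sum test
#' (exact for small tie-free groups, normal approximation with continuity
#' correction otherwise).
#'
#' @param abundance abundance tibble (AF matrix).
#' @param samples sample table with `outcome` and `cohort` columns.
#' @param candidate_ids peptides eligible for the panel (typically the
#'   FU-origin set from [paired_origin_screen()]).
#' @param alpha selection level on the two-sided p-value.
#' @param cohort which cohort to test on (default `"discovery"`).
#' @return tibble ordered by p: `catalog_id`, `statistic`, `p_value`,
#'   `selected`. Candidates absent from the matrix are dropped with a
#'   warning.
#' @export
select_candidates <- function(abundance, samples, candidate_ids, alpha = 0.05,
                              cohort = "discovery") {
  sub <- subset_cohort(abundance, samples, cohort)
  if (!nrow(sub)) abort_usage(sprintf("no samples in cohort '%s'.", cohort))
  m <- abundance_to_matrix(sub)
  lab <- outcome_factor(samples$outcome[match(rownames(m), samples$sample_id)])
  if (anyNA(lab)) abort_usage("all cohort samples need an ESRD/noESRD outcome label.")
  if (nlevels(droplevels(lab)) < 2) {
    abort_usage("both outcome classes must be present in the discovery cohort.")
  }
  present <- intersect(candidate_ids, colnames(m))
  if (!length(present)) {
    warn("none of the candidate peptides are present in the abundance matrix.")
    return(tibble::tibble(catalog_id = character(), statistic = numeric(),
                          p_value = numeric(), selected = logical()))
  }
  if (length(present) < length(candidate_ids)) {
    warn(sprintf("%d candidate peptide(s) absent from the matrix were dropped.",
                 length(candidate_ids) - length(present)))
  }
  res <- purrr::map_dfr(present, function(id) {
    ht <- suppressWarnings(
      wilcox.test(m[lab == "ESRD", id], m[lab == "noESRD", id],
                  alternative = "two.sided")
    )
    tibble::tibble(catalog_id = id, statistic = unname(ht$statistic),
                   p_value = ht$p.value)
  })
  res$selected <- res$p_value < alpha
  dplyr::arrange(res, .data$p_value)
}

#' Train a random-forest panel classifier
#'
#' Fits a random forest (1000 trees by default, other hyper-parameters at
#' package defaults) on the discovery-cohort abundances of the panel
#' peptides, predicting the ESRD/noESRD outcome. Deterministic given `seed`.
#'
#' @param abundance abundance tibble.
#' @param samples sample table with `outcome` and `cohort`.
#' @param peptide_ids panel peptides (non-empty, present in the matrix).
#' @param n_trees number of trees.
#' @param seed RNG seed for the forest.
#' @param cohort training cohort label.
#' @return a `panel_model`: the fitted forest plus `peptide_ids`, `n_trees`,
#'   `seed` and `cutoff` (initialised to 0, the natural threshold of the
#'   vote-difference score; see [optimize_cutoff()]).
#' @export
train_classifier <- function(abundance, samples, peptide_ids, n_trees = 1000,
                             seed = 1L, cohort = "discovery") {
  if (!length(peptide_ids)) abort_usage("`peptide_ids` must be non-empty.")
  n_trees <- check_scalar_count(n_trees, "n_trees", min = 1)
  sub <- subset_cohort(abundance, samples, cohort)
  m <- abundance_to_matrix(sub)
  if (!all(peptide_ids %in% colnames(m))) {
    abort_usage("all panel peptides must be columns of the training matrix.")
  }
  lab <- outcome_factor(samples$outcome[match(rownames(m), samples$sample_id)])
  if (anyNA(lab) || nlevels(droplevels(lab)) < 2) {
    abort_usage("training needs both outcome classes with labels on every sample.")
  }
  if (min(table(lab)) < 2) abort_usage("need at least 2 samples per class.")
  x <- as.data.frame(m[, peptide_ids, drop = FALSE])
  names(x) <- make.names(peptide_ids)
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = lab, ntree = n_trees)
  structure(
    list(forest = forest, peptide_ids = peptide_ids, n_trees = n_trees,
         seed = seed, cutoff = 0),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("<panel_model> %d peptides, %d trees, cutoff %.3g\n",
              length(x$peptide_ids), x$n_trees, x$cutoff))
  invisible(x)
}

#' Tidy a panel model
#'
#' @param x a `panel_model`.
#' @param ... unused.
#' @return per-peptide variable importance (mean decrease in Gini).
#' @method tidy panel_model
#' @export
tidy.panel_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(
    catalog_id = x$peptide_ids,
    importance = unname(imp[, "MeanDecreaseGini"])
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @method glance panel_model
#' @export
glance.panel_model <- function(x, ...) {
  tibble::tibble(
    n_peptides = length(x$peptide_ids),
    n_trees = x$n_trees,
    oob_error = unname(x$forest$err.rate[x$n_trees, "OOB"]),
    cutoff = x$cutoff,
    seed = x$seed
  )
}

#' Score samples with a panel model
#'
#' The score of a sample is the fraction of trees voting ESRD minus the
#' fraction voting noESRD, hence lies in \[-1, 1\] with 0 as the natural
#' decision threshold; a sample is classified ESRD iff score > cutoff.
#' Panel peptides missing from the matrix are imputed as 0 (not detected)
#' with a warning.
#'
#' @param model a `panel_model`.
#' @param abundance abundance tibble (any cohort).
#' @param cutoff decision threshold; defaults to the model's.
#' @return tibble: `sample_id`, `score`, `predicted` (`ESRD`/`noESRD`).
#' @export
panel_score <- function(model, abundance, cutoff = model$cutoff) {
  m <- abundance_to_matrix(abundance)
  if (!nrow(m)) abort_usage("no samples to score.")
  missing <- setdiff(model$peptide_ids, colnames(m))
  if (length(missing)) {
    warn(sprintf("%d panel peptide(s) absent from the matrix; imputing 0.",
                 length(missing)))
    add <- matrix(0, nrow(m), length(missing),
                  dimnames = list(rownames(m), missing))
    m <- cbind(m, add)
  }
  x <- as.data.frame(m[, model$peptide_ids, drop = FALSE])
  names(x) <- make.names(model$peptide_ids)
  votes <- predict(model$forest, newdata = x, type = "vote", norm.votes = TRUE)
  score <- votes[, "ESRD"] - votes[, "noESRD"]
  tibble::tibble(
    sample_id = rownames(m),
    score = unname(score),
    predicted = ifelse(score > cutoff, "ESRD", "noESRD")
  )
}

#' Youden-optimal score cutoff
#'
#' Scans the midpoints of adjacent sorted unique scores and returns the
#' cutoff maximising Youden's J = sensitivity + specificity - 1 under the
#' rule "classify ESRD iff score > cutoff". Ties in J are broken toward the
#' candidate nearest 0 (the score scale's natural threshold).
#'
#' @param scores numeric scores.
#' @param labels outcome labels (`ESRD`/`noESRD`), both classes present.
#' @return the optimal cutoff (0 when every cutoff is equivalent).
#' @export
optimize_cutoff <- function(scores, labels) {
  lab <- outcome_factor(labels)
  if (length(scores) != length(lab)) abort_usage("scores and labels differ in length.")
  if (nlevels(droplevels(lab)) < 2) abort_usage("both outcome classes are required.")
  u <- sort(unique(scores))
  if (length(u) < 2) return(0)
  cand <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(cand, function(ct) {
    sens <- mean(scores[lab == "ESRD"] > ct)
    spec <- mean(scores[lab == "noESRD"] <= ct)
    sens + spec - 1
  }, numeric(1))
  best <- which(j == max(j))
  if (max(j) <= 0) return(0)
  cand[best][which.min(abs(cand[best]))]
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from beta quantiles:
#' lower = `qbeta(a/2, s, n - s + 1)` (0 when s = 0) and
#' upper = `qbeta(1 - a/2, s + 1, n - s)` (1 when s = n).
#'
#' @param successes,trials counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param conf confidence level (default 0.95).
#' @return one-row tibble: `estimate`, `lower`, `upper` (fractions).
#' @examples
#' clopper_pearson(8, 8)   # lower bound 0.631 -> printed as 63%
#' clopper_pearson(7, 8)   # lower bound 0.473 -> printed as 47%
#' @export
clopper_pearson <- function(successes, trials, conf = 0.95) {
  s <- check_scalar_count(successes, "successes")
  n <- check_scalar_count(trials, "trials", min = 1)
  if (s > n) abort_usage("`successes` cannot exceed `trials`.")
  if (conf <= 0 || conf >= 1) abort_usage("`conf` must lie in (0, 1).")
  a <- 1 - conf
  lower <- if (s == 0) 0 else qbeta(a / 2, s, n - s + 1)
  upper <- if (s == n) 1 else qbeta(1 - a / 2, s + 1, n - s)
  tibble::tibble(estimate = s / n, lower = lower, upper = upper)
}

#' AUC with DeLong confidence interval and null test
#'
#' The area under the ROC curve equals the Mann-Whitney probability
#' `P(score_case > score_control)` with ties counted 1/2. The standard error
#' comes from the DeLong U-statistic variance (placement values); the CI is
#' asymptotic normal clipped to \[0, 1\] and the p-value tests AUC = 0.5
#' (no discrimination), two-sided.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels outcome labels (`ESRD` = case, `noESRD` = control).
#' @param conf confidence level.
#' @return one-row tibble: `auc`, `lower`, `upper`, `se`, `p_vs_0_5`,
#'   `n_cases`, `n_controls`.
#' @export
auc_with_ci <- function(scores, labels, conf = 0.95) {
  lab <- outcome_factor(labels)
  if (length(scores) != length(lab)) abort_usage("scores and labels differ in length.")
  if (anyNA(scores) || anyNA(lab)) abort_usage("scores and labels must be complete.")
  x <- scores[lab == "ESRD"]    # cases
  y <- scores[lab == "noESRD"]  # controls
  m <- length(x); n <- length(y)
  if (m < 1 || n < 1) abort_usage("both outcome classes are required.")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)  # placement of each case among controls
  v01 <- colMeans(psi)  # placement of each control among cases
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (se == 0) {
    p <- if (auc == 0.5) 1 else 0
    lower <- upper <- auc
  } else {
    p <- 2 * pnorm(-abs(auc - 0.5) / se)
    lower <- max(0, auc - z * se)
    upper <- min(1, auc + z * se)
  }
  tibble::tibble(auc = auc, lower = lower, upper = upper, se = se,
                 p_vs_0_5 = p, n_cases = m, n_controls = n)
}

#' Validate a panel model on an outcome-labelled cohort
#'
#' Scores the cohort, classifies at the model cutoff, and reports sensitivity
#' and specificity (with exact Clopper-Pearson 95% CIs, as percentages), the
#' confusion counts, and the AUC with DeLong CI and the test of AUC = 0.5.
#'
#' @param model a `panel_model`.
#' @param abundance abundance tibble.
#' @param samples sample table with `outcome` (and `cohort` if `cohort` set).
#' @param cohort cohort label to validate on (`NULL` = all labelled samples).
#' @param cutoff decision threshold; defaults to the model's.
#' @param conf confidence level for all intervals.
#' @return a `validation_report`; `tidy()` gives the metric table, `glance()`
#'   a one-row summary, `$scores` the per-sample scores.
#' @export
validate_panel <- function(model, abundance, samples, cohort = "validation",
                           cutoff = model$cutoff, conf = 0.95) {
  sub <- if (is.null(cohort)) abundance else subset_cohort(abundance, samples, cohort)
  if (!nrow(sub)) abort_usage("no samples to validate on.")
  sc <- panel_score(model, sub, cutoff = cutoff)
  truth <- outcome_factor(samples$outcome[match(sc$sample_id, samples$sample_id)])
  if (anyNA(truth)) abort_usage("every validation sample needs an outcome label.")
  sc$outcome <- as.character(truth)
  tp <- sum(truth == "ESRD" & sc$predicted == "ESRD")
  fn <- sum(truth == "ESRD" & sc$predicted == "noESRD")
  tn <- sum(truth == "noESRD" & sc$predicted == "noESRD")
  fp <- sum(truth == "noESRD" & sc$predicted == "ESRD")
  if (tp + fn == 0 || tn + fp == 0) abort_usage("both outcome classes are required.")
  sens_ci <- clopper_pearson(tp, tp + fn, conf)
  spec_ci <- clopper_pearson(tn, tn + fp, conf)
  auc <- auc_with_ci(sc$score, truth, conf)
  structure(
    list(
      scores = sc,
      cutoff = cutoff,
      conf = conf,
      confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
      sensitivity_pct = 100 * sens_ci$estimate,
      sens_ci_pct = 100 * c(sens_ci$lower, sens_ci$upper),
      specificity_pct = 100 * spec_ci$estimate,
      spec_ci_pct = 100 * c(spec_ci$lower, spec_ci$upper),
      auc = auc$auc,
      auc_ci = c(auc$lower, auc$upper),
      auc_p_vs_0_5 = auc$p_vs_0_5
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  sensitivity %.1f%% [%d-%d], specificity %.1f%% [%d-%d]\n",
              x$sensitivity_pct,
              round_half_up(x$sens_ci_pct[1]), round_half_up(x$sens_ci_pct[2]),
              x$specificity_pct,
              round_half_up(x$spec_ci_pct[1]), round_half_up(x$spec_ci_pct[2])))
  cat(sprintf("  AUC %.2f [%.2f-%.2f], p(AUC = 0.5) = %.3g\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$auc_p_vs_0_5))
  cat(sprintf("  confusion: TP %d, FN %d, TN %d, FP %d (cutoff %.3g)\n",
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"], x$cutoff))
  invisible(x)
}

#' Tidy a validation report
#'
#' @param x a `validation_report`.
#' @param ... unused.
#' @return tibble with one row per metric (`sensitivity`, `specificity`,
#'   `auc`): `estimate`, `lower`, `upper` (percent for the first two).
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity_pct", "specificity_pct", "auc"),
    estimate = c(x$sensitivity_pct, x$specificity_pct, x$auc),
    lower = c(x$sens_ci_pct[1], x$spec_ci_pct[1], x$auc_ci[1]),
    upper = c(x$sens_ci_pct[2], x$spec_ci_pct[2], x$auc_ci[2])
  )
}

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    sensitivity_pct = x$sensitivity_pct,
    specificity_pct = x$specificity_pct,
    auc = x$auc,
    auc_p_vs_0_5 = x$auc_p_vs_0_5,
    tp = unname(x$confusion["TP"]), fn = unname(x$confusion["FN"]),
    tn = unname(x$confusion["TN"]), fp = unname(x$confusion["FP"]),
    cutoff = x$cutoff
  )
}

#' Correlate two classifiers' scores
#'
#' Spearman correlation (two-sided) between paired per-sample scores of two
#' classifiers, e.g. an AF panel versus an externally produced FU panel.
#'
#' @param scores_a,scores_b numeric vectors over the same samples (>= 3).
#' @return one-row tibble: `rho`, `p_value`, `n`.
#' @export
compare_classifiers <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    abort_usage("score vectors must cover the same samples.")
  }
  if (length(scores_a) < 3) abort_usage("need at least 3 paired scores.")
  res <- spearman_safe(scores_a, scores_b)
  tibble::tibble(rho = res$rho, p_value = res$p, n = length(scores_a))
}

#' Schwartz pediatric eGFR
#'
#' Bedside Schwartz estimate of the glomerular filtration rate,
#' `eGFR = k * height / creatinine` (ml/min/1.73 m^2), with the default
#' k = 0.413. The companion helper [outcome_from_egfr()] labels a child
#' noESRD iff eGFR is strictly above 15 ml/min.
#'
#' @param height_cm height in cm (> 0).
#' @param serum_creatinine_mg_dl serum creatinine in mg/dL (> 0).
#' @param k Schwartz constant.
#' @return numeric eGFR, vectorised.
#' @export
schwartz_egfr <- function(height_cm, serum_creatinine_mg_dl, k = 0.413) {
  if (any(height_cm <= 0) || any(serum_creatinine_mg_dl <= 0)) {
    abort_usage("height and creatinine must be positive.")
  }
  k * height_cm / serum_creatinine_mg_dl
}

#' @rdname schwartz_egfr
#' @param egfr eGFR in ml/min/1.73 m^2.
#' @export
outcome_from_egfr <- function(egfr) {
  ifelse(egfr > 15, "noESRD", "ESRD")
}
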