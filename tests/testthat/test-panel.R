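puv_fixture <- function(seed = 42, effect = 8, detection = 1) {
  cfg <- simulation_config(
    n_peptides_shared = 80, n_peptides_af_only = 10, n_peptides_fu_only = 10,
    n_af_samples = 40, n_fu_samples = 20, n_paired = 16,
    corr_subset_size = 25, n_outcome_peptides = 5,
    outcome_effect_size = effect, detection_prob = detection, seed = seed
  )
  generate_puv_cohort(cfg, 6, 8, 8, 8)
}

test_that("Wilcoxon selection recovers strongly shifted peptides at the 6+8 design", {
  recovered <- 0; n_rep <- 10
  for (seed in 1:n_rep) {
    co <- puv_fixture(seed = 500 + seed)
    flagged <- co$truth$catalog_id[co$truth$outcome_associated]
    cand <- select_candidates(co$af, co$samples,
                              co$truth$catalog_id[co$truth$origin_class == "shared-correlated"])
    recovered <- recovered + mean(flagged %in% cand$catalog_id[cand$selected])
  }
  expect_gte(recovered / n_rep, 0.95)
})

test_that("selection warns and returns empty for candidates absent from the matrix", {
  co <- puv_fixture()
  expect_warning(
    out <- select_candidates(co$af, co$samples, c("nope1", "nope2")),
    "none of the candidate"
  )
  expect_equal(nrow(out), 0)
})

test_that("training is deterministic in the seed and scores stay in [-1, 1]", {
  co <- puv_fixture()
  peps <- co$truth$catalog_id[co$truth$outcome_associated]
  m1 <- train_classifier(co$af, co$samples, peps, n_trees = 500, seed = 7)
  m2 <- train_classifier(co$af, co$samples, peps, n_trees = 500, seed = 7)
  s1 <- panel_score(m1, co$af)
  s2 <- panel_score(m2, co$af)
  expect_identical(s1$score, s2$score)
  expect_true(all(s1$score >= -1 & s1$score <= 1))
  # classification flips exactly at the cutoff
  expect_identical(s1$predicted, ifelse(s1$score > m1$cutoff, "ESRD", "noESRD"))
  # a large planted effect memorises the training set
  disc <- co$samples$sample_id[!is.na(co$samples$cohort) &
                                 co$samples$cohort == "discovery" &
                                 co$samples$fluid == "AF"]
  tr <- s1[s1$sample_id %in% disc, ]
  lab <- co$samples$outcome[match(tr$sample_id, co$samples$sample_id)]
  expect_gt(min(tr$score[lab == "ESRD"]), max(tr$score[lab == "noESRD"]))
})

test_that("single-class training data is a usage error", {
  co <- puv_fixture()
  samples <- co$samples
  samples$outcome[!is.na(samples$outcome) & samples$outcome == "ESRD"] <- "noESRD"
  expect_error(
    train_classifier(co$af, samples, co$truth$catalog_id[co$truth$outcome_associated]),
    class = "fetopep_usage_error"
  )
})

test_that("cutoff optimisation maximises Youden's J with ties broken toward 0", {
  expect_equal(optimize_cutoff(c(-0.8, -0.6, 0.4, 0.9),
                               c("noESRD", "noESRD", "ESRD", "ESRD")), -0.1)
  # identical distributions: no cutoff discriminates, fall back to 0
  expect_equal(optimize_cutoff(c(1, 2, 1, 2), c("ESRD", "ESRD", "noESRD", "noESRD")), 0)
  # random scores: achieved J equals an exhaustive threshold sweep
  for (seed in 1:6) {
    set.seed(seed)
    sc <- round(rnorm(14), 2)
    lab <- sample(c("ESRD", "noESRD"), 14, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(lab)) < 2) next
    ct <- optimize_cutoff(sc, lab)
    j_at <- function(c) {
      mean(sc[lab == "ESRD"] > c) + mean(sc[lab == "noESRD"] <= c) - 1
    }
    sweep_best <- max(vapply(c(sc - 1e-9, sc + 1e-9), j_at, numeric(1)), 0)
    expect_equal(j_at(ct), sweep_best, tolerance = 1e-12)
  }
})

test_that("Clopper-Pearson intervals reproduce the printed validation CIs", {
  sens <- clopper_pearson(8, 8)
  expect_equal(round(100 * sens$lower), 63)
  expect_equal(sens$upper, 1)
  spec <- clopper_pearson(7, 8)
  expect_equal(round(100 * spec$lower), 47)
  expect_equal(round(100 * spec$upper), 100)
  expect_equal(spec$estimate, 0.875)
  # closed form for zero successes: upper = 1 - (alpha/2)^(1/n)
  z <- clopper_pearson(0, 1)
  expect_equal(z$lower, 0)
  expect_equal(z$upper, 1 - 0.025, tolerance = 1e-12)
})

test_that("Clopper-Pearson matches the tail-bisection oracle and shrinks with n", {
  for (n in c(1, 5, 8, 20)) {
    for (s in unique(c(0, 1, floor(n / 2), n))) {
      got <- clopper_pearson(s, n)
      want <- oracle_cp(s, n)
      expect_equal(got$lower, unname(want["lower"]), tolerance = 1e-9)
      expect_equal(got$upper, unname(want["upper"]), tolerance = 1e-9)
      expect_gte(s / n, got$lower)
      expect_lte(s / n, got$upper)
    }
  }
  widths <- vapply(c(8, 16, 32, 64), function(n) {
    ci <- clopper_pearson(round(0.75 * n), n)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(clopper_pearson(9, 8), class = "fetopep_usage_error")
})

test_that("AUC equals exhaustive pair counting and handles separation", {
  perf <- auc_with_ci(c(-1, -0.5, 0.5, 1), c("noESRD", "noESRD", "ESRD", "ESRD"))
  expect_equal(perf$auc, 1)
  expect_lt(perf$p_vs_0_5, 1)
  for (seed in 1:8) {
    set.seed(seed)
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    sc <- c(rnorm(n1), rnorm(n2))
    if (seed %% 2 == 0) sc <- round(sc) # induce ties
    lab <- c(rep("ESRD", n1), rep("noESRD", n2))
    got <- auc_with_ci(sc, lab)
    expect_equal(got$auc, oracle_auc(sc, lab), tolerance = 1e-12)
    expect_true(got$lower <= got$auc && got$auc <= got$upper)
  }
})

test_that("DeLong inference agrees with the pROC reference implementation", {
  set.seed(11)
  sc <- c(rnorm(12, 1), rnorm(10))
  lab <- c(rep("ESRD", 12), rep("noESRD", 10))
  got <- auc_with_ci(sc, lab)
  roc <- pROC::roc(response = factor(lab, c("noESRD", "ESRD")), predictor = sc,
                   quiet = TRUE, direction = "<")
  ci <- pROC::ci.auc(roc, method = "delong")
  expect_equal(got$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
  expect_equal(got$lower, ci[1], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(got$upper, ci[3], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("validation reports are internally consistent", {
  co <- puv_fixture(seed = 77)
  scr <- paired_origin_screen(co$af, co$fu, co$samples)
  cand <- select_candidates(co$af, co$samples, scr$catalog_id[scr$selected])
  model <- train_classifier(co$af, co$samples, cand$catalog_id[cand$selected],
                            seed = 5)
  rep <- validate_panel(model, co$af, co$samples)
  cm <- rep$confusion
  expect_equal(rep$sensitivity_pct, 100 * cm["TP"] / (cm["TP"] + cm["FN"]),
               ignore_attr = TRUE)
  expect_equal(rep$specificity_pct, 100 * cm["TN"] / (cm["TN"] + cm["FP"]),
               ignore_attr = TRUE)
  expect_true(rep$sens_ci_pct[1] <= rep$sensitivity_pct &&
                rep$sensitivity_pct <= rep$sens_ci_pct[2])
  expect_true(rep$spec_ci_pct[1] <= rep$specificity_pct &&
                rep$specificity_pct <= rep$spec_ci_pct[2])
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  td <- tidy(rep)
  expect_equal(nrow(td), 3)
})

test_that("no-signal data yields chance-level validation AUC", {
  aucs <- vapply(1:5, function(seed) {
    co <- puv_fixture(seed = 900 + seed, effect = 1)
    peps <- co$truth$catalog_id[co$truth$outcome_associated]
    model <- train_classifier(co$af, co$samples, peps, n_trees = 300, seed = 1)
    validate_panel(model, co$af, co$samples)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})

test_that("classifier score correlation behaves like a paired Spearman", {
  s <- c(0.2, -0.5, 0.9, 0.1, -0.8)
  expect_equal(compare_classifiers(s, s)$rho, 1)
  expect_equal(compare_classifiers(s, -s)$rho, -1)
  set.seed(3)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(compare_classifiers(a, b)$rho, oracle_spearman(a, b),
               tolerance = 1e-12)
  expect_error(compare_classifiers(1:4, 1:5), class = "fetopep_usage_error")
})

test_that("Schwartz eGFR arithmetic and the strict 15 ml/min rule hold", {
  expect_equal(schwartz_egfr(100, 1), 41.3)
  expect_equal(schwartz_egfr(100, 2), schwartz_egfr(100, 1) / 2)
  expect_equal(outcome_from_egfr(15), "ESRD") # strictly greater than 15
  expect_equal(outcome_from_egfr(15.01), "noESRD")
  expect_error(schwartz_egfr(-1, 1), class = "fetopep_usage_error")
})
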