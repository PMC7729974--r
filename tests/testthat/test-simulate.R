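test_that("the same seed and config reproduce the cohort bit-identically", {
  a <- generate_cohort(small_sim_config(seed = 7))
  b <- generate_cohort(small_sim_config(seed = 7))
  expect_identical(a$af, b$af)
  expect_identical(a$fu, b$fu)
  expect_identical(a$catalog, b$catalog)
  c <- generate_cohort(small_sim_config(seed = 8))
  expect_false(identical(a$af, c$af))
})

test_that("with full detection, fluid-specific peptides never cross fluids and the Venn equals the configured counts", {
  cfg <- small_sim_config(detection_prob = 1, seed = 3)
  co <- generate_cohort(cfg)
  af_ids <- setdiff(names(co$af), "sample_id")
  fu_ids <- setdiff(names(co$fu), "sample_id")
  truth <- co$truth
  expect_length(intersect(truth$catalog_id[truth$origin_class == "AF-only"], fu_ids), 0)
  expect_length(intersect(truth$catalog_id[truth$origin_class == "FU-only"], af_ids), 0)
  v <- venn_partition(co$af, co$fu)
  expect_equal(length(v$af_only_ids), cfg$n_peptides_af_only)
  expect_equal(length(v$fu_only_ids), cfg$n_peptides_fu_only)
  expect_equal(v$n_common, cfg$n_peptides_shared)
})

test_that("planted pair correlation is calibrated to the target strength", {
  cfg <- small_sim_config(
    n_peptides_shared = 120, corr_subset_size = 120, n_af_samples = 50,
    n_fu_samples = 50, n_paired = 50, detection_prob = 1,
    corr_strength = 0.7, ga_trend = 1, seed = 21
  )
  co <- generate_cohort(cfg)
  af_m <- abundance_to_matrix(co$af)
  fu_m <- abundance_to_matrix(co$fu)
  af_s <- co$samples[co$samples$fluid == "AF", ]
  fu_s <- co$samples[co$samples$fluid == "FU", ]
  pats <- intersect(af_s$patient_id, fu_s$patient_id)
  a <- af_s$sample_id[match(pats, af_s$patient_id)]
  f <- fu_s$sample_id[match(pats, fu_s$patient_id)]
  planted <- co$truth$catalog_id[co$truth$origin_class == "shared-correlated"]
  rhos <- vapply(planted, function(p) {
    stats::cor(af_m[a, p], fu_m[f, p], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.7), 0.1)
})

test_that("a perfect planted link (corr_strength = 1) yields exact rank agreement", {
  cfg <- small_sim_config(detection_prob = 1, corr_strength = 1,
                          n_paired = 12, seed = 4)
  co <- generate_cohort(cfg)
  screen <- paired_origin_screen(co$af, co$fu, co$samples)
  planted <- co$truth$catalog_id[co$truth$origin_class == "shared-correlated"]
  hit <- screen[screen$catalog_id %in% planted, ]
  expect_true(all(hit$rho == 1))
  expect_true(all(hit$selected))
})

test_that("mean abundance declines across gestational bins under a sub-unit trend", {
  cfg <- small_sim_config(
    n_peptides_shared = 150, n_af_samples = 240, n_paired = 0,
    detection_prob = 1, ga_trend = 0.8, seed = 17
  )
  co <- generate_cohort(cfg)
  af_s <- co$samples[co$samples$fluid == "AF", ]
  tr <- trend_across_bins(co$af, af_s)
  means <- tidy(tr)$mean
  expect_true(all(diff(means) < 0))
  expect_lt(glance(tr)$p_value, 0.001)
})

test_that("impossible configurations are rejected", {
  expect_error(small_sim_config(n_paired = 30), class = "fetopep_config_error")
  expect_error(small_sim_config(corr_subset_size = 100), class = "fetopep_config_error")
  expect_error(small_sim_config(detection_prob = 0), class = "fetopep_config_error")
  expect_error(small_sim_config(corr_strength = 1.2), class = "fetopep_config_error")
})

test_that("the PUV design labels discovery and validation arms as configured", {
  cfg <- small_sim_config(n_af_samples = 40, n_fu_samples = 20, n_paired = 16,
                          n_outcome_peptides = 5, corr_subset_size = 10, seed = 9)
  co <- generate_puv_cohort(cfg, 6, 8, 8, 8)
  s <- co$samples
  af <- s[s$fluid == "AF", ]
  expect_equal(sum(af$cohort == "discovery" & af$outcome == "ESRD", na.rm = TRUE), 6)
  expect_equal(sum(af$cohort == "discovery" & af$outcome == "noESRD", na.rm = TRUE), 8)
  expect_equal(sum(af$cohort == "validation" & af$outcome == "ESRD", na.rm = TRUE), 8)
  expect_equal(sum(af$cohort == "validation" & af$outcome == "noESRD", na.rm = TRUE), 8)
  # validation fetuses have matched FU samples carrying the same labels
  val_pat <- af$patient_id[!is.na(af$cohort) & af$cohort == "validation"]
  fu <- s[s$fluid == "FU" & s$patient_id %in% val_pat, ]
  expect_equal(nrow(fu), 16)
  expect_true(all(fu$cohort == "validation"))
})

test_that("outcome-flagged peptides carry the planted fold change", {
  cfg <- small_sim_config(n_af_samples = 60, n_fu_samples = 20, n_paired = 16,
                          n_outcome_peptides = 5, corr_subset_size = 10,
                          detection_prob = 1, outcome_effect_size = 8, seed = 13)
  co <- generate_puv_cohort(cfg, 10, 10, 8, 8)
  af_m <- abundance_to_matrix(co$af)
  s <- co$samples
  esrd <- s$sample_id[s$fluid == "AF" & !is.na(s$outcome) & s$outcome == "ESRD"]
  ctrl <- s$sample_id[s$fluid == "AF" & !is.na(s$outcome) & s$outcome == "noESRD"]
  flagged <- co$truth$catalog_id[co$truth$outcome_associated]
  unflagged <- setdiff(co$truth$catalog_id[co$truth$origin_class == "shared-uncorrelated"],
                       flagged)
  fc_flag <- mean(log(colMeans(af_m[esrd, flagged])) - log(colMeans(af_m[ctrl, flagged])))
  fc_null <- mean(log(colMeans(af_m[esrd, unflagged])) - log(colMeans(af_m[ctrl, unflagged])))
  expect_gt(fc_flag, log(4))
  expect_lt(abs(fc_null), log(2))
})
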