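test_that("venn partition equals brute-force set algebra on random ID sets", {
  for (seed in 1:8) {
    set.seed(seed)
    universe <- paste0("p", 1:200)
    af <- sample(universe, sample(0:150, 1))
    fu <- sample(universe, sample(1:150, 1))
    if (!length(af)) af <- character(0)
    v <- suppressWarnings(venn_partition(af, fu))
    o <- oracle_venn(af, fu)
    expect_setequal(v$af_only_ids, o$af_only)
    expect_setequal(v$common_ids, o$common)
    expect_setequal(v$fu_only_ids, o$fu_only)
    # conservation
    expect_equal(length(v$af_only_ids) + v$n_common, v$n_af_total)
    expect_equal(length(v$fu_only_ids) + v$n_common, v$n_fu_total)
  }
})

test_that("identical sets give a pure overlap", {
  v <- venn_partition(c("a", "b"), c("a", "b"))
  expect_length(v$af_only_ids, 0)
  expect_length(v$fu_only_ids, 0)
  expect_equal(v$pct_of_af_number, 100)
})

test_that("abundance share uses mean AF abundance and is scale invariant", {
  af <- tibble::tibble(sample_id = c("s1", "s2"),
                       p1 = c(4, 0), p2 = c(2, 2), p3 = c(1, 1))
  # means: p1 = 2, p2 = 2, p3 = 1; common = p2, p3 -> 3/5 of abundance
  v <- venn_partition(af, c("p2", "p3"))
  expect_equal(v$pct_of_af_abundance, 60)
  af10 <- dplyr::mutate(af, dplyr::across(-sample_id, ~ .x * 10))
  v10 <- venn_partition(af10, c("p2", "p3"))
  expect_equal(v10$pct_of_af_abundance, v$pct_of_af_abundance)
  expect_equal(tidy(v)$n_common, 2)
})

test_that("disjoint non-empty ID spaces warn rather than fail", {
  expect_warning(venn_partition(c("a", "b"), c("x", "y")), "ID space")
})

test_that("per-bin overlap omits bins lacking a fluid and restricts correctly", {
  fx <- tiny_cohort()
  bb <- overlap_by_bin(fx$af, fx$fu, fx$samples, min_freq = 0)
  # every sampled bin has 1 AF + 1 FU sample and all peptides detected
  expect_true(all(bb$n_common == 8))
  # remove the FU sample of one bin: that bin disappears from the series
  fu_sub <- fx$fu[fx$fu$sample_id != "U1", ]
  bb2 <- overlap_by_bin(fx$af, fu_sub, fx$samples, min_freq = 0)
  expect_equal(nrow(bb2), nrow(bb) - 1)
  expect_false("11-14" %in% bb2$ga_bin)
  # the union of per-bin common sets is contained in the global common set
  co <- generate_cohort(small_sim_config(seed = 33))
  af_s <- co$samples[co$samples$fluid == "AF", ]
  fu_s <- co$samples[co$samples$fluid == "FU", ]
  v <- venn_partition(frequency_filter(co$af, af_s),
                      frequency_filter(co$fu, fu_s))
  per_bin_common <- character(0)
  freq_af <- detection_frequency(co$af, af_s)
  freq_fu <- detection_frequency(co$fu, fu_s)
  for (b in intersect(freq_af$ga_bin, freq_fu$ga_bin)) {
    set_af <- freq_af$catalog_id[freq_af$ga_bin == b & freq_af$frequency >= 0.5]
    set_fu <- freq_fu$catalog_id[freq_fu$ga_bin == b & freq_fu$frequency >= 0.5]
    per_bin_common <- union(per_bin_common, intersect(set_af, set_fu))
  }
  expect_true(all(per_bin_common %in% v$common_ids))
})

test_that("mass summaries use the closed 800-5000 Da window and match recomputation", {
  cat2 <- tibble::tibble(catalog_id = c("a", "b"), mass_da = c(800, 5000))
  expect_equal(mass_summary(cat2)$fraction_in_800_5000, 1)
  cat3 <- tibble::tibble(catalog_id = c("a", "b"), mass_da = c(700, 900))
  expect_equal(mass_summary(cat3)$fraction_in_800_5000, 0.5)
  set.seed(2)
  masses <- stats::rlnorm(1000, log(2500), 0.5)
  cat4 <- tibble::tibble(catalog_id = paste0("p", 1:1000), mass_da = masses)
  ms <- mass_summary(cat4)
  expect_equal(ms$mean_da, mean(masses))
  expect_equal(ms$median_da, stats::median(masses))
  expect_equal(ms$sem_da, stats::sd(masses) / sqrt(1000))
  expect_equal(ms$fraction_in_800_5000, mean(masses >= 800 & masses <= 5000))
  expect_error(mass_summary(cat4, character(0)), class = "fetopep_usage_error")
})

test_that("protein origin shares are computed over sequenced peptides only", {
  cat <- tibble::tibble(
    catalog_id = paste0("p", 1:6),
    mass_da = rep(1000, 6),
    protein_name = c(rep("Collagen alpha-1(I) chain", 3),
                     "Fibrinogen alpha chain", NA, NA)
  )
  tab <- protein_origin_table(cat)
  expect_equal(tab$pct_of_sequenced[tab$protein_name == "Collagen alpha-1(I) chain"], 75)
  expect_equal(attr(tab, "n_unsequenced"), 2)
  all_unseq <- protein_origin_table(dplyr::mutate(cat, protein_name = NA))
  expect_equal(nrow(all_unseq), 0)
  expect_equal(attr(all_unseq, "n_unsequenced"), 6)
})

test_that("the Mann-Whitney wrapper matches exact enumeration and edge cases", {
  res <- compare_groups(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, oracle_mw_p(c(1, 2, 3), c(10, 20, 30)))
  same <- compare_groups(1:6, 1:6)
  expect_gt(same$p_value, 0.9)
  shift <- compare_groups(rnorm(30), rnorm(30) + 5)
  expect_lt(shift$p_value, 0.001)
  expect_error(compare_groups(numeric(0), 1:3), class = "fetopep_usage_error")
  # random small instances against the enumeration oracle (tie-free)
  for (seed in 1:5) {
    set.seed(seed)
    a <- sample(100, 5); b <- sample(200:300, 4)
    expect_equal(compare_groups(a, b)$p_value, oracle_mw_p(a, b))
  }
})

test_that("bin trends flag flat, separated and declining profiles correctly", {
  samples <- assign_ga_bins(tibble::tibble(
    sample_id = paste0("s", 1:8), fluid = "AF",
    gestational_age_wa = rep(c(12, 30), each = 4)
  ))
  flat <- tibble::tibble(sample_id = samples$sample_id, p1 = rep(2, 8))
  tr <- trend_across_bins(flat, samples)
  expect_equal(glance(tr)$p_value, 1)
  sep <- tibble::tibble(sample_id = samples$sample_id, p1 = rep(c(1, 3), each = 4))
  tr2 <- trend_across_bins(sep, samples)
  expect_equal(glance(tr2)$p_value, 0)
  one_bin <- samples[samples$ga_bin == "11-14", ]
  expect_error(trend_across_bins(flat[1:4, ], one_bin), class = "fetopep_usage_error")
})
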