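# Fetal-urine origin attribution for amniotic-fluid peptides.
#
# Two complementary views: a global Spearman correlation between per-peptide
# average abundances in the two fluids over the common set, and a per-peptide
# Spearman screen across paired AF/FU samples from the same fetus. A peptide
# is called "FU origin" when its paired abundances are significantly
# positively correlated (rho > 0 and two-sided p < alpha).

spearman_safe <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, zero_variance = TRUE))
  }
  ht <- suppressWarnings(
    cor.test(x, y, method = "spearman", alternative = "two.sided", exact = FALSE)
  )
  list(rho = unname(ht$estimate), p = ht$p.value, zero_variance = FALSE)
}

#' Global correlation of average abundances between fluids
#'
#' Spearman correlation between per-peptide mean AF abundance and per-peptide
#' mean FU abundance over a peptide set (typically the common/overlap set, or
#' a protein-restricted subset of it). Ties are mid-ranked.
#'
#' @param af,fu abundance tibbles sharing a catalog ID space.
#' @param ids peptide IDs to use; must resolve in both matrices, at least 3.
#' @return one-row tibble: `rho`, `p_value`, `n_peptides`.
#' @export
average_abundance_correlation <- function(af, fu, ids) {
  ids <- unique(ids)
  if (length(ids) < 3) abort_usage("need at least 3 peptides for a correlation.")
  mu_af <- peptide_mean_abundance(af)
  mu_fu <- peptide_mean_abundance(fu)
  if (!all(ids %in% names(mu_af)) || !all(ids %in% names(mu_fu))) {
    abort_usage("some peptide IDs are absent from one of the matrices.")
  }
  res <- spearman_safe(mu_af[ids], mu_fu[ids])
  tibble::tibble(rho = res$rho, p_value = res$p, n_peptides = length(ids))
}

#' Paired-sample origin screen
#'
#' For each peptide of the common set, computes the Spearman correlation of
#' its abundance across paired AF/FU samples (one pair per fetus, matched via
#' `patient_id`; non-detect zeros enter as true zero abundances) and calls
#' the peptide FU-origin (`selected`) when rho > 0 and the two-sided p-value
#' is below `alpha`. No multiple-testing correction is applied by default,
#' matching a nominal-significance screen; set `adjust = "BH"` for
#' Benjamini-Hochberg control.
#'
#' @param af,fu abundance tibbles.
#' @param samples sample table with `fluid` and `patient_id`; patients with
#'   one AF and one FU sample form the pairs.
#' @param ids peptides to screen (default: IDs present in both matrices).
#' @param alpha significance level for selection.
#' @param min_detected_pairs minimum number of pairs in which the peptide is
#'   detected in both fluids; below it the peptide is never selected and is
#'   flagged (`low_detection`).
#' @param adjust `"none"` (default) or `"BH"`; selection then uses the
#'   adjusted p-value.
#' @return tibble sorted by p: `catalog_id`, `rho`, `p_value`, `n_pairs`,
#'   `n_detected_pairs`, `selected`, `zero_variance`, `low_detection`.
#' @export
paired_origin_screen <- function(af, fu, samples, ids = NULL, alpha = 0.05,
                                 min_detected_pairs = 3, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  af_m <- abundance_to_matrix(af)
  fu_m <- abundance_to_matrix(fu)
  if (!all(c("fluid", "patient_id") %in% names(samples))) {
    abort_usage("`samples` must carry `fluid` and `patient_id` for pairing.")
  }
  af_s <- samples[samples$fluid == "AF" & samples$sample_id %in% rownames(af_m), ]
  fu_s <- samples[samples$fluid == "FU" & samples$sample_id %in% rownames(fu_m), ]
  pats <- intersect(af_s$patient_id, fu_s$patient_id)
  pats <- pats[!is.na(pats)]
  if (length(pats) < 3) abort_usage("need at least 3 complete AF/FU pairs.")
  af_rows <- af_s$sample_id[match(pats, af_s$patient_id)]
  fu_rows <- fu_s$sample_id[match(pats, fu_s$patient_id)]
  ids <- ids %||% intersect(colnames(af_m), colnames(fu_m))
  missing <- setdiff(ids, intersect(colnames(af_m), colnames(fu_m)))
  if (length(missing)) {
    abort_usage(sprintf("peptide(s) absent from a matrix: %s",
                        paste(head(missing, 3), collapse = ", ")))
  }
  x_af <- af_m[af_rows, ids, drop = FALSE]
  x_fu <- fu_m[fu_rows, ids, drop = FALSE]
  res <- purrr::map(seq_along(ids), function(j) {
    a <- x_af[, j]; f <- x_fu[, j]
    s <- spearman_safe(a, f)
    tibble::tibble(
      catalog_id = ids[j],
      rho = s$rho,
      p_value = s$p,
      n_pairs = length(a),
      n_detected_pairs = sum(a > 0 & f > 0),
      zero_variance = s$zero_variance
    )
  })
  out <- dplyr::bind_rows(res)
  out$low_detection <- out$n_detected_pairs < min_detected_pairs
  p_sel <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$selected <- !out$zero_variance & !out$low_detection &
    !is.na(out$rho) & out$rho > 0 & p_sel < alpha
  dplyr::arrange(out, .data$p_value)
}
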