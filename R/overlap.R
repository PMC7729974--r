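# Two-fluid peptidome overlap: Venn partitions, per-bin overlap trajectories,
# mass summaries, protein-origin tabulations and the standard group tests.

fluid_peptide_set <- function(x) {
  if (is.character(x)) unique(x) else peptide_ids(x)
}

# mean abundance per peptide, zeros (non-detects) included, so sporadic
# peptides are diluted; this is the signal-share reading of "% of total
# abundance". detected_only = TRUE averages positive cells instead.
peptide_mean_abundance <- function(abundance, detected_only = FALSE) {
  m <- abundance_to_matrix(abundance)
  if (detected_only) {
    mu <- apply(m, 2, function(v) if (any(v > 0)) mean(v[v > 0]) else 0)
  } else {
    mu <- colMeans(m)
  }
  mu
}

#' Two-fluid Venn partition of peptide sets
#'
#' Splits the AF and FU peptide sets (a peptide belongs to a fluid's set iff
#' it survived that fluid's detection-frequency filter) into AF-only, common
#' and FU-only, with the common share expressed as a percentage of the AF
#' peptide number and, when abundance tibbles are supplied, of total AF
#' abundance (sum over common peptides of the mean AF abundance divided by
#' the sum over all AF peptides).
#'
#' @param af,fu either filtered abundance tibbles (samples by peptides) or
#'   plain character vectors of peptide IDs.
#' @param detected_only if `TRUE`, abundance shares average detected
#'   (positive) cells only instead of including zeros.
#' @return a `venn_partition` object; see [tidy.venn_partition()].
#' @examples
#' venn_partition(c("a", "b", "c"), c("b", "c", "d"))
#' @export
venn_partition <- function(af, fu, detected_only = FALSE) {
  af_set <- fluid_peptide_set(af)
  fu_set <- fluid_peptide_set(fu)
  common <- intersect(af_set, fu_set)
  if (!length(common) && length(af_set) && length(fu_set)) {
    warn("AF and FU peptide sets share no IDs; check that both use one catalog ID space.")
  }
  pct_abund <- NA_real_
  if (is.data.frame(af)) {
    mu <- peptide_mean_abundance(af, detected_only)
    tot <- sum(mu)
    pct_abund <- if (tot > 0) 100 * sum(mu[common]) / tot else NA_real_
  }
  structure(
    list(
      af_only_ids = setdiff(af_set, fu_set),
      common_ids = common,
      fu_only_ids = setdiff(fu_set, af_set),
      n_af_total = length(af_set),
      n_fu_total = length(fu_set),
      n_common = length(common),
      pct_of_af_number = if (length(af_set)) 100 * length(common) / length(af_set) else NA_real_,
      pct_of_af_abundance = pct_abund
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  cat(sprintf("  AF only: %d   common: %d   FU only: %d\n",
              length(x$af_only_ids), x$n_common, length(x$fu_only_ids)))
  cat(sprintf("  common = %s%% of AF peptide number",
              format(round_half_up(x$pct_of_af_number))))
  if (!is.na(x$pct_of_af_abundance)) {
    cat(sprintf(", %s%% of AF abundance", format(round_half_up(x$pct_of_af_abundance))))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a Venn partition
#'
#' @param x a `venn_partition`.
#' @param ... unused.
#' @return one-row tibble of counts and percentages (full precision; round at
#'   report time).
#' @method tidy venn_partition
#' @export
tidy.venn_partition <- function(x, ...) {
  tibble::tibble(
    n_af_only = length(x$af_only_ids),
    n_common = x$n_common,
    n_fu_only = length(x$fu_only_ids),
    n_af_total = x$n_af_total,
    n_fu_total = x$n_fu_total,
    pct_of_af_number = x$pct_of_af_number,
    pct_of_af_abundance = x$pct_of_af_abundance
  )
}

#' Per-bin overlap trajectory
#'
#' Recomputes presence per gestational-age bin (detection frequency >=
#' `min_freq` among that bin's samples of each fluid) and partitions the two
#' per-bin sets. Bins with no sample in either fluid are omitted rather than
#' reported as zero.
#'
#' @param af,fu abundance tibbles (unfiltered or filtered; presence is
#'   re-derived within each bin).
#' @param samples sample table covering both fluids with `ga_bin` assigned.
#' @param scheme bin scheme, see [ga_bin_scheme()].
#' @param min_freq per-bin detection-frequency threshold.
#' @return tibble, one row per retained bin, with per-bin counts and AF
#'   percentages (columns as in [tidy.venn_partition()] plus `ga_bin`).
#' @export
overlap_by_bin <- function(af, fu, samples, scheme = ga_bin_scheme(),
                           min_freq = 0.5) {
  if (!"ga_bin" %in% names(samples)) {
    abort_usage("`samples` must carry `ga_bin`; run assign_ga_bins() first.")
  }
  af_m <- abundance_to_matrix(af)
  fu_m <- abundance_to_matrix(fu)
  purrr::map_dfr(scheme$ga_bin, function(b) {
    af_ids <- samples$sample_id[samples$fluid == "AF" & samples$ga_bin == b]
    fu_ids <- samples$sample_id[samples$fluid == "FU" & samples$ga_bin == b]
    af_ids <- intersect(af_ids, rownames(af_m))
    fu_ids <- intersect(fu_ids, rownames(fu_m))
    if (!length(af_ids) || !length(fu_ids)) return(NULL)
    af_bin <- af_m[af_ids, , drop = FALSE]
    fu_bin <- fu_m[fu_ids, , drop = FALSE]
    af_set <- colnames(af_bin)[colMeans(af_bin > 0) >= min_freq & colSums(af_bin > 0) > 0]
    fu_set <- colnames(fu_bin)[colMeans(fu_bin > 0) >= min_freq & colSums(fu_bin > 0) > 0]
    part <- venn_partition(matrix_to_abundance(af_bin[, af_set, drop = FALSE]),
                           fu_set)
    dplyr::bind_cols(tibble::tibble(ga_bin = b), tidy(part))
  })
}

#' Mass distribution summary
#'
#' @param catalog peptide catalog with `catalog_id` and `mass_da`.
#' @param ids peptide IDs to summarise; default all.
#' @return one-row tibble: `n`, `mean_da`, `median_da`, `sem_da`,
#'   `fraction_in_800_5000` (closed interval \[800, 5000\] Da).
#' @export
mass_summary <- function(catalog, ids = catalog$catalog_id) {
  mass <- catalog$mass_da[match(ids, catalog$catalog_id)]
  if (!length(ids)) abort_usage("cannot summarise an empty peptide set.")
  if (anyNA(mass)) abort_usage("some peptide IDs do not resolve in the catalog.")
  tibble::tibble(
    n = length(mass),
    mean_da = mean(mass),
    median_da = median(mass),
    sem_da = if (length(mass) > 1) sd(mass) / sqrt(length(mass)) else NA_real_,
    fraction_in_800_5000 = mean(mass >= 800 & mass <= 5000)
  )
}

#' Parent-protein origin table
#'
#' Tabulates sequenced peptides by parent protein; shares are computed over
#' sequenced peptides only, with unsequenced peptides counted separately.
#' When an abundance tibble is given, per-protein abundance shares (of the
#' summed mean abundance of sequenced peptides) are added.
#'
#' @param catalog peptide catalog with optional `protein_name`.
#' @param ids peptide IDs to tabulate.
#' @param abundance optional abundance tibble for abundance shares.
#' @return tibble with `protein_name`, `n_peptides`, `pct_of_sequenced` and
#'   optionally `pct_of_abundance`; attribute `n_unsequenced` carries the
#'   count of peptides without a sequence annotation.
#' @export
protein_origin_table <- function(catalog, ids = catalog$catalog_id,
                                 abundance = NULL) {
  sub <- catalog[match(ids, catalog$catalog_id), ]
  has_prot <- "protein_name" %in% names(sub)
  annotated <- if (has_prot) !is.na(sub$protein_name) & sub$protein_name != "" else rep(FALSE, nrow(sub))
  n_unseq <- sum(!annotated)
  if (!any(annotated)) {
    out <- tibble::tibble(protein_name = character(), n_peptides = integer(),
                          pct_of_sequenced = numeric())
    attr(out, "n_unsequenced") <- n_unseq
    return(out)
  }
  seq_sub <- sub[annotated, ]
  out <- seq_sub |>
    dplyr::count(.data$protein_name, name = "n_peptides") |>
    dplyr::mutate(pct_of_sequenced = 100 * .data$n_peptides / sum(.data$n_peptides)) |>
    dplyr::arrange(dplyr::desc(.data$n_peptides))
  if (!is.null(abundance)) {
    mu <- peptide_mean_abundance(abundance)
    mu <- mu[intersect(seq_sub$catalog_id, names(mu))]
    by_prot <- tibble::tibble(
      catalog_id = names(mu),
      protein_name = seq_sub$protein_name[match(names(mu), seq_sub$catalog_id)],
      mu = unname(mu)
    ) |>
      dplyr::group_by(.data$protein_name) |>
      dplyr::summarise(abund = sum(.data$mu), .groups = "drop")
    out$pct_of_abundance <- 100 * by_prot$abund[match(out$protein_name, by_prot$protein_name)] /
      sum(by_prot$abund)
  }
  attr(out, "n_unsequenced") <- n_unseq
  out
}

#' Two-group comparison (Mann-Whitney)
#'
#' Thin wrapper over the two-sided Wilcoxon rank-sum (Mann-Whitney) test,
#' exact where base R permits (no ties, small n) and normal-approximate with
#' continuity correction otherwise; ties are mid-ranked.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param test currently only `"mann_whitney"`.
#' @return one-row tibble: `statistic` (U for group `a`), `p_value`, `n_a`,
#'   `n_b`, `method`.
#' @export
compare_groups <- function(a, b, test = c("mann_whitney")) {
  test <- match.arg(test)
  if (!length(a) || !length(b)) abort_usage("both groups must be non-empty.")
  ht <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_a = length(a),
    n_b = length(b),
    method = "Mann-Whitney"
  )
}

#' Abundance trend across gestational bins
#'
#' Per-sample mean abundance is summarised per gestational bin (mean and SEM)
#' and the across-bin effect tested by classical one-way ANOVA. If within-bin
#' variance is exactly zero while bin means differ, the p-value degenerates
#' to 0.
#'
#' @param abundance abundance tibble.
#' @param samples sample table with `ga_bin` assigned.
#' @param scheme bin scheme (orders the output).
#' @param value per-sample statistic: `"mean_abundance"` (mean signal over
#'   peptides, zeros included) or `"n_peptides"` (detected peptide count).
#' @return a `bin_trend` object; `tidy()` gives the per-bin table, `glance()`
#'   the ANOVA F and p.
#' @export
trend_across_bins <- function(abundance, samples, scheme = ga_bin_scheme(),
                              value = c("mean_abundance", "n_peptides")) {
  value <- match.arg(value)
  if (!"ga_bin" %in% names(samples)) {
    abort_usage("`samples` must carry `ga_bin`; run assign_ga_bins() first.")
  }
  m <- abundance_to_matrix(abundance)
  bins <- samples$ga_bin[match(rownames(m), samples$sample_id)]
  per_sample <- tibble::tibble(
    sample_id = rownames(m),
    ga_bin = factor(as.character(bins), levels = scheme$ga_bin),
    value = if (value == "mean_abundance") rowMeans(m) else rowSums(m > 0)
  )
  per_sample <- dplyr::filter(per_sample, !is.na(.data$ga_bin))
  used <- droplevels(per_sample$ga_bin)
  if (nlevels(used) < 2) abort_usage("need at least two non-empty bins for a trend.")
  by_bin <- per_sample |>
    dplyr::group_by(.data$ga_bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    )
  if (diff(range(per_sample$value)) == 0) {
    # constant response: no effect by construction
    return(structure(
      list(by_bin = by_bin, f_statistic = 0, p_value = 1, value = value),
      class = "bin_trend"
    ))
  }
  fit <- stats::aov(value ~ ga_bin, data = transform(per_sample, ga_bin = used))
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (is.na(f) || is.infinite(f)) {
    # zero residual variance with distinct means: perfect separation
    between <- tab[["Sum Sq"]][1]
    p <- if (between > 0) 0 else 1
    f <- if (between > 0) Inf else 0
  }
  structure(
    list(by_bin = by_bin, f_statistic = f, p_value = p, value = value),
    class = "bin_trend"
  )
}

#' @method tidy bin_trend
#' @export
tidy.bin_trend <- function(x, ...) x$by_bin

#' @method glance bin_trend
#' @export
glance.bin_trend <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, p_value = x$p_value,
                 value = x$value)
}

#' @export
print.bin_trend <- function(x, ...) {
  cat(sprintf("<bin_trend: %s>  one-way ANOVA F = %.3g, p = %.3g\n",
              x$value, x$f_statistic, x$p_value))
  print(x$by_bin)
  invisible(x)
}
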