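#' Per-bin detection frequency
#'
#' Share of samples within each gestational-age bin in which a peptide has a
#' positive signal. Bins with no samples are dropped.
#'
#' @param abundance samples-by-peptides wide tibble.
#' @param samples sample table with `sample_id` and `ga_bin` assigned
#'   (see [assign_ga_bins()]).
#' @return long tibble with `catalog_id`, `ga_bin`, `n_samples`, `n_detected`,
#'   `frequency`.
#' @export
detection_frequency <- function(abundance, samples) {
  if (!"ga_bin" %in% names(samples)) {
    abort_usage("`samples` must carry a `ga_bin` column; run assign_ga_bins() first.")
  }
  m <- abundance_to_matrix(abundance)
  bins <- samples$ga_bin[match(rownames(m), samples$sample_id)]
  if (anyNA(bins)) abort_data("abundance contains sample_id absent from `samples`.")
  purrr::map_dfr(levels(droplevels(bins)), function(b) {
    rows <- which(bins == b)
    tibble::tibble(
      catalog_id = colnames(m),
      ga_bin = b,
      n_samples = length(rows),
      n_detected = colSums(m[rows, , drop = FALSE] > 0),
      frequency = .data$n_detected / .data$n_samples
    )
  })
}

#' Detection-frequency filter
#'
#' Retains the peptides of one body fluid that are detected (signal > 0) in
#' at least `min_freq` of the samples of at least one gestational-age bin,
#' the standard inclusion rule for CE-MS peptidome studies (50% in at least
#' one gestational period). Bins without samples are ignored; the sample
#' axis is preserved.
#'
#' @param abundance samples-by-peptides wide tibble for a single fluid.
#' @param samples sample table covering those samples, with `fluid` and
#'   `ga_bin` columns; all rows matching the abundance samples must come from
#'   one fluid.
#' @param min_freq minimum detection frequency in `[0, 1]`; at `min_freq = 0`
#'   every peptide with at least one detection is retained.
#' @return the filtered abundance tibble (same samples, surviving peptides).
#' @export
frequency_filter <- function(abundance, samples, min_freq = 0.5) {
  if (!is.numeric(min_freq) || length(min_freq) != 1 || min_freq < 0 || min_freq > 1) {
    abort_usage("`min_freq` must be a single fraction in [0, 1].")
  }
  used <- samples[samples$sample_id %in% abundance$sample_id, ]
  if (dplyr::n_distinct(used$fluid) > 1) {
    abort_usage("frequency_filter() is defined per fluid; got samples from both AF and FU.")
  }
  freq <- detection_frequency(abundance, samples)
  keep <- freq |>
    dplyr::group_by(.data$catalog_id) |>
    dplyr::summarise(max_freq = max(.data$frequency), .groups = "drop") |>
    dplyr::filter(.data$max_freq >= min_freq, .data$max_freq > 0) |>
    dplyr::pull("catalog_id")
  # preserve original column order
  keep <- intersect(peptide_ids(abundance), keep)
  abundance[c("sample_id", keep)]
}
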