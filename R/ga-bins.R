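#' Gestational-age bin scheme
#'
#' The eight gestational periods used throughout the analysis, as closed
#' integer intervals over completed weeks of amenorrhea (WA): 11--14, 15--17,
#' 18--21, 22--24, 25--28, 29--31, 32--35 and 36--39 WA. The intervals are
#' non-overlapping, ascending, and jointly cover 11--39 WA.
#'
#' @param breaks optional override: a two-column data frame (or matrix) of
#'   integer `lower`/`upper` bounds, one row per bin, ascending and
#'   non-overlapping.
#' @return a tibble with columns `ga_bin` (label, e.g. `"11-14"`), `lower`,
#'   `upper` (integer weeks, closed bounds).
#' @examples
#' ga_bin_scheme()
#' @export
ga_bin_scheme <- function(breaks = NULL) {
  if (is.null(breaks)) {
    lower <- c(11L, 15L, 18L, 22L, 25L, 29L, 32L, 36L)
    upper <- c(14L, 17L, 21L, 24L, 28L, 31L, 35L, 39L)
  } else {
    breaks <- as.data.frame(breaks)
    if (ncol(breaks) < 2) abort_config("`breaks` needs two columns: lower, upper.")
    lower <- as.integer(breaks[[1]])
    upper <- as.integer(breaks[[2]])
    if (any(upper < lower)) abort_config("each bin needs upper >= lower.")
    if (is.unsorted(lower, strictly = TRUE) ||
        any(lower[-1] <= upper[-length(upper)])) {
      abort_config("bins must be ascending and non-overlapping.")
    }
  }
  tibble::tibble(
    ga_bin = sprintf("%d-%d", lower, upper),
    lower = lower,
    upper = upper
  )
}

#' Assign gestational-age bins to a sample table
#'
#' Gestational age is truncated to completed weeks (obstetric convention)
#' before lookup in the closed-interval bin scheme, so 14.9 WA falls in the
#' 11--14 bin. Every age must land in exactly one bin.
#'
#' @param samples data frame with at least `sample_id` and
#'   `gestational_age_wa` (numeric, weeks of amenorrhea).
#' @param scheme bin scheme tibble from [ga_bin_scheme()].
#' @return the sample table as a tibble with a `ga_bin` factor column
#'   (levels ordered by the scheme), replacing any existing `ga_bin`.
#' @examples
#' s <- tibble::tibble(sample_id = c("a", "b"), gestational_age_wa = c(14.6, 29))
#' assign_ga_bins(s)
#' @export
assign_ga_bins <- function(samples, scheme = ga_bin_scheme()) {
  if (!is.data.frame(samples) || !"gestational_age_wa" %in% names(samples)) {
    abort_usage("`samples` must contain a `gestational_age_wa` column.")
  }
  wk <- floor(samples$gestational_age_wa)
  idx <- vapply(wk, function(w) {
    hit <- which(scheme$lower <= w & w <= scheme$upper)
    if (length(hit) == 1L) hit else NA_integer_
  }, integer(1))
  if (anyNA(idx)) {
    bad <- samples$sample_id[is.na(idx)]
    abort_range(sprintf(
      "gestational age outside the bin scheme for sample(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  dplyr::mutate(
    tibble::as_tibble(samples),
    ga_bin = factor(scheme$ga_bin[idx], levels = scheme$ga_bin)
  )
}
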