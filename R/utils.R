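# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages follow the
#' conventional half-up rule instead (68.63 -> 69, 68.5 -> 69).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

abort_usage <- function(msg, ...) abort(msg, class = "fetopep_usage_error", ...)
abort_data <- function(msg, ...) abort(msg, class = "fetopep_data_error", ...)
abort_format <- function(msg, ...) abort(msg, class = "fetopep_format_error", ...)
abort_range <- function(msg, ...) abort(msg, class = "fetopep_range_error", ...)
abort_config <- function(msg, ...) abort(msg, class = "fetopep_config_error", ...)

# Coerce a samples-by-peptides wide tibble (first column `sample_id`) to a
# numeric matrix with sample_id rownames.
abundance_to_matrix <- function(abundance) {
  if (!is.data.frame(abundance)) {
    abort_usage("`abundance` must be a data frame with a `sample_id` column.")
  }
  if (!"sample_id" %in% names(abundance)) {
    abort_format("abundance table lacks required column `sample_id`.")
  }
  m <- as.matrix(abundance[setdiff(names(abundance), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(abundance$sample_id)
  if (anyNA(m)) {
    abort_data("abundance table contains non-numeric or missing values.")
  }
  if (any(m < 0)) abort_data("abundance values must be nonnegative (0 = not detected).")
  if (anyDuplicated(rownames(m))) abort_data("duplicate sample_id in abundance table.")
  if (anyDuplicated(colnames(m))) abort_data("duplicate peptide catalog_id in abundance table.")
  m
}

matrix_to_abundance <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

peptide_ids <- function(abundance) setdiff(names(abundance), "sample_id")

check_scalar_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort_usage(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
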