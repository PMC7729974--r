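# Delimited-format readers/writers for the peptidome data model.
#
# On disk the wide layout has peptides as rows (first column `catalog_id`,
# remaining columns one per sample); the long layout has one row per
# (sample, peptide) cell with columns sample_id, catalog_id, abundance.
# In memory abundance is always a samples-by-peptides wide tibble whose
# first column is `sample_id`. Absent cells are materialised as 0
# (non-detect); values use '.' as the decimal separator.

sniff_delim <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_quiet <- function(path, ...) {
  if (!file.exists(path)) abort_usage(sprintf("file does not exist: %s", path))
  readr::read_delim(
    path, delim = sniff_delim(path), show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE, ...
  )
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_format(sprintf(
      "%s: missing required column(s): %s", path, paste(missing, collapse = ", ")
    ))
  }
}

parse_abundance_values <- function(x, path) {
  x_chr <- as.character(x)
  vals <- suppressWarnings(as.numeric(x_chr))
  bad <- which(!is.na(x_chr) & x_chr != "" & is.na(vals))
  if (length(bad)) {
    abort_data(sprintf(
      "%s: non-numeric abundance value %s at row %d",
      path, dQuote(x_chr[bad[1]]), bad[1]
    ))
  }
  vals[is.na(vals)] <- 0
  vals
}

#' Read an abundance table
#'
#' @param path CSV/TSV file (delimiter sniffed from the extension).
#' @param layout `"wide"` (file rows are peptides, first column `catalog_id`,
#'   one column per sample) or `"long"` (columns `sample_id`, `catalog_id`,
#'   `abundance`).
#' @return samples-by-peptides wide tibble, first column `sample_id`; empty
#'   or absent cells become 0 (not detected).
#' @export
read_abundance <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  raw <- read_delim_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  if (layout == "wide") {
    require_columns(raw, "catalog_id", path)
    if (anyDuplicated(raw$catalog_id)) {
      abort_data(sprintf("%s: duplicate catalog_id rows", path))
    }
    sample_ids <- setdiff(names(raw), "catalog_id")
    if (!length(sample_ids)) abort_format(sprintf("%s: no sample columns", path))
    m <- vapply(sample_ids, function(s) parse_abundance_values(raw[[s]], path),
                numeric(nrow(raw)))
    m <- matrix(m, nrow = nrow(raw), dimnames = list(NULL, sample_ids))
    out <- t(m)
    colnames(out) <- raw$catalog_id
    rownames(out) <- sample_ids
    matrix_to_abundance(out)
  } else {
    require_columns(raw, c("sample_id", "catalog_id", "abundance"), path)
    raw$abundance <- parse_abundance_values(raw$abundance, path)
    dup <- dplyr::summarise(
      dplyr::group_by(raw, .data$sample_id, .data$catalog_id),
      n = dplyr::n(), distinct = dplyr::n_distinct(.data$abundance),
      .groups = "drop"
    )
    conflict <- dplyr::filter(dup, .data$n > 1, .data$distinct > 1)
    if (nrow(conflict)) {
      abort_data(sprintf(
        "%s: conflicting duplicate cell(s), e.g. (%s, %s)",
        path, conflict$sample_id[1], conflict$catalog_id[1]
      ))
    }
    raw <- dplyr::distinct(raw, .data$sample_id, .data$catalog_id, .keep_all = TRUE)
    wide <- tidyr::pivot_wider(
      raw[c("sample_id", "catalog_id", "abundance")],
      names_from = "catalog_id", values_from = "abundance", values_fill = 0
    )
    tibble::as_tibble(wide)
  }
}

#' Write an abundance table
#'
#' @param abundance samples-by-peptides wide tibble (first column `sample_id`).
#' @param path output CSV/TSV path (delimiter from extension).
#' @param layout on-disk layout, see [read_abundance()]. Long output drops
#'   zero cells (non-detects are implicit).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(abundance, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  m <- abundance_to_matrix(abundance)
  if (layout == "wide") {
    out <- dplyr::bind_cols(
      tibble::tibble(catalog_id = colnames(m)),
      tibble::as_tibble(t(m), .name_repair = "minimal")
    )
  } else {
    out <- matrix_to_abundance(m) |>
      tidyr::pivot_longer(-"sample_id", names_to = "catalog_id",
                          values_to = "abundance") |>
      dplyr::filter(.data$abundance > 0)
  }
  readr::write_delim(out, path, delim = sniff_delim(path), progress = FALSE)
  invisible(path)
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

validate_catalog <- function(catalog, path = "catalog") {
  require_columns(catalog, c("catalog_id", "mass_da"), path)
  catalog <- tibble::as_tibble(catalog)
  catalog$catalog_id <- as.character(catalog$catalog_id)
  if (anyDuplicated(catalog$catalog_id)) {
    abort_data(sprintf("%s: duplicate catalog_id", path))
  }
  catalog$mass_da <- as.numeric(catalog$mass_da)
  if (any(is.na(catalog$mass_da) | catalog$mass_da <= 0)) {
    abort_data(sprintf("%s: mass_da must be a positive number", path))
  }
  if ("sequence" %in% names(catalog)) {
    seqs <- catalog$sequence
    ok <- is.na(seqs) | seqs == "" | grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)
    if (!all(ok)) {
      abort_data(sprintf(
        "%s: invalid amino-acid sequence for catalog_id %s",
        path, catalog$catalog_id[which(!ok)[1]]
      ))
    }
    catalog$sequence[!is.na(seqs) & seqs == ""] <- NA_character_
  }
  catalog
}

validate_samples <- function(samples, path = "samples") {
  require_columns(samples, c("sample_id", "fluid", "gestational_age_wa"), path)
  samples <- tibble::as_tibble(samples)
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    abort_data(sprintf("%s: duplicate sample_id", path))
  }
  if (!all(samples$fluid %in% c("AF", "FU"))) {
    abort_data(sprintf("%s: fluid must be 'AF' or 'FU'", path))
  }
  samples$gestational_age_wa <- as.numeric(samples$gestational_age_wa)
  if ("patient_id" %in% names(samples)) {
    per <- table(samples$patient_id[!is.na(samples$patient_id)],
                 samples$fluid[!is.na(samples$patient_id)])
    if (any(per > 1)) {
      abort_data(sprintf("%s: a patient_id has more than one sample per fluid", path))
    }
  }
  samples
}

#' Read a peptidome triple (catalog, samples, abundance)
#'
#' Reads the three delimited tables and checks that every abundance axis key
#' resolves in its table: samples in the sample table, peptides in the
#' catalog. A warning (not an error) is raised when per-sample abundance
#' totals differ by more than `total_ratio_warn`-fold, as a sanity check
#' that upstream normalisation was applied.
#'
#' @param abundance_path,catalog_path,samples_path file paths;
#'   `catalog_path`/`samples_path` may be `NULL` to skip that table.
#' @param layout abundance layout, see [read_abundance()].
#' @param total_ratio_warn warn if max/min per-sample total exceeds this.
#' @return list with elements `catalog`, `samples`, `abundance`.
#' @export
read_peptidome <- function(abundance_path, catalog_path = NULL,
                           samples_path = NULL, layout = c("wide", "long"),
                           total_ratio_warn = 10) {
  abundance <- read_abundance(abundance_path, layout)
  catalog <- if (!is.null(catalog_path)) {
    validate_catalog(read_delim_quiet(catalog_path), catalog_path)
  }
  samples <- if (!is.null(samples_path)) {
    validate_samples(read_delim_quiet(samples_path), samples_path)
  }
  if (!is.null(catalog)) {
    unknown <- setdiff(peptide_ids(abundance), catalog$catalog_id)
    if (length(unknown)) {
      abort_data(sprintf(
        "abundance peptide(s) missing from catalog: %s%s",
        paste(head(unknown, 3), collapse = ", "),
        if (length(unknown) > 3) ", ..." else ""
      ))
    }
  }
  if (!is.null(samples)) {
    unknown <- setdiff(abundance$sample_id, samples$sample_id)
    if (length(unknown)) {
      abort_data(sprintf(
        "abundance sample(s) missing from sample table: %s",
        paste(head(unknown, 3), collapse = ", ")
      ))
    }
  }
  totals <- rowSums(abundance_to_matrix(abundance))
  pos <- totals[totals > 0]
  if (length(pos) > 1 && max(pos) / min(pos) > total_ratio_warn) {
    warn(sprintf(
      "per-sample abundance totals differ by > %gx; input may not be normalized",
      total_ratio_warn
    ))
  }
  list(catalog = catalog, samples = samples, abundance = abundance)
}
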