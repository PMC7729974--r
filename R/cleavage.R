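# Rule-based in-silico protease digestion.
#
# A bond between residues i and i+1 (0-based residue indexing; the reported
# cut position is i, i.e. the index of the bond after residue i) is cleaved
# when it matches at least one site rule of the enzyme and is not blocked.
# A site rule fires when the P1 residue (N-terminal to the scissile bond)
# belongs to `p1`, or - for enzymes such as pepsin that also recognise the
# C-terminal side - when the P1' residue belongs to `p1_prime`. `block_p1p`
# lists P1' residues that veto a P1 match (e.g. proline after a tryptic
# K/R). The built-in tables are simplified versions of the ExPASy
# PeptideCutter specificities.

new_cleavage_rules <- function(enzyme, p1 = character(), p1_prime = character(),
                               block_p1p = character()) {
  stopifnot(all(c(p1, p1_prime, block_p1p) %in% AA_ALPHABET))
  if (!length(p1) && !length(p1_prime)) abort_usage("a rule set needs at least one residue set.")
  structure(list(enzyme = enzyme, p1 = p1, p1_prime = p1_prime,
                 block_p1p = block_p1p),
            class = "cleavage_rules")
}

#' @export
print.cleavage_rules <- function(x, ...) {
  cat(sprintf("<cleavage_rules: %s> cut after [%s]%s%s\n",
              x$enzyme, paste(x$p1, collapse = ""),
              if (length(x$block_p1p)) sprintf(" unless before [%s]", paste(x$block_p1p, collapse = "")) else "",
              if (length(x$p1_prime)) sprintf("; also before [%s]", paste(x$p1_prime, collapse = "")) else ""))
  invisible(x)
}

#' Built-in protease cleavage rules
#'
#' Simplified specificity tables for proteases plausibly present in amniotic
#' fluid: trypsin (after K/R unless followed by P), high-specificity
#' chymotrypsin (after F/Y/W unless followed by P), Arg-C proteinase (after
#' R), and two pepsin models (pH 1.3: around F/L; pH > 2: around F/L/W/Y),
#' which cut when either side of the bond matches. These approximate the
#' ExPASy PeptideCutter tables without their full context exceptions; custom
#' rule sets can be built with the same structure via the `custom` argument.
#'
#' @param enzymes character vector among `"trypsin"`, `"chymotrypsin"`,
#'   `"arg_c"`, `"pepsin_ph1.3"`, `"pepsin_ph2"`; default all.
#' @param custom optional list of lists with fields `enzyme`, `p1`,
#'   `p1_prime`, `block_p1p` appended to the panel.
#' @return named list of `cleavage_rules` objects.
#' @export
cleavage_rules <- function(enzymes = c("trypsin", "chymotrypsin", "arg_c",
                                       "pepsin_ph1.3", "pepsin_ph2"),
                           custom = NULL) {
  builtin <- list(
    trypsin = new_cleavage_rules("trypsin", p1 = c("K", "R"), block_p1p = "P"),
    chymotrypsin = new_cleavage_rules("chymotrypsin", p1 = c("F", "Y", "W"),
                                      block_p1p = "P"),
    arg_c = new_cleavage_rules("arg_c", p1 = "R"),
    `pepsin_ph1.3` = new_cleavage_rules("pepsin_ph1.3", p1 = c("F", "L"),
                                        p1_prime = c("F", "L")),
    pepsin_ph2 = new_cleavage_rules("pepsin_ph2", p1 = c("F", "L", "W", "Y"),
                                    p1_prime = c("F", "L", "W", "Y"))
  )
  enzymes <- match.arg(enzymes, names(builtin), several.ok = TRUE)
  out <- builtin[enzymes]
  for (cu in custom %||% list()) {
    out[[cu$enzyme]] <- new_cleavage_rules(
      cu$enzyme, cu$p1 %||% character(),
      cu$p1_prime %||% character(), cu$block_p1p %||% character()
    )
  }
  out
}

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) < 2) {
    abort_usage("`sequence` must be a single amino-acid string of length >= 2.")
  }
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% AA_ALPHABET)
  if (length(bad)) {
    abort_data(sprintf("invalid residue '%s' at position %d", res[bad[1]], bad[1]))
  }
  res
}

#' Cleavage sites of one enzyme on one sequence
#'
#' @param sequence amino-acid string (20-letter alphabet, length >= 2).
#' @param rules a `cleavage_rules` object (one element of [cleavage_rules()]).
#' @return strictly ascending integer vector of cut positions; position `i`
#'   (0-based) is the bond between residues `i` and `i + 1`, so values range
#'   over `0 .. nchar(sequence) - 2`. Terminal "bonds" outside the chain do
#'   not exist and are never reported.
#' @examples
#' cleavage_sites("GKAG", cleavage_rules("trypsin")$trypsin)  # 1
#' cleavage_sites("GKPG", cleavage_rules("trypsin")$trypsin)  # blocked by P
#' @export
cleavage_sites <- function(sequence, rules) {
  if (!inherits(rules, "cleavage_rules")) {
    abort_usage("`rules` must be a single cleavage_rules object.")
  }
  res <- check_sequence(sequence)
  n <- length(res)
  p1 <- res[seq_len(n - 1)]
  p1p <- res[seq_len(n - 1) + 1]
  hit <- (p1 %in% rules$p1 & !(p1p %in% rules$block_p1p)) |
    (p1p %in% rules$p1_prime)
  which(hit) - 1L
}

#' Degradability of a sequence under an enzyme panel
#'
#' A peptide is degradable when at least one enzyme of the panel has at least
#' one internal cleavage site. Adding enzymes can only keep or increase
#' degradability.
#'
#' @param sequence amino-acid string.
#' @param enzyme_panel named list of `cleavage_rules`, see [cleavage_rules()].
#' @return one-row tibble: `degradable` plus one `n_sites_<enzyme>` column
#'   per enzyme.
#' @export
degradable <- function(sequence, enzyme_panel = cleavage_rules()) {
  if (!length(enzyme_panel)) abort_usage("the enzyme panel must be non-empty.")
  counts <- vapply(enzyme_panel,
                   function(r) length(cleavage_sites(sequence, r)), integer(1))
  out <- tibble::as_tibble(as.list(setNames(counts, paste0("n_sites_", names(counts)))))
  dplyr::bind_cols(tibble::tibble(degradable = any(counts > 0)), out)
}

#' Digest a table of peptide sequences
#'
#' Applies [degradable()] to every sequenced peptide of a catalog-like table,
#' e.g. to ask how many fluid-specific peptides could be degraded by
#' proteases of the other fluid.
#'
#' @param peptides data frame with `catalog_id` and `sequence` columns
#'   (rows without a sequence are skipped).
#' @param enzyme_panel named list of `cleavage_rules`.
#' @return tibble: `catalog_id`, `degradable`, per-enzyme site counts.
#' @export
digest_peptides <- function(peptides, enzyme_panel = cleavage_rules()) {
  if (!all(c("catalog_id", "sequence") %in% names(peptides))) {
    abort_usage("`peptides` needs `catalog_id` and `sequence` columns.")
  }
  rows <- which(!is.na(peptides$sequence) & peptides$sequence != "")
  purrr::map_dfr(rows, function(i) {
    dplyr::bind_cols(
      tibble::tibble(catalog_id = as.character(peptides$catalog_id[i])),
      degradable(peptides$sequence[i], enzyme_panel)
    )
  })
}
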