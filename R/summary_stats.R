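#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited file of per-variant association statistics
#' into the standard column layout used throughout the package:
#' `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`, `p_value`,
#' and optionally `eaf` (effect-allele frequency) and `n` (sample size).
#'
#' The delimiter is auto-detected from the header line (tab preferred, then
#' comma); any other dialect must be converted upstream. Alleles are
#' uppercased. Rows whose `beta` or `se` cannot be parsed as numbers, whose
#' `se` is not positive, or whose `p_value` falls outside (0, 1] are rejected
#' rather than fatal: they are dropped from the result and returned in the
#' `"rejected"` attribute with a reason, and a warning summarises the count.
#' Reading fails only if the file is empty, a mapped column is missing, or
#' every row is malformed.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector or list mapping standard field
#'   names to column names in the file, e.g.
#'   `c(variant_id = "SNP", beta = "Effect")`. Fields not mentioned use the
#'   recommended default names (`variant_id`, `effect_allele`, `other_allele`,
#'   `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, `n`).
#' @return A tibble with one row per well-formed data row, in file order,
#'   with attribute `"rejected"` (a tibble of `variant_id`, `row`, `reason`).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "variant_id\teffect_allele\tother_allele\tbeta\tstandard_error\tp_value",
#'   "rs1\ta\tg\t0.12\t0.01\t1e-30",
#'   "rs2\tC\tT\t-0.08\t0.02\t4e-9"
#' ), tf)
#' read_summary_stats(tf)
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "cardiomr_error_io")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(first)) {
    abort("Empty summary-statistics file.", class = "cardiomr_error_empty_file")
  }
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","

  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE
  )
  if (nrow(raw) == 0L) {
    abort("Summary-statistics file has a header but no data rows.",
          class = "cardiomr_error_empty_file")
  }

  defaults <- c(
    variant_id = "variant_id", effect_allele = "effect_allele",
    other_allele = "other_allele", eaf = "effect_allele_frequency",
    beta = "beta", se = "standard_error", p_value = "p_value", n = "n"
  )
  map <- defaults
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    unknown <- setdiff(names(column_map), names(defaults))
    if (length(unknown)) {
      abort(sprintf("Unknown field(s) in column_map: %s",
                    paste(unknown, collapse = ", ")),
            class = "cardiomr_error_domain")
    }
    map[names(column_map)] <- column_map
  }

  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
                "p_value")
  missing_cols <- required[!map[required] %in% names(raw)]
  if (length(missing_cols)) {
    abort(
      sprintf("Missing column(s) in %s: %s (mapped from field %s)",
              path, paste(map[missing_cols], collapse = ", "),
              paste(missing_cols, collapse = ", ")),
      class = "cardiomr_error_missing_column",
      fields = missing_cols
    )
  }

  out <- tibble::tibble(
    variant_id = raw[[map[["variant_id"]]]],
    effect_allele = toupper(raw[[map[["effect_allele"]]]]),
    other_allele = toupper(raw[[map[["other_allele"]]]]),
    beta = suppressWarnings(as.numeric(raw[[map[["beta"]]]])),
    se = suppressWarnings(as.numeric(raw[[map[["se"]]]])),
    p_value = suppressWarnings(as.numeric(raw[[map[["p_value"]]]])),
    eaf = if (map[["eaf"]] %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[map[["eaf"]]]]))
    } else NA_real_,
    n = if (map[["n"]] %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[map[["n"]]]]))
    } else NA_real_
  )

  bad_reason <- dplyr::case_when(
    is.na(out$beta) ~ "unparseable beta",
    is.na(out$se) | out$se <= 0 ~ "invalid se",
    is.na(out$p_value) | out$p_value <= 0 | out$p_value > 1 ~ "invalid p_value",
    !out$effect_allele %in% c("A", "C", "G", "T") |
      !out$other_allele %in% c("A", "C", "G", "T") ~ "invalid allele",
    out$effect_allele == out$other_allele ~ "identical alleles",
    TRUE ~ NA_character_
  )
  rejected <- tibble::tibble(
    variant_id = out$variant_id[!is.na(bad_reason)],
    row = which(!is.na(bad_reason)),
    reason = bad_reason[!is.na(bad_reason)]
  )
  out <- out[is.na(bad_reason), , drop = FALSE]
  if (nrow(out) == 0L) {
    abort("All rows malformed; nothing to read.",
          class = "cardiomr_error_all_malformed")
  }
  if (nrow(rejected) > 0L) {
    warn(sprintf("%d malformed row(s) rejected while reading %s.",
                 nrow(rejected), path))
  }
  attr(out, "rejected") <- rejected
  out
}

#' Retrieve rows rejected during summary-statistics parsing
#'
#' @param x A tibble returned by [read_summary_stats()].
#' @return A tibble of `variant_id`, `row`, `reason` (zero rows if none).
#' @export
rejected_rows <- function(x) {
  r <- attr(x, "rejected")
  if (is.null(r)) {
    r <- tibble::tibble(variant_id = character(), row = integer(),
                        reason = character())
  }
  r
}

# Validate a summary-statistics tibble has the columns estimators rely on.
check_assoc_table <- function(x, name = "assocs",
                              cols = c("variant_id", "beta", "se", "p_value")) {
  if (!is.data.frame(x)) {
    stop_domain(sprintf("`%s` must be a data frame.", name))
  }
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    abort(sprintf("`%s` lacks column(s): %s", name, paste(miss, collapse = ", ")),
          class = "cardiomr_error_missing_column", fields = miss)
  }
  invisible(x)
}
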