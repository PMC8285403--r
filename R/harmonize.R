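#' Harmonize exposure and outcome summary statistics to one effect allele
#'
#' Pairs each exposure instrument with its outcome association and expresses
#' both effects for the exposure's effect allele. Matching is by `variant_id`
#' only. For each exposure variant found in the outcome table:
#'
#' * outcome alleles in the same orientation: kept as-is (`status = "direct"`);
#' * outcome alleles swapped (outcome effect allele equals the exposure other
#'   allele): the outcome beta is negated and its effect-allele frequency
#'   reflected (`status = "allele_flipped"`);
#' * palindromic pairs (A/T or C/G), whose strand is ambiguous: under
#'   `palindrome_policy = "drop"` they are excluded; under `"infer_by_eaf"`
#'   allele frequencies orient the pair (`status = "palindromic_inferred"`),
#'   the outcome beta being negated when the frequencies indicate opposite
#'   coding. A palindromic pair is dropped when either frequency is missing
#'   or lies within `0.5 +/- eaf_ambiguity_band` (reason
#'   `"ambiguous palindrome"`), because frequency cannot then distinguish the
#'   strands.
#'
#' Exposure variants absent from the outcome table are recorded in the drop
#' log with reason `"missing_in_outcome"` unless a proxy substitution is
#' supplied via `proxies` (see [substitute_proxies()]), in which case the
#' proxy's outcome association is paired with the target's exposure effect
#' (`status = "proxy"`; no allele-orientation logic is applied across distinct
#' variants). Outcome allele pairs that are neither identical nor swapped are
#' dropped as `"allele_mismatch"`.
#'
#' Harmonization is idempotent: re-harmonizing the exposure/outcome tables of
#' a harmonized set (see [harmonized_tables()]) reproduces it with every
#' status `"direct"`.
#'
#' @param exposure,outcome Summary-statistics tibbles as returned by
#'   [read_summary_stats()] (or the generator). The exposure rows are the
#'   selected instruments.
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eaf_ambiguity_band Half-width of the frequency band around 0.5
#'   within which a palindromic pair is considered unorientable; default 0.08
#'   (drop when EAF in 0.42-0.58).
#' @param proxies Optional tibble from [substitute_proxies()] with columns
#'   `target_id`, `proxy_id`, `r2`.
#' @param exposure_label,outcome_label Trait labels carried into reports.
#' @return A tibble of class `mr_harmonized` with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `eaf_exposure`, `eaf_outcome`, `status`,
#'   `proxy_id`, `r2_with_proxy`; the drop log is in `attr(, "dropped")`
#'   (also via [dropped_variants()]).
#' @seealso [dropped_variants()], [harmonized_tables()], [mr_ivw()]
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop"),
                      eaf_ambiguity_band = 0.08,
                      proxies = NULL,
                      exposure_label = "exposure",
                      outcome_label = "outcome") {
  palindrome_policy <- match.arg(palindrome_policy)
  check_number(eaf_ambiguity_band, "eaf_ambiguity_band", 0, 0.5)
  check_assoc_table(exposure, "exposure",
                    c("variant_id", "effect_allele", "other_allele", "beta", "se"))
  check_assoc_table(outcome, "outcome",
                    c("variant_id", "effect_allele", "other_allele", "beta", "se"))
  if (anyDuplicated(exposure$variant_id)) {
    stop_domain("Duplicate variant_id in exposure instruments.")
  }
  if (!"eaf" %in% names(exposure)) exposure$eaf <- NA_real_
  if (!"eaf" %in% names(outcome)) outcome$eaf <- NA_real_
  outcome <- outcome[!duplicated(outcome$variant_id), , drop = FALSE]

  n <- nrow(exposure)
  j <- match(exposure$variant_id, outcome$variant_id)
  found <- !is.na(j)

  by <- outcome$beta[j]
  sy <- outcome$se[j]
  eaf_oc <- outcome$eaf[j]
  oc_ea <- outcome$effect_allele[j]
  oc_oa <- outcome$other_allele[j]

  same <- found & oc_ea == exposure$effect_allele &
    oc_oa == exposure$other_allele
  swapped <- found & oc_ea == exposure$other_allele &
    oc_oa == exposure$effect_allele

  by[swapped] <- -by[swapped]
  eaf_oc[swapped] <- 1 - eaf_oc[swapped]

  status <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  status[same] <- "direct"
  status[swapped] <- "allele_flipped"
  reason[found & !same & !swapped] <- "allele_mismatch"
  reason[!found] <- "missing_in_outcome"

  pal <- is_palindromic(exposure$effect_allele, exposure$other_allele) &
    (same | swapped)
  if (any(pal)) {
    if (palindrome_policy == "drop") {
      status[pal] <- NA_character_
      reason[pal] <- "palindromic"
    } else {
      band_lo <- 0.5 - eaf_ambiguity_band
      band_hi <- 0.5 + eaf_ambiguity_band
      no_eaf <- pal & (is.na(exposure$eaf) | is.na(eaf_oc))
      ambiguous <- pal & !no_eaf &
        ((exposure$eaf > band_lo & exposure$eaf < band_hi) |
           (eaf_oc > band_lo & eaf_oc < band_hi))
      status[no_eaf] <- NA_character_
      reason[no_eaf] <- "missing EAF on palindrome"
      status[ambiguous] <- NA_character_
      reason[ambiguous] <- "ambiguous palindrome"
      ok <- pal & !no_eaf & !ambiguous
      # Discordant minor/major orientation across studies means the outcome
      # coding refers to the complementary-strand allele: flip the sign.
      discord <- ok & ((exposure$eaf < 0.5) != (eaf_oc < 0.5))
      by[discord] <- -by[discord]
      eaf_oc[discord] <- 1 - eaf_oc[discord]
      status[ok] <- "palindromic_inferred"
    }
  }

  proxy_id <- rep(NA_character_, n)
  r2_with_proxy <- rep(NA_real_, n)
  if (!is.null(proxies) && nrow(proxies) > 0L) {
    miss <- which(!found)
    pm <- match(exposure$variant_id[miss], proxies$target_id)
    has <- !is.na(pm)
    pj <- match(proxies$proxy_id[pm[has]], outcome$variant_id)
    usable <- !is.na(pj) & !is.na(proxies$proxy_id[pm[has]])
    idx <- miss[has][usable]
    pjj <- pj[usable]
    if (length(idx)) {
      by[idx] <- outcome$beta[pjj]
      sy[idx] <- outcome$se[pjj]
      eaf_oc[idx] <- outcome$eaf[pjj]
      status[idx] <- "proxy"
      reason[idx] <- NA_character_
      proxy_id[idx] <- outcome$variant_id[pjj]
      r2_with_proxy[idx] <- proxies$r2[pm[has]][usable]
    }
  }

  kept <- !is.na(status)
  instruments <- tibble::tibble(
    variant_id = exposure$variant_id[kept],
    effect_allele = exposure$effect_allele[kept],
    other_allele = exposure$other_allele[kept],
    beta_exposure = exposure$beta[kept],
    se_exposure = exposure$se[kept],
    beta_outcome = by[kept],
    se_outcome = sy[kept],
    eaf_exposure = exposure$eaf[kept],
    eaf_outcome = eaf_oc[kept],
    status = status[kept],
    proxy_id = proxy_id[kept],
    r2_with_proxy = r2_with_proxy[kept]
  )
  dropped <- tibble::tibble(
    variant_id = exposure$variant_id[!kept],
    reason = reason[!kept]
  )
  new_harmonized(instruments, dropped, exposure_label, outcome_label)
}

new_harmonized <- function(instruments, dropped, exposure_label, outcome_label) {
  structure(
    instruments,
    dropped = dropped,
    exposure_label = exposure_label,
    outcome_label = outcome_label,
    class = c("mr_harmonized", class(tibble::tibble()))
  )
}

#' Drop log of a harmonized instrument set
#'
#' @param x An `mr_harmonized` tibble from [harmonize()].
#' @return Tibble of `variant_id`, `reason` for every exposure instrument not
#'   carried into the harmonized set.
#' @export
dropped_variants <- function(x) {
  stopifnot(inherits(x, "mr_harmonized"))
  attr(x, "dropped")
}

#' Re-express a harmonized set as exposure and outcome association tables
#'
#' Returns the two variant tables implied by a harmonized set, both on the
#' harmonized effect-allele orientation. Useful for round-trip checks
#' (harmonization is idempotent on these tables) and for exporting.
#'
#' @param x An `mr_harmonized` tibble.
#' @return A list with elements `exposure` and `outcome`.
#' @export
harmonized_tables <- function(x) {
  stopifnot(inherits(x, "mr_harmonized"))
  tb <- tibble::as_tibble(x)
  list(
    exposure = tibble::tibble(
      variant_id = tb$variant_id, effect_allele = tb$effect_allele,
      other_allele = tb$other_allele, beta = tb$beta_exposure,
      se = tb$se_exposure, p_value = wald_p(tb$beta_exposure, tb$se_exposure),
      eaf = tb$eaf_exposure
    ),
    outcome = tibble::tibble(
      variant_id = tb$variant_id, effect_allele = tb$effect_allele,
      other_allele = tb$other_allele, beta = tb$beta_outcome,
      se = tb$se_outcome, p_value = wald_p(tb$beta_outcome, tb$se_outcome),
      eaf = tb$eaf_outcome
    )
  )
}

#' Write a harmonized set and its drop log to TSV
#'
#' Writes one row per instrument to `path` and, if any variants were dropped,
#' a sibling file `<path>.dropped.tsv` with the drop log.
#'
#' @param x An `mr_harmonized` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(x, path) {
  stopifnot(inherits(x, "mr_harmonized"))
  readr::write_tsv(tibble::as_tibble(x), path)
  d <- dropped_variants(x)
  if (nrow(d) > 0L) {
    readr::write_tsv(d, paste0(path, ".dropped.tsv"))
  }
  invisible(path)
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("<mr_harmonized> %s -> %s: %d instrument(s), %d dropped\n",
              attr(x, "exposure_label"), attr(x, "outcome_label"),
              nrow(x), nrow(attr(x, "dropped"))))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
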