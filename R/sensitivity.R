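#' Leave-one-out influence analysis
#'
#' Re-estimates the IVW causal effect omitting each instrument in turn and
#' flags variants whose omission changes the significance classification of
#' the association at level `alpha` (in either direction), mirroring how
#' influential variants are reported: a variant whose exclusion induces or
#' removes a significant result.
#'
#' @inheritParams mr_ivw
#' @param alpha Significance level for the classification flag; default 0.05.
#' @param model IVW model for the full-set and omission fits.
#' @return Tibble of class `mr_loo` with one row per instrument:
#'   `omitted_variant`, `k`, `beta`, `se`, `p_value`, `classification_changed`.
#'   The full-set estimate is in `attr(, "full_estimate")`.
#' @export
leave_one_out <- function(data, alpha = 0.05, model = c("random", "fixed")) {
  model <- match.arg(model)
  check_harmonized_cols(data)
  check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  k <- nrow(data)
  if (k < 2L) stop_insufficient("Leave-one-out needs at least 2 instruments.")
  ids <- if ("variant_id" %in% names(data)) data$variant_id else
    paste0("instrument_", seq_len(k))
  eff_model <- if (k - 1L >= 2L) model else "fixed"
  full <- mr_ivw(data, model = if (k >= 2L) model else "fixed")
  full_sig <- full$p_value < alpha
  rows <- purrr::map_dfr(seq_len(k), function(i) {
    est <- mr_ivw(data[-i, , drop = FALSE], model = eff_model)
    tibble::tibble(
      omitted_variant = ids[i], k = est$k, beta = est$beta, se = est$se,
      p_value = est$p_value,
      classification_changed = (est$p_value < alpha) != full_sig
    )
  })
  structure(rows, full_estimate = full, alpha = alpha,
            class = c("mr_loo", class(tibble::tibble())))
}

#' Directional-pleiotropy report (MR-Egger intercept)
#'
#' Extracts the MR-Egger intercept, its standard error and p-value, the
#' standard test for average directional pleiotropy across the instrument
#' set: a nonzero intercept indicates that invalid pathways do not cancel.
#'
#' @inheritParams mr_ivw
#' @return One-row tibble: `intercept`, `intercept_se`, `intercept_p`.
#' @export
pleiotropy_report <- function(data) {
  est <- mr_egger(data)
  ic <- est[est$method == "egger_intercept", ]
  tibble::tibble(
    intercept = ic$beta, intercept_se = ic$se, intercept_p = ic$p_value
  )
}
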