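#' Select genome-wide-significant instruments
#'
#' Keeps associations with `p_value` strictly below `p_threshold`, preserving
#' input order. The conventional genome-wide threshold 5e-8 is the default.
#'
#' @param assocs Summary-statistics tibble (needs `p_value`).
#' @param p_threshold Significance cutoff in (0, 1); strict inequality.
#' @return The filtered tibble (possibly zero rows).
#' @export
select_instruments <- function(assocs, p_threshold = 5e-8) {
  check_assoc_table(assocs, "assocs", "p_value")
  check_number(p_threshold, "p_threshold", 0, 1, open_lower = TRUE,
               open_upper = TRUE)
  assocs[assocs$p_value < p_threshold, , drop = FALSE]
}

#' Greedy LD pruning to an approximately independent instrument set
#'
#' Sorts candidates by ascending p-value (ties broken by `variant_id`), then
#' repeatedly accepts the best remaining variant and discards every remaining
#' variant in LD with it at `r2 >= r2_threshold`. All accepted pairs therefore
#' satisfy `r2 < r2_threshold`. This is the standard clumping rule: when two
#' variants are linked, the one with the lowest association p-value survives.
#'
#' @param assocs Summary-statistics tibble with `variant_id` and `p_value`.
#' @param ld An [ld_reference()]; pairs absent from it count as r2 = 0.
#' @param r2_threshold LD cutoff in (0, 1]; default 0.01.
#' @param strict Error when a candidate is absent from the LD reference
#'   instead of assuming independence.
#' @return Accepted rows, in acceptance order (ascending p-value).
#' @export
ld_prune <- function(assocs, ld, r2_threshold = 0.01, strict = FALSE) {
  check_assoc_table(assocs, "assocs", c("variant_id", "p_value"))
  check_number(r2_threshold, "r2_threshold", 0, 1, open_lower = TRUE)
  stopifnot(inherits(ld, "ld_reference"))
  if (strict) {
    absent <- setdiff(assocs$variant_id, ld$ids)
    if (length(absent)) {
      abort(sprintf("Variant(s) absent from LD reference: %s",
                    paste(absent, collapse = ", ")),
            class = "cardiomr_error_unknown_variant")
    }
  }
  ord <- order(assocs$p_value, assocs$variant_id)
  pool <- assocs[ord, , drop = FALSE]
  keep <- integer(0)
  alive <- rep(TRUE, nrow(pool))
  for (i in seq_len(nrow(pool))) {
    if (!alive[i]) next
    keep <- c(keep, i)
    if (i < nrow(pool)) {
      rest <- which(alive & seq_len(nrow(pool)) > i)
      if (length(rest)) {
        r2 <- ld_r2(ld, pool$variant_id[i], pool$variant_id[rest])
        alive[rest[r2 >= r2_threshold]] <- FALSE
      }
    }
  }
  pool[keep, , drop = FALSE]
}

#' Find proxy variants for instruments missing from the outcome study
#'
#' For each missing target, selects the outcome-present variant with the
#' highest r-squared strictly greater than `r2_min` (default 0.9). Ties are
#' broken by smaller exposure p-value (when `exposure` is supplied), then by
#' lexicographic variant id. Targets with no qualifying proxy are reported
#' with `proxy_id = NA`.
#'
#' @param missing Character vector of target variant ids.
#' @param ld An [ld_reference()].
#' @param outcome Outcome summary-statistics tibble (candidate proxies must be
#'   present here).
#' @param r2_min Minimum r-squared, strict; default 0.9.
#' @param exposure Optional exposure tibble used for the p-value tie-break.
#' @return Tibble of `target_id`, `proxy_id`, `r2`; unsubstituted targets have
#'   `proxy_id = NA` and `r2 = NA`.
#' @export
substitute_proxies <- function(missing, ld, outcome, r2_min = 0.9,
                               exposure = NULL) {
  stopifnot(inherits(ld, "ld_reference"))
  check_assoc_table(outcome, "outcome", "variant_id")
  check_number(r2_min, "r2_min", 0, 1, open_lower = TRUE)
  candidates <- setdiff(unique(outcome$variant_id), missing)
  exp_p <- if (!is.null(exposure)) {
    setNames(exposure$p_value, exposure$variant_id)
  } else NULL
  purrr::map_dfr(missing, function(target) {
    if (length(candidates) == 0L) {
      return(tibble::tibble(target_id = target, proxy_id = NA_character_,
                            r2 = NA_real_))
    }
    r2 <- ld_r2(ld, target, candidates)
    ok <- which(r2 > r2_min)
    if (length(ok) == 0L) {
      return(tibble::tibble(target_id = target, proxy_id = NA_character_,
                            r2 = NA_real_))
    }
    cand <- candidates[ok]
    pv <- if (!is.null(exp_p)) {
      ifelse(is.na(exp_p[cand]), Inf, exp_p[cand])
    } else rep(Inf, length(cand))
    pick <- order(-r2[ok], pv, cand)[1]
    tibble::tibble(target_id = target, proxy_id = cand[pick], r2 = r2[ok][pick])
  })
}

#' Regression F-statistic for an instrument set
#'
#' Instrument strength from the variance explained: `F = (r2/(1-r2)) *
#' ((n-k-1)/k)` for `k` instruments jointly explaining a fraction `r2` of the
#' exposure variance in a study of `n` individuals. F > 10 is the
#' conventional screen against weak-instrument bias.
#'
#' @param r2_explained Fraction of exposure variance explained, in \[0, 1).
#' @param n Exposure-study sample size; must exceed `k + 1`.
#' @param k Number of instruments.
#' @return The F-statistic (nonnegative scalar).
#' @examples
#' instrument_f_statistic(0.15, 65556, 104)
#' @export
instrument_f_statistic <- function(r2_explained, n, k) {
  check_number(r2_explained, "r2_explained", 0, 1, open_upper = TRUE)
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (n <= k + 1) stop_domain("`n` must exceed `k` + 1.")
  (r2_explained / (1 - r2_explained)) * ((n - k - 1) / k)
}

#' Per-variant F-statistic (squared Wald z)
#'
#' @param beta,se Effect estimate and its standard error (vectorized).
#' @return `(beta/se)^2`.
#' @export
per_variant_f <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop_domain("`se` must be positive and finite.")
  }
  (beta / se)^2
}

#' Analytic power of a two-sample MR test with a binary outcome
#'
#' Normal-approximation power of the IVW z-test for a log-odds causal effect
#' `ln(or_alternative)` per standard-deviation increase in the exposure, with
#' instruments explaining `r2_explained` of the exposure variance and an
#' outcome GWAS of `n` individuals at case fraction `case_fraction`. The
#' noncentrality is `|ln OR| * sqrt(n * r2 * cf * (1 - cf))` and power is
#' `pnorm(lambda - z*) + pnorm(-lambda - z*)`; at `or_alternative = 1` the
#' function returns exactly `alpha`.
#'
#' @param n Outcome-study sample size.
#' @param case_fraction Proportion of cases, in (0, 1).
#' @param r2_explained Exposure variance explained by the instruments.
#' @param or_alternative Odds ratio under the alternative (> 0).
#' @param alpha Two-sided significance level; default 0.05.
#' @return Power in (0, 1).
#' @examples
#' mr_power_binary(463456, 9006 / 463456, 0.15, 1.2)
#' @export
mr_power_binary <- function(n, case_fraction, r2_explained, or_alternative,
                            alpha = 0.05) {
  n <- check_count(n, "n")
  check_number(case_fraction, "case_fraction", 0, 1, open_lower = TRUE,
               open_upper = TRUE)
  check_number(r2_explained, "r2_explained", 0, 1, open_upper = TRUE)
  check_number(or_alternative, "or_alternative", 0, Inf, open_lower = TRUE)
  check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (or_alternative == 1) return(alpha)
  b <- log(or_alternative)
  zstar <- qnorm(1 - alpha / 2)
  lambda <- abs(b) * sqrt(n * r2_explained * case_fraction * (1 - case_fraction))
  pnorm(lambda - zstar) + pnorm(-lambda - zstar)
}

#' Instrument-set diagnostics
#'
#' Bundles the strength and power diagnostics reported alongside an MR
#' analysis: variance explained, regression F-statistic, and analytic power
#' for a stated detectable odds ratio.
#'
#' @param r2_explained Exposure variance explained by the instrument set.
#' @param n_exposure Exposure-study sample size.
#' @param k Instrument count.
#' @param n_outcome,case_fraction Outcome study size and case fraction for the
#'   power column (optional; power is `NA` when absent).
#' @param or_alternative Detectable odds ratio for the power column.
#' @param alpha Significance level.
#' @return One-row tibble: `r2_explained`, `n_exposure`, `k`, `f_statistic`,
#'   `power`.
#' @export
instrument_diagnostics <- function(r2_explained, n_exposure, k,
                                   n_outcome = NULL, case_fraction = NULL,
                                   or_alternative = 1.2, alpha = 0.05) {
  f <- instrument_f_statistic(r2_explained, n_exposure, k)
  pw <- if (!is.null(n_outcome) && !is.null(case_fraction)) {
    mr_power_binary(n_outcome, case_fraction, r2_explained, or_alternative,
                    alpha)
  } else NA_real_
  tibble::tibble(
    r2_explained = r2_explained, n_exposure = as.integer(n_exposure),
    k = as.integer(k), f_statistic = f, power = pw
  )
}
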