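#' Bonferroni-corrected significance threshold for an exposure-outcome grid
#'
#' `alpha / (n_exposures * n_outcomes)`. For seven exposures and five
#' outcomes at alpha 0.05 this is 0.05/35 = 0.00142 (3 s.f.), the threshold
#' separating significant from suggestive associations.
#'
#' @param n_exposures,n_outcomes Positive test-grid dimensions.
#' @param alpha Family-wise level; default 0.05.
#' @return The corrected threshold.
#' @examples
#' bonferroni_threshold(7, 5)
#' @export
bonferroni_threshold <- function(n_exposures, n_outcomes, alpha = 0.05) {
  n_exposures <- check_count(n_exposures, "n_exposures")
  n_outcomes <- check_count(n_outcomes, "n_outcomes")
  check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  alpha / (n_exposures * n_outcomes)
}

#' Classify an association p-value
#'
#' `"significant"` when `p < threshold`; `"suggestive"` when
#' `threshold <= p < alpha`; `"null"` otherwise. Vectorized over `p`.
#'
#' @param p P-value(s) in (0, 1].
#' @param threshold Multiple-testing-corrected threshold (below `alpha`).
#' @param alpha Nominal level; default 0.05.
#' @return Character vector of categories.
#' @export
classify_association <- function(p, threshold, alpha = 0.05) {
  check_number(threshold, "threshold", 0, alpha, open_lower = TRUE,
               open_upper = TRUE)
  check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop_domain("`p` must lie in (0, 1].")
  }
  dplyr::case_when(
    p < threshold ~ "significant",
    p < alpha ~ "suggestive",
    TRUE ~ "null"
  )
}

#' Convert a log-odds estimate to an odds ratio on a stated contrast
#'
#' Exponentiates `factor * beta` with a Wald confidence interval, reporting
#' the effect per `factor` units of genetically predicted increase in the
#' exposure (e.g. `factor = 10` for "per 10 units").
#'
#' @param beta,se Log-odds estimate and standard error (vectorized).
#' @param factor Units of exposure per reported contrast; default 1.
#' @param level Confidence level; default 0.95.
#' @return Tibble with `or`, `ci_low`, `ci_high`.
#' @export
scale_estimate <- function(beta, se, factor = 1, level = 0.95) {
  check_number(level, "level", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (any(!is.finite(se) | se <= 0)) stop_domain("`se` must be positive.")
  if (any(!is.finite(factor) | factor <= 0)) {
    stop_domain("`factor` must be positive.")
  }
  zstar <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    or = exp(factor * beta),
    ci_low = exp(factor * (beta - zstar * se)),
    ci_high = exp(factor * (beta + zstar * se))
  )
}

#' Attach odds ratios and multiple-testing verdicts to MR estimates
#'
#' Scales each estimate to an odds ratio (per-exposure scale factors
#' supported) and classifies its p-value against the corrected and nominal
#' thresholds.
#'
#' @param estimates An `mr_estimate` tibble (one or more methods and pairs).
#' @param threshold Corrected significance threshold (see
#'   [bonferroni_threshold()]).
#' @param alpha Nominal level; default 0.05.
#' @param scale_factor Single number, or named vector keyed by exposure label,
#'   of exposure units per reported contrast; default 1.
#' @param level Confidence level for the ORs.
#' @return Tibble of verdicts: the estimate columns plus `scale_factor`,
#'   `or`, `ci_low`, `ci_high`, `category`, `threshold_significant`,
#'   `threshold_suggestive`.
#' @export
classify_estimates <- function(estimates, threshold, alpha = 0.05,
                               scale_factor = 1, level = 0.95) {
  check_assoc_table(estimates, "estimates",
                    c("exposure", "outcome", "method", "beta", "se", "p_value"))
  sf <- if (!is.null(names(scale_factor))) {
    got <- scale_factor[estimates$exposure]
    if (anyNA(got)) {
      stop_domain("`scale_factor` lacks an entry for some exposure.")
    }
    unname(got)
  } else {
    rep_len(scale_factor, nrow(estimates))
  }
  sc <- scale_estimate(estimates$beta, estimates$se, sf, level)
  dplyr::bind_cols(
    tibble::as_tibble(estimates),
    tibble::tibble(scale_factor = sf), sc,
    tibble::tibble(
      category = classify_association(estimates$p_value, threshold, alpha),
      threshold_significant = threshold,
      threshold_suggestive = alpha
    )
  )
}

format_scientific <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(NA_character_)
    if (v == 0) return("0")
    if (abs(v) >= 1e-3 && abs(v) < 1e4) return(formatC(v, digits = 3, format = "fg", flag = "#"))
    e <- floor(log10(abs(v)))
    m <- v / 10^e
    sprintf("%.2f × 10^%d", m, e)
  }, character(1))
}

method_rank <- c(
  ivw_random = 1, ivw_fixed = 1, wald_ratio = 1, egger_slope = 2,
  weighted_median = 3, simple_median = 4, egger_intercept = 5
)

#' Assemble the results bundle for an analysis grid
#'
#' Produces a deterministic, order-independent results table and a
#' human-readable text report from a verdict table ([classify_estimates()])
#' and optional sensitivity outputs. Rows are ordered by exposure
#' (alphabetical), then outcome in the supplied canonical order (for stroke
#' subtypes, e.g. any stroke, any ischemic stroke, large-artery, cardioembolic,
#' small-vessel), then method (primary IVW first). Pairs with too few
#' instruments for sensitivity analyses are annotated
#' `"NA (insufficient instruments)"`.
#'
#' @param verdicts Verdict tibble from [classify_estimates()].
#' @param sensitivity Optional list with elements `pleiotropy` (tibble with
#'   `exposure`, `outcome`, `intercept`, `intercept_se`, `intercept_p`) and
#'   `leave_one_out` (tibble with `exposure`, `outcome` plus the
#'   [leave_one_out()] columns).
#' @param outcome_order Character vector giving the canonical outcome order;
#'   outcomes not listed sort alphabetically after it.
#' @return An `mr_report`: list with `table` (tibble), `sensitivity` (list),
#'   and `text` (character lines).
#' @export
compile_report <- function(verdicts, sensitivity = NULL, outcome_order = NULL) {
  check_assoc_table(verdicts, "verdicts",
                    c("exposure", "outcome", "method", "k", "beta", "se",
                      "p_value", "or", "ci_low", "ci_high", "category"))
  if (nrow(verdicts) == 0L) stop_domain("Need at least one verdict.")
  out_rank <- function(o) {
    r <- match(o, outcome_order %||% character())
    ifelse(is.na(r), length(outcome_order %||% character()) + 1L, r)
  }
  tb <- tibble::as_tibble(verdicts)
  tb <- tb[order(tb$exposure, out_rank(tb$outcome), tb$outcome,
                 method_rank[tb$method], tb$method), , drop = FALSE]

  lines <- character(0)
  pairs <- dplyr::distinct(tb, .data$exposure, .data$outcome)
  for (i in seq_len(nrow(pairs))) {
    ex <- pairs$exposure[i]
    oc <- pairs$outcome[i]
    sub <- tb[tb$exposure == ex & tb$outcome == oc &
                tb$method != "egger_intercept", , drop = FALSE]
    lines <- c(lines, sprintf("== %s -> %s ==", ex, oc))
    for (j in seq_len(nrow(sub))) {
      r <- sub[j, ]
      lines <- c(lines, sprintf(
        "  %-16s k=%-4d OR %s (95%% CI %s-%s)  p = %s  [%s]",
        r$method, r$k, format_scientific(r$or), format_scientific(r$ci_low),
        format_scientific(r$ci_high), format_scientific(r$p_value), r$category
      ))
    }
    pl <- NULL
    if (!is.null(sensitivity$pleiotropy)) {
      pl <- sensitivity$pleiotropy
      pl <- pl[pl$exposure == ex & pl$outcome == oc, , drop = FALSE]
    }
    if (!is.null(pl) && nrow(pl) == 1L) {
      lines <- c(lines, sprintf(
        "  pleiotropy: intercept = %s, p = %s",
        format_scientific(pl$intercept), format_scientific(pl$intercept_p)
      ))
    } else {
      lines <- c(lines, "  pleiotropy: NA (insufficient instruments)")
    }
    if (!is.null(sensitivity$leave_one_out)) {
      lo <- sensitivity$leave_one_out
      lo <- lo[lo$exposure == ex & lo$outcome == oc, , drop = FALSE]
      if (nrow(lo)) {
        flagged <- lo$omitted_variant[lo$classification_changed]
        lines <- c(lines, if (length(flagged)) {
          sprintf("  leave-one-out: %d variant(s) change the verdict: %s",
                  length(flagged), paste(sort(flagged), collapse = ", "))
        } else {
          "  leave-one-out: no single variant changes the verdict"
        })
      }
    }
  }

  structure(list(table = tb, sensitivity = sensitivity, text = lines),
            class = "mr_report")
}

#' Write an assembled report to disk
#'
#' Writes `estimates.tsv`, `report.txt`, and when present
#' `sensitivity_loo.tsv` and `sensitivity_pleiotropy.tsv`, under `dir`.
#'
#' @param report An `mr_report` from [compile_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mr_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$table, file.path(dir, "estimates.tsv"))
  writeLines(report$text, file.path(dir, "report.txt"))
  if (!is.null(report$sensitivity$leave_one_out)) {
    readr::write_tsv(tibble::as_tibble(report$sensitivity$leave_one_out),
                     file.path(dir, "sensitivity_loo.tsv"))
  }
  if (!is.null(report$sensitivity$pleiotropy)) {
    readr::write_tsv(tibble::as_tibble(report$sensitivity$pleiotropy),
                     file.path(dir, "sensitivity_pleiotropy.tsv"))
  }
  invisible(dir)
}

#' @export
print.mr_report <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}
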