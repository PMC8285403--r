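#' Tidy an MR estimate table
#'
#' Broom-style view of one or more causal estimates: one row per method with
#' `term`, `estimate`, `std.error`, `statistic`, `p.value` and Wald confidence
#' bounds on the log-odds scale.
#'
#' @param x An `mr_estimate` tibble.
#' @param conf.level Confidence level; default 0.95.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mr_estimate <- function(x, conf.level = 0.95, ...) {
  zstar <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome, term = x$method,
    estimate = x$beta, std.error = x$se, statistic = x$beta / x$se,
    p.value = x$p_value, conf.low = x$beta - zstar * x$se,
    conf.high = x$beta + zstar * x$se, k = x$k
  )
}

#' Glance at an MR estimate table
#'
#' @param x An `mr_estimate` tibble.
#' @param ... Unused.
#' @return One-row tibble: instrument count, number of methods, and the
#'   primary (IVW) estimate when present.
#' @export
glance.mr_estimate <- function(x, ...) {
  ivw <- x[x$method %in% c("ivw_random", "ivw_fixed"), , drop = FALSE]
  tibble::tibble(
    k = max(x$k), n_methods = length(unique(x$method)),
    beta_ivw = if (nrow(ivw)) ivw$beta[1] else NA_real_,
    p_ivw = if (nrow(ivw)) ivw$p_value[1] else NA_real_
  )
}

#' Glance at a harmonized instrument set
#'
#' @param x An `mr_harmonized` tibble.
#' @param ... Unused.
#' @return One-row tibble of instrument counts by harmonization status and
#'   the number dropped.
#' @export
glance.mr_harmonized <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  tibble::tibble(
    exposure = attr(x, "exposure_label"), outcome = attr(x, "outcome_label"),
    k = nrow(tb),
    n_direct = sum(tb$status == "direct"),
    n_flipped = sum(tb$status == "allele_flipped"),
    n_palindromic_inferred = sum(tb$status == "palindromic_inferred"),
    n_proxy = sum(tb$status == "proxy"),
    n_dropped = nrow(attr(x, "dropped"))
  )
}

#' Forest-style plot of MR estimates
#'
#' Odds ratios with Wald confidence intervals, one row per method (the Egger
#' intercept, which is not an odds ratio, is omitted).
#'
#' @param object An `mr_estimate` tibble.
#' @param scale_factor Exposure units per contrast; default 1.
#' @param conf.level Confidence level; default 0.95.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_estimate <- function(object, scale_factor = 1, conf.level = 0.95,
                                 ...) {
  tb <- tibble::as_tibble(object)
  tb <- tb[tb$method != "egger_intercept", , drop = FALSE]
  sc <- scale_estimate(tb$beta, tb$se, scale_factor, conf.level)
  dat <- dplyr::bind_cols(tb, sc)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = sprintf("OR per %g unit(s) of exposure", scale_factor),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a harmonized instrument set
#'
#' Per-variant outcome effects against exposure effects with error bars and
#' the IVW (through-origin) and Egger fits overlaid when estimable.
#'
#' @param object An `mr_harmonized` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_harmonized <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$beta_exposure,
                                        y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_outcome - .data$se_outcome,
      ymax = .data$beta_outcome + .data$se_outcome
    ), width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome") +
    ggplot2::theme_minimal()
  if (nrow(tb) >= 1L) {
    ivw <- mr_ivw(object, model = if (nrow(tb) >= 2L) "random" else "fixed")
    p <- p + ggplot2::geom_abline(slope = ivw$beta, intercept = 0,
                                  colour = "steelblue")
  }
  if (nrow(tb) >= 3L) {
    eg <- mr_egger(object)
    p <- p + ggplot2::geom_abline(
      slope = eg$beta[eg$method == "egger_slope"],
      intercept = eg$beta[eg$method == "egger_intercept"],
      colour = "firebrick", linetype = "dotdash"
    )
  }
  p
}

#' Leave-one-out influence plot
#'
#' One row per omitted variant: the IVW estimate on the remaining
#' instruments, with the full-set estimate as a reference line; variants
#' whose omission changes the significance verdict are highlighted.
#'
#' @param object An `mr_loo` tibble from [leave_one_out()].
#' @param conf.level Confidence level; default 0.95.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_loo <- function(object, conf.level = 0.95, ...) {
  tb <- tibble::as_tibble(object)
  zstar <- qnorm(1 - (1 - conf.level) / 2)
  full <- attr(object, "full_estimate")
  ggplot2::ggplot(tb, ggplot2::aes(
    x = .data$beta, y = stats::reorder(.data$omitted_variant, .data$beta),
    colour = .data$classification_changed
  )) +
    ggplot2::geom_vline(xintercept = full$beta, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$beta - zstar * .data$se,
      xmax = .data$beta + zstar * .data$se
    )) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "black", `TRUE` = "firebrick"),
      name = "verdict changes"
    ) +
    ggplot2::labs(x = "IVW estimate omitting the variant", y = NULL) +
    ggplot2::theme_minimal()
}
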