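new_mr_estimate <- function(method, beta, se, p_value, k,
                            exposure = "exposure", outcome = "outcome") {
  structure(
    tibble::tibble(
      exposure = exposure, outcome = outcome, method = method,
      k = as.integer(k), beta = beta, se = se, p_value = p_value
    ),
    class = c("mr_estimate", class(tibble::tibble()))
  )
}

labels_of <- function(data) {
  c(attr(data, "exposure_label") %||% "exposure",
    attr(data, "outcome_label") %||% "outcome")
}

check_harmonized_cols <- function(data) {
  check_assoc_table(
    data, "data",
    c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  )
  if (any(data$se_outcome <= 0) || any(data$se_exposure <= 0)) {
    stop_domain("Standard errors must be positive.")
  }
  invisible(data)
}

#' Wald ratio: per-variant causal estimate
#'
#' The single-instrument causal estimate `by/bx` with either the first-order
#' delta-method standard error `sy/|bx|` (which ignores uncertainty in the
#' exposure effect) or the second-order expansion
#' `sqrt(sy^2/bx^2 + by^2 sx^2 / bx^4)`.
#'
#' @param bx,sx Exposure effect and standard error (`bx` must be nonzero).
#' @param by,sy Outcome effect and standard error.
#' @param se_order `"first"` (default) or `"second"`.
#' @return An `mr_estimate` tibble (one row, method `"wald_ratio"`).
#' @export
mr_wald_ratio <- function(bx, sx, by, sy, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  check_number(bx, "bx")
  check_number(sx, "sx", 0, Inf, open_lower = TRUE)
  check_number(by, "by")
  check_number(sy, "sy", 0, Inf, open_lower = TRUE)
  if (bx == 0) stop_domain("Wald ratio undefined: `bx` = 0.")
  beta <- by / bx
  se <- if (se_order == "first") {
    sy / abs(bx)
  } else {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  }
  new_mr_estimate("wald_ratio", beta, se, wald_p(beta, se), 1L)
}

#' Inverse-variance weighted (IVW) causal estimate
#'
#' Combines per-variant Wald ratios with inverse-variance weights; equivalent
#' to a weighted through-origin regression of the outcome effects on the
#' exposure effects with weights `1/se_outcome^2`:
#' `beta = sum(bx by / sy^2) / sum(bx^2 / sy^2)`. The fixed-effect standard
#' error is `1/sqrt(sum(bx^2/sy^2))`; the multiplicative random-effects model
#' (default) inflates it by `max(1, sqrt(Q/(k-1)))` where `Q` is the weighted
#' residual sum of squares of the through-origin fit, so it never falls below
#' the fixed-effect value. With a single instrument the estimate equals the
#' first-order Wald ratio.
#'
#' @param data Harmonized instrument set ([harmonize()] output, or any data
#'   frame with `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`).
#' @param model `"random"` (default) or `"fixed"`.
#' @return An `mr_estimate` tibble (one row).
#' @export
mr_ivw <- function(data, model = c("random", "fixed")) {
  model <- match.arg(model)
  check_harmonized_cols(data)
  k <- nrow(data)
  if (k < 1L) stop_insufficient("IVW needs at least 1 instrument.")
  if (model == "random" && k < 2L) {
    stop_domain("Random-effects IVW needs at least 2 instruments.")
  }
  bx <- data$beta_exposure
  by <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  denom <- sum(w * bx^2)
  if (denom == 0) stop_domain("All exposure effects are zero.")
  beta <- sum(w * bx * by) / denom
  se <- 1 / sqrt(denom)
  method <- "ivw_fixed"
  if (model == "random") {
    q <- sum(w * (by - beta * bx)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
    method <- "ivw_random"
  }
  lab <- labels_of(data)
  new_mr_estimate(method, beta, se, wald_p(beta, se), k, lab[1], lab[2])
}

#' MR-Egger regression: causal slope and pleiotropy intercept
#'
#' Weighted regression of outcome effects on exposure effects with an
#' unconstrained intercept (weights `1/se_outcome^2`), after recoding the
#' exposure orientation so every exposure effect is nonnegative. The slope is
#' the causal estimate under the InSIDE assumption; the intercept estimates
#' the average directional pleiotropic effect, and its test is the standard
#' directional-pleiotropy diagnostic. Standard errors are the weighted-fit
#' errors inflated by `max(1, sqrt(RSS/(k-2)))`; p-values use a t reference
#' with `k - 2` degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` tibble with two rows: methods `"egger_slope"` and
#'   `"egger_intercept"`.
#' @export
mr_egger <- function(data) {
  check_harmonized_cols(data)
  k <- nrow(data)
  if (k < 3L) stop_insufficient("MR-Egger needs at least 3 instruments.")
  flip <- sign(data$beta_exposure)
  flip[flip == 0] <- 1
  bx <- data$beta_exposure * flip
  by <- data$beta_outcome * flip
  if (length(unique(bx)) == 1L) {
    abort("All exposure effects identical: Egger slope unidentifiable.",
          class = "cardiomr_error_degenerate_design")
  }
  w <- 1 / data$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma                     # sqrt(weighted RSS / (k - 2))
  se_unscaled <- sm$coefficients[, "Std. Error"] / sigma
  se <- se_unscaled * max(1, sigma)
  est <- coef(fit)
  pv <- 2 * pt(-abs(est / se), df = k - 2)
  lab <- labels_of(data)
  new_mr_estimate(
    c("egger_slope", "egger_intercept"),
    beta = c(est[["bx"]], est[["(Intercept)"]]),
    se = c(se[["bx"]], se[["(Intercept)"]]),
    p_value = c(pv[["bx"]], pv[["(Intercept)"]]),
    k = k, exposure = lab[1], outcome = lab[2]
  )
}

#' Median-based causal estimates with parametric-bootstrap standard errors
#'
#' Computes the simple or weighted median of the per-variant Wald ratios.
#' Ratios are sorted ascending; with normalized weights `w_j` (all equal for
#' the simple median, `bx_j^2/sy_j^2` for the weighted median) the estimate
#' interpolates linearly between the two ratios whose standardized cumulative
#' weights `p_j = cumsum(w)_j - w_j/2` bracket 1/2. The weighted median is
#' consistent when valid instruments contribute at least half the weight.
#' The standard error is a parametric bootstrap: exposure and outcome effects
#' are resampled from normal distributions centred on their estimates,
#' the median recomputed `n_boot` times, and the bootstrap standard deviation
#' reported; the p-value is a two-sided normal test.
#'
#' @inheritParams mr_ivw
#' @param weighting `"weighted"` (default) or `"simple"`.
#' @param n_boot Bootstrap replicates; default 1000.
#' @param seed Integer seed for the bootstrap (mandatory, so results are
#'   reproducible); the global RNG state is left untouched.
#' @return An `mr_estimate` tibble (one row, method `"weighted_median"` or
#'   `"simple_median"`).
#' @export
mr_median <- function(data, weighting = c("weighted", "simple"),
                      n_boot = 1000, seed) {
  weighting <- match.arg(weighting)
  check_harmonized_cols(data)
  if (missing(seed)) stop_domain("`seed` is required for the median bootstrap.")
  n_boot <- check_count(n_boot, "n_boot")
  k <- nrow(data)
  if (k < 3L) stop_insufficient("Median estimators need at least 3 instruments.")
  if (any(data$beta_exposure == 0)) {
    stop_domain("Median estimator undefined when an exposure effect is 0.")
  }
  bx <- data$beta_exposure
  by <- data$beta_outcome
  sx <- data$se_exposure
  sy <- data$se_outcome

  point_of <- function(bx_i, by_i) {
    r <- by_i / bx_i
    w <- if (weighting == "simple") rep(1, k) else bx_i^2 / sy^2
    weighted_median(r, w)
  }
  beta <- point_of(bx, by)

  boots <- with_local_seed(seed, {
    bxm <- matrix(rnorm(n_boot * k, mean = rep(bx, each = n_boot),
                        sd = rep(sx, each = n_boot)), nrow = n_boot)
    bym <- matrix(rnorm(n_boot * k, mean = rep(by, each = n_boot),
                        sd = rep(sy, each = n_boot)), nrow = n_boot)
    vapply(seq_len(n_boot),
           function(i) point_of(bxm[i, ], bym[i, ]), numeric(1))
  })
  se <- sd(boots)
  lab <- labels_of(data)
  new_mr_estimate(
    if (weighting == "weighted") "weighted_median" else "simple_median",
    beta, se, wald_p(beta, se), k, lab[1], lab[2]
  )
}

#' Run the full estimator battery on a harmonized set
#'
#' Convenience wrapper returning IVW (primary), MR-Egger slope and intercept,
#' and the weighted and simple medians as one stacked `mr_estimate` tibble.
#' Methods whose instrument-count requirements are not met are omitted.
#'
#' @inheritParams mr_ivw
#' @param n_boot,seed Passed to [mr_median()].
#' @return An `mr_estimate` tibble, one row per method.
#' @export
mr_estimates <- function(data, model = c("random", "fixed"), n_boot = 1000,
                         seed) {
  model <- match.arg(model)
  check_harmonized_cols(data)
  k <- nrow(data)
  out <- list()
  if (k >= 1L) {
    out$ivw <- mr_ivw(data, model = if (k >= 2L) model else "fixed")
  }
  if (k >= 3L) {
    out$egger <- mr_egger(data)
    out$wmed <- mr_median(data, "weighted", n_boot = n_boot, seed = seed)
    out$smed <- mr_median(data, "simple", n_boot = n_boot, seed = seed + 1L)
  }
  res <- dplyr::bind_rows(out)
  structure(res, class = c("mr_estimate", class(tibble::tibble())))
}
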