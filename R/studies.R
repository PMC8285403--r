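# Replicated simulation studies used to check the statistical guarantees of
# the estimators. Each returns its summary as a tibble; all randomness flows
# from the `seed` argument. The studies bypass the allele-encoding layer
# (palindromic/swap fractions set to 0 and the harmonized table built
# directly), since encoding round-trips are checked separately and the
# questions here are purely statistical.

study_scenario <- function(cf) {
  sim <- generate_dataset(cf)
  tibble::tibble(
    beta_exposure = sim$exposure$beta, se_exposure = sim$exposure$se,
    beta_outcome = sim$outcome$beta, se_outcome = sim$outcome$se
  )
}

#' Confidence-interval coverage of the MR estimators
#'
#' Simulates replicate datasets with strong instruments and no pleiotropy and
#' reports, for each estimator, the fraction of replicates whose 95% Wald
#' interval covers the true causal effect. Nominal behaviour is coverage near
#' 0.95 for all four estimators.
#'
#' @param n_rep Number of replicate datasets; default 500.
#' @param seed Integer seed.
#' @param k Instruments per replicate; default 100.
#' @param true_beta True causal effect; default 0.2.
#' @param n_boot Bootstrap replicates inside each median estimator;
#'   default 300.
#' @param level Confidence level; default 0.95.
#' @return Tibble with `method`, `coverage`, `n_rep`.
#' @export
study_coverage <- function(n_rep = 500, seed, k = 100, true_beta = 0.2,
                           n_boot = 300, level = 0.95) {
  if (missing(seed)) stop_domain("`seed` is required.")
  n_rep <- check_count(n_rep, "n_rep")
  zstar <- qnorm(1 - (1 - level) / 2)
  methods <- c("ivw_random", "egger_slope", "weighted_median", "simple_median")
  hits <- setNames(numeric(length(methods)), methods)
  for (r in seq_len(n_rep)) {
    cf <- sim_config(
      n_variants = k, true_beta = true_beta, pleiotropy_mode = "none",
      palindromic_fraction = 0, allele_swap_fraction = 0,
      seed = seed + r
    )
    dat <- study_scenario(cf)
    est <- dplyr::bind_rows(
      mr_ivw(dat, model = "random"),
      mr_egger(dat),
      mr_median(dat, "weighted", n_boot = n_boot, seed = seed + r),
      mr_median(dat, "simple", n_boot = n_boot, seed = seed + n_rep + r)
    )
    est <- est[est$method %in% methods, , drop = FALSE]
    cover <- abs(est$beta - true_beta) <= zstar * est$se
    hits[est$method] <- hits[est$method] + cover
  }
  tibble::tibble(method = methods, coverage = unname(hits) / n_rep,
                 n_rep = n_rep)
}

#' Calibration and recovery of the MR-Egger intercept test
#'
#' With `pleiotropy_mean = 0` and mode `"none"` this measures the type-I
#' error of the directional-pleiotropy test at `alpha` (nominally 0.05);
#' with a directional mean it measures how well the average injected direct
#' effect is recovered by the mean intercept estimate. The exposure GWAS is
#' taken large (n = 500,000) so instrument effects are essentially noise-free
#' and the test's calibration is assessed under its own assumptions.
#'
#' @param n_rep Number of replicates.
#' @param seed Integer seed.
#' @param k Instruments per replicate; default 100.
#' @param pleiotropy_mean Mean direct effect; 0 for the null.
#' @param pleiotropy_sd Spread of direct effects; default 0.01 when a mean is
#'   injected, 0 otherwise.
#' @param alpha Test level; default 0.05.
#' @return One-row tibble: `rejection_rate`, `mean_intercept`, `n_rep`.
#' @export
study_egger_calibration <- function(n_rep, seed, k = 100, pleiotropy_mean = 0,
                                    pleiotropy_sd = if (pleiotropy_mean == 0) 0 else 0.01,
                                    alpha = 0.05) {
  if (missing(seed)) stop_domain("`seed` is required.")
  n_rep <- check_count(n_rep, "n_rep")
  mode <- if (pleiotropy_mean == 0 && pleiotropy_sd == 0) "none" else "directional"
  rej <- 0
  intercepts <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cf <- sim_config(
      n_variants = k, n_exposure = 500000, pleiotropy_mode = mode,
      pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
      palindromic_fraction = 0, allele_swap_fraction = 0,
      seed = seed + r
    )
    pr <- pleiotropy_report(study_scenario(cf))
    rej <- rej + (pr$intercept_p < alpha)
    intercepts[r] <- pr$intercept
  }
  tibble::tibble(rejection_rate = rej / n_rep,
                 mean_intercept = mean(intercepts), n_rep = n_rep)
}

#' Bias of IVW versus the weighted median under partial directional pleiotropy
#'
#' Gives 30% of instruments a directional (positive-mean) direct effect and
#' compares the average bias of the IVW estimate with that of the weighted
#' median, which is consistent while valid instruments hold a majority of the
#' weight. A continuous outcome with a large GWAS is used so per-variant
#' ratios are precise and the contrast is between the estimators, not the
#' noise.
#'
#' @param n_rep Number of replicates; default 200.
#' @param seed Integer seed.
#' @param k Instruments per replicate; default 100.
#' @param invalid_fraction Fraction of pleiotropic instruments; default 0.3.
#' @param pleiotropy_mean Mean direct effect among invalid instruments;
#'   default 0.02.
#' @param true_beta True causal effect; default 0.2.
#' @return One-row tibble: `bias_ivw`, `bias_weighted_median`, `n_rep`.
#' @export
study_median_robustness <- function(n_rep = 200, seed, k = 100,
                                    invalid_fraction = 0.3,
                                    pleiotropy_mean = 0.02, true_beta = 0.2) {
  if (missing(seed)) stop_domain("`seed` is required.")
  n_rep <- check_count(n_rep, "n_rep")
  b_ivw <- b_wm <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cf <- sim_config(
      n_variants = k, true_beta = true_beta,
      pleiotropy_mode = "directional", pleiotropy_mean = pleiotropy_mean,
      pleiotropy_sd = pleiotropy_mean / 2,
      pleiotropy_fraction = invalid_fraction,
      outcome_case_fraction = NULL,
      palindromic_fraction = 0, allele_swap_fraction = 0,
      seed = seed + r
    )
    dat <- study_scenario(cf)
    b_ivw[r] <- mr_ivw(dat, model = "random")$beta - true_beta
    b_wm[r] <- mr_median(dat, "weighted", n_boot = 1,
                         seed = seed + r)$beta - true_beta
  }
  tibble::tibble(bias_ivw = mean(b_ivw), bias_weighted_median = mean(b_wm),
                 n_rep = n_rep)
}

#' Monte-Carlo check of the analytic binary-outcome power formula
#'
#' Runs replicate IVW analyses at a stated scenario and compares the
#' empirical rejection rate of the IVW z-test with [mr_power_binary()]. The
#' exposure GWAS is taken large so the analytic formula's assumption of
#' noise-free instrument effects holds.
#'
#' @param n_rep Replicates; default 2000.
#' @param seed Integer seed.
#' @param n Outcome-study sample size; default 50000.
#' @param case_fraction Outcome case fraction; default 0.1.
#' @param r2_explained Exposure variance explained; default 0.05.
#' @param or_alternative True odds ratio; default 1.2.
#' @param k Instruments; default 20.
#' @param alpha Test level; default 0.05.
#' @return One-row tibble: `power_analytic`, `power_monte_carlo`, `n_rep`.
#' @export
study_power_mc <- function(n_rep = 2000, seed, n = 50000, case_fraction = 0.1,
                           r2_explained = 0.05, or_alternative = 1.2, k = 20,
                           alpha = 0.05) {
  if (missing(seed)) stop_domain("`seed` is required.")
  n_rep <- check_count(n_rep, "n_rep")
  analytic <- mr_power_binary(n, case_fraction, r2_explained, or_alternative,
                              alpha)
  zstar <- qnorm(1 - alpha / 2)
  rej <- 0
  for (r in seq_len(n_rep)) {
    cf <- sim_config(
      n_variants = k, n_exposure = 500000, n_outcome = n,
      outcome_case_fraction = case_fraction,
      true_beta = log(or_alternative), instrument_r2_total = r2_explained,
      pleiotropy_mode = "none", palindromic_fraction = 0,
      allele_swap_fraction = 0, seed = seed + r
    )
    est <- mr_ivw(study_scenario(cf), model = "fixed")
    rej <- rej + (abs(est$beta / est$se) > zstar)
  }
  tibble::tibble(power_analytic = analytic, power_monte_carlo = rej / n_rep,
                 n_rep = n_rep)
}
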