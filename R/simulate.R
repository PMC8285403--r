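#' Configuration for the synthetic GWAS summary-statistics generator
#'
#' Validates and completes the generator settings. Defaults mirror a
#' well-powered cardioembolic analysis: an exposure GWAS of 65,556
#' individuals with about 100 independent instruments jointly explaining 15%
#' of the exposure variance, and a binary-outcome GWAS of 463,456 individuals
#' at case fraction 9006/463,456 (cardioembolic-stroke scale).
#'
#' @param n_variants Number of instrument variants.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param true_beta True causal effect of the (standardized) exposure on the
#'   outcome, on the outcome's scale (log-odds for a binary outcome).
#' @param instrument_r2_total Exposure variance jointly explained by the
#'   variants, in (0, 1); split across variants and met exactly.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct effects) or
#'   `"directional"` (mean `pleiotropy_mean`).
#' @param pleiotropy_mean,pleiotropy_sd Location and spread of the direct
#'   (pleiotropic) outcome effects when the mode allows them.
#' @param pleiotropy_fraction Fraction of variants that receive a nonzero
#'   direct effect (selected at random); default 1 (all variants). Lets
#'   scenarios with a minority of invalid instruments be simulated.
#' @param maf_range Length-2 vector inside (0, 0.5]; minor-allele frequencies
#'   are drawn uniformly in this range.
#' @param palindromic_fraction Fraction of variants given A/T or C/G allele
#'   pairs.
#' @param allele_swap_fraction Fraction of variants whose outcome-file rows
#'   are re-encoded with swapped alleles and negated beta (exercises
#'   harmonization).
#' @param ld_block_sizes Integer vector of LD block sizes (assigned to the
#'   first `sum(ld_block_sizes)` variants); empty for fully independent
#'   variants.
#' @param within_block_r2 Pairwise r-squared inside each LD block, in \[0, 1).
#' @param outcome_case_fraction Case fraction of the binary outcome GWAS in
#'   (0, 1), used for the outcome standard errors; `NULL` for a continuous
#'   outcome.
#' @param seed Integer seed; required, all randomness flows from it.
#' @return A validated list of class `mr_sim_config`.
#' @export
sim_config <- function(n_variants = 100,
                       n_exposure = 65556,
                       n_outcome = 463456,
                       true_beta = 0.2,
                       instrument_r2_total = 0.15,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       pleiotropy_fraction = 1,
                       maf_range = c(0.05, 0.5),
                       palindromic_fraction = 0.15,
                       allele_swap_fraction = 0.3,
                       ld_block_sizes = integer(0),
                       within_block_r2 = 0.8,
                       outcome_case_fraction = 9006 / 463456,
                       seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) {
    abort("`seed` is required: the generator has no hidden randomness.",
          class = "cardiomr_error_config")
  }
  bad <- function(msg) abort(msg, class = "cardiomr_error_config")
  n_variants <- check_count(n_variants, "n_variants")
  n_exposure <- check_count(n_exposure, "n_exposure")
  n_outcome <- check_count(n_outcome, "n_outcome")
  check_number(true_beta, "true_beta")
  check_number(instrument_r2_total, "instrument_r2_total", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(pleiotropy_mean, "pleiotropy_mean")
  check_number(pleiotropy_sd, "pleiotropy_sd", 0, Inf)
  check_number(pleiotropy_fraction, "pleiotropy_fraction", 0, 1)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    bad("`maf_range` must be (low, high) within (0, 0.5].")
  }
  check_number(palindromic_fraction, "palindromic_fraction", 0, 1)
  check_number(allele_swap_fraction, "allele_swap_fraction", 0, 1)
  if (length(ld_block_sizes) &&
      (any(ld_block_sizes < 1) || sum(ld_block_sizes) > n_variants)) {
    bad("`ld_block_sizes` must be positive and sum to at most `n_variants`.")
  }
  check_number(within_block_r2, "within_block_r2", 0, 1, open_upper = TRUE)
  if (!is.null(outcome_case_fraction)) {
    check_number(outcome_case_fraction, "outcome_case_fraction", 0, 1,
                 open_lower = TRUE, open_upper = TRUE)
  }
  structure(
    list(
      n_variants = n_variants, n_exposure = n_exposure, n_outcome = n_outcome,
      true_beta = true_beta, instrument_r2_total = instrument_r2_total,
      pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
      pleiotropy_sd = pleiotropy_sd,
      pleiotropy_fraction = pleiotropy_fraction, maf_range = maf_range,
      palindromic_fraction = palindromic_fraction,
      allele_swap_fraction = allele_swap_fraction,
      ld_block_sizes = as.integer(ld_block_sizes),
      within_block_r2 = within_block_r2,
      outcome_case_fraction = outcome_case_fraction,
      seed = as.integer(seed)
    ),
    class = "mr_sim_config"
  )
}

#' Generate a synthetic two-sample MR dataset with known ground truth
#'
#' Simulates exposure and outcome GWAS summary statistics under the standard
#' two-sample MR data-generating model. Per variant `j`: a minor-allele
#' frequency `p_j` uniform in `maf_range`; a true exposure effect `gamma_j`
#' (positive, the effect allele being the exposure-increasing allele) with
#' magnitudes scaled so that `sum(2 p_j (1-p_j) gamma_j^2)` equals
#' `instrument_r2_total` exactly for a standardized exposure; a direct
#' (pleiotropic) outcome effect `alpha_j` of 0, `N(0, sd^2)` or
#' `N(mean, sd^2)` by mode; a true outcome effect
#' `Gamma_j = true_beta * gamma_j + alpha_j`. Observed effects are drawn as
#' `gamma_hat ~ N(gamma, se_x^2)` and `Gamma_hat ~ N(Gamma, se_y^2)` with
#' `se^2 = 1/(2 n p (1-p))` per study (times `1/(cf (1-cf))` for a binary
#' outcome at case fraction `cf`), and Wald p-values. Allele pairs are
#' palindromic for the configured fraction; the outcome file re-encodes the
#' configured fraction of variants with swapped alleles and negated betas so
#' harmonization is exercised. The LD reference is block-diagonal with
#' `within_block_r2` inside blocks. Identical seeds give identical output.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `mr_simulation`: `exposure` and `outcome`
#'   summary-statistics tibbles, `ld` (an [ld_reference()]), and `truth`
#'   (tibble `variant_id`, `maf`, `gamma`, `alpha` with attribute
#'   `true_beta`).
#' @examples
#' sim <- generate_dataset(sim_config(n_variants = 20, seed = 1))
#' h <- harmonize(sim$exposure, sim$outcome)
#' mr_ivw(h)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "mr_sim_config"))
  cf <- config
  with_local_seed(cf$seed, {
    n <- cf$n_variants
    ids <- sprintf("rs%06d", seq_len(n))
    maf <- runif(n, cf$maf_range[1], cf$maf_range[2])
    het <- 2 * maf * (1 - maf)

    u <- runif(n, 0.5, 1.5)
    gamma <- u * sqrt(cf$instrument_r2_total / sum(het * u^2))

    alpha <- switch(cf$pleiotropy_mode,
      none = rep(0, n),
      balanced = rnorm(n, 0, cf$pleiotropy_sd),
      directional = rnorm(n, cf$pleiotropy_mean, cf$pleiotropy_sd)
    )
    if (cf$pleiotropy_mode != "none" && cf$pleiotropy_fraction < 1) {
      off <- sample.int(n, n - round(cf$pleiotropy_fraction * n))
      alpha[off] <- 0
    }
    big_gamma <- cf$true_beta * gamma + alpha

    se_x <- sqrt(1 / (cf$n_exposure * het))
    se_y <- if (is.null(cf$outcome_case_fraction)) {
      sqrt(1 / (cf$n_outcome * het))
    } else {
      sqrt(1 / (cf$n_outcome * het * cf$outcome_case_fraction *
                  (1 - cf$outcome_case_fraction)))
    }
    bx <- rnorm(n, gamma, se_x)
    by <- rnorm(n, big_gamma, se_y)

    n_pal <- round(cf$palindromic_fraction * n)
    pal <- seq_len(n) %in% sample.int(n, n_pal)
    pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                        ncol = 2, byrow = TRUE)
    npal_pairs <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C",
                           "A", "C", "C", "A", "G", "T", "T", "G"),
                         ncol = 2, byrow = TRUE)
    ea <- oa <- character(n)
    pick_pal <- sample.int(nrow(pal_pairs), n, replace = TRUE)
    pick_npal <- sample.int(nrow(npal_pairs), n, replace = TRUE)
    ea[pal] <- pal_pairs[pick_pal[pal], 1]
    oa[pal] <- pal_pairs[pick_pal[pal], 2]
    ea[!pal] <- npal_pairs[pick_npal[!pal], 1]
    oa[!pal] <- npal_pairs[pick_npal[!pal], 2]

    # Two cohorts drawn from one population: frequencies agree up to small
    # sampling noise, which is what EAF-based palindrome inference relies on.
    eaf_x <- pmin(pmax(maf + rnorm(n, 0, 0.005), 0.001), 0.999)
    eaf_y <- pmin(pmax(maf + rnorm(n, 0, 0.005), 0.001), 0.999)

    exposure <- tibble::tibble(
      variant_id = ids, effect_allele = ea, other_allele = oa,
      beta = bx, se = se_x, p_value = wald_p(bx, se_x),
      eaf = eaf_x, n = cf$n_exposure
    )

    n_swap <- round(cf$allele_swap_fraction * n)
    swap <- seq_len(n) %in% sample.int(n, n_swap)
    outcome <- tibble::tibble(
      variant_id = ids,
      effect_allele = ifelse(swap, oa, ea),
      other_allele = ifelse(swap, ea, oa),
      beta = ifelse(swap, -by, by),
      se = se_y, p_value = wald_p(by, se_y),
      eaf = ifelse(swap, 1 - eaf_y, eaf_y),
      n = cf$n_outcome
    )

    pairs <- ld_block_pairs(ids, cf$ld_block_sizes, cf$within_block_r2)
    ld <- ld_reference(pairs, variant_ids = ids)

    truth <- tibble::tibble(variant_id = ids, maf = maf, gamma = gamma,
                            alpha = alpha)
    attr(truth, "true_beta") <- cf$true_beta

    structure(
      list(exposure = exposure, outcome = outcome, ld = ld, truth = truth,
           config = cf),
      class = "mr_simulation"
    )
  })
}

ld_block_pairs <- function(ids, block_sizes, r2) {
  if (!length(block_sizes) || r2 == 0) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          r2 = numeric()))
  }
  start <- cumsum(c(1L, head(block_sizes, -1L)))
  purrr::map2_dfr(start, block_sizes, function(s, len) {
    if (len < 2L) {
      return(tibble::tibble(id_a = character(), id_b = character(),
                            r2 = numeric()))
    }
    idx <- utils::combn(seq.int(s, s + len - 1L), 2)
    tibble::tibble(id_a = ids[idx[1, ]], id_b = ids[idx[2, ]], r2 = r2)
  })
}

#' Realized variance explained by the true exposure effects
#'
#' `sum(2 p_j (1 - p_j) gamma_j^2)` for a standardized exposure; by the
#' generator's exact scaling this equals the configured
#' `instrument_r2_total` up to floating-point error.
#'
#' @param truth Truth tibble from [generate_dataset()] (needs `gamma`), or a
#'   numeric vector of true per-variant effects.
#' @param mafs Minor-allele frequencies, same length.
#' @return The realized r-squared.
#' @export
realized_r2 <- function(truth, mafs) {
  gamma <- if (is.data.frame(truth)) truth$gamma else truth
  if (length(gamma) != length(mafs)) {
    stop_domain("`truth` and `mafs` lengths differ.")
  }
  if (any(mafs <= 0 | mafs >= 1)) stop_domain("`mafs` must lie in (0, 1).")
  sum(2 * mafs * (1 - mafs) * gamma^2)
}

#' Write a simulated dataset to TSV files
#'
#' Writes `exposure.tsv`, `outcome.tsv`, `ld.tsv` (long format) and
#' `truth.tsv` under `dir`, in the same dialects the pipeline reads back.
#'
#' @param sim An `mr_simulation` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mr_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- sim$exposure
  names(ex)[names(ex) == "se"] <- "standard_error"
  names(ex)[names(ex) == "eaf"] <- "effect_allele_frequency"
  oc <- sim$outcome
  names(oc)[names(oc) == "se"] <- "standard_error"
  names(oc)[names(oc) == "eaf"] <- "effect_allele_frequency"
  readr::write_tsv(ex, file.path(dir, "exposure.tsv"))
  readr::write_tsv(oc, file.path(dir, "outcome.tsv"))
  m <- sim$ld$r2
  up <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  readr::write_tsv(
    tibble::tibble(id_a = sim$ld$ids[up[, 1]], id_b = sim$ld$ids[up[, 2]],
                   r2 = m[up]),
    file.path(dir, "ld.tsv")
  )
  tr <- sim$truth
  tr$true_beta <- attr(sim$truth, "true_beta")
  readr::write_tsv(tr, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @export
print.mr_simulation <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    paste0("<mr_simulation> %d variant(s); true beta %.3g; r2 %.3g; ",
           "pleiotropy %s; seed %d\n"),
    cf$n_variants, cf$true_beta, cf$instrument_r2_total, cf$pleiotropy_mode,
    cf$seed
  ))
  invisible(x)
}
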