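# Builders for small in-code fixtures shared across test files.

make_assoc <- function(variant_id, effect_allele, other_allele, beta, se,
                       p_value = NULL, eaf = NA_real_, n = NA_real_) {
  tibble::tibble(
    variant_id = variant_id, effect_allele = effect_allele,
    other_allele = other_allele, beta = beta, se = se,
    p_value = p_value %||% (2 * stats::pnorm(-abs(beta / se))),
    eaf = eaf, n = n
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal harmonized-shaped table for exercising estimators directly.
make_harmonized <- function(bx, sx, by, sy, ids = NULL) {
  tibble::tibble(
    variant_id = ids %||% sprintf("rs%03d", seq_along(bx)),
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy
  )
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Closed-form weighted-least-squares oracles, via normal equations -- an
# independent route from the package's own algebra / lm() fits.
oracle_wls_origin <- function(bx, by, w) {
  beta <- solve(t(bx * w) %*% bx, t(bx * w) %*% by)[1, 1]
  se_fixed <- sqrt(solve(t(bx * w) %*% bx)[1, 1])
  q <- sum(w * (by - beta * bx)^2)
  list(beta = beta, se_fixed = se_fixed, q = q)
}

oracle_wls_intercept <- function(bx, by, w) {
  X <- cbind(1, bx)
  xtwx_inv <- solve(t(X) %*% (w * X))
  est <- xtwx_inv %*% t(X) %*% (w * by)
  rss <- sum(w * (by - X %*% est)^2)
  k <- length(bx)
  sigma2 <- rss / (k - 2)
  se_unscaled <- sqrt(diag(xtwx_inv))
  se <- unname(se_unscaled * max(1, sqrt(sigma2)))
  list(intercept = unname(est[1, 1]), slope = unname(est[2, 1]),
       se_intercept = se[1], se_slope = se[2])
}

# Harmonized tables drawn from the generator, post-harmonization.
sim_harmonized <- function(seed, n_variants = 30, ...) {
  sim <- generate_dataset(sim_config(n_variants = n_variants, seed = seed, ...))
  harmonize(sim$exposure, sim$outcome)
}
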