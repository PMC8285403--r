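test_that("Wald ratio arithmetic and delta-method standard errors", {
  e <- mr_wald_ratio(0.5, 0.05, 0.1, 0.02, se_order = "first")
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.04)
  # second-order expansion evaluated by hand:
  # sqrt(0.02^2/0.5^2 + 0.1^2 * 0.05^2 / 0.5^4) = sqrt(0.0016 + 0.0004)
  e2 <- mr_wald_ratio(0.5, 0.05, 0.1, 0.02, se_order = "second")
  expect_equal(e2$se, sqrt(0.002), tolerance = 1e-12)

  null <- mr_wald_ratio(0.5, 0.05, 0, 0.02)
  expect_equal(null$beta, 0)
  expect_equal(null$se, 0.04)
  expect_equal(null$p_value, 1)

  expect_error(mr_wald_ratio(0, 0.05, 0.1, 0.02),
               class = "cardiomr_error_domain")
})

test_that("IVW with one instrument reduces to the first-order Wald ratio", {
  dat <- make_harmonized(0.5, 0.05, 0.1, 0.02)
  ivw <- mr_ivw(dat, model = "fixed")
  wald <- mr_wald_ratio(0.5, 0.05, 0.1, 0.02, se_order = "first")
  expect_equal(ivw$beta, wald$beta, tolerance = 1e-15)
  expect_equal(ivw$se, wald$se, tolerance = 1e-15)
  expect_equal(ivw$p_value, wald$p_value, tolerance = 1e-15)
})

test_that("duplicating an instrument halves the IVW variance", {
  one <- make_harmonized(0.5, 0.05, 0.1, 0.02)
  two <- make_harmonized(c(0.5, 0.5), 0.05, c(0.1, 0.1), 0.02)
  e1 <- mr_ivw(one, model = "fixed")
  e2 <- mr_ivw(two, model = "fixed")
  expect_equal(e2$beta, e1$beta, tolerance = 1e-15)
  expect_equal(e2$se, e1$se / sqrt(2), tolerance = 1e-12)
})

test_that("IVW matches the closed-form weighted-least-squares oracle", {
  for (seed in 1:5) {
    h <- sim_harmonized(seed, n_variants = 20)
    w <- 1 / h$se_outcome^2
    oracle <- oracle_wls_origin(h$beta_exposure, h$beta_outcome, w)
    fixed <- mr_ivw(h, model = "fixed")
    expect_equal(fixed$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(fixed$se, oracle$se_fixed, tolerance = 1e-10)
    random <- mr_ivw(h, model = "random")
    k <- nrow(h)
    expect_equal(random$se,
                 oracle$se_fixed * max(1, sqrt(oracle$q / (k - 1))),
                 tolerance = 1e-10)
    expect_gte(random$se, fixed$se)
  }
})

test_that("IVW insufficiency and degeneracy are errors", {
  empty <- make_harmonized(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_error(mr_ivw(empty),
               class = "cardiomr_error_insufficient_instruments")
  expect_error(mr_ivw(make_harmonized(0.5, 0.05, 0.1, 0.02), model = "random"),
               class = "cardiomr_error_domain")
})

test_that("Egger recovers an exact line and matches the WLS oracle", {
  bx <- c(0.1, 0.2, 0.4)
  dat <- make_harmonized(bx, 0.01, 0.01 + 0.3 * bx, c(0.02, 0.01, 0.03))
  e <- mr_egger(dat)
  expect_equal(e$beta[e$method == "egger_slope"], 0.3, tolerance = 1e-12)
  expect_equal(e$beta[e$method == "egger_intercept"], 0.01, tolerance = 1e-12)

  null <- mr_egger(make_harmonized(bx, 0.01, c(0, 0, 0), 0.02))
  expect_equal(null$beta, c(0, 0), tolerance = 1e-12)

  for (seed in 6:10) {
    h <- sim_harmonized(seed, n_variants = 30)
    w <- 1 / h$se_outcome^2
    oracle <- oracle_wls_intercept(h$beta_exposure, h$beta_outcome, w)
    e <- mr_egger(h)
    expect_equal(e$beta[e$method == "egger_slope"], oracle$slope,
                 tolerance = 1e-10)
    expect_equal(e$beta[e$method == "egger_intercept"], oracle$intercept,
                 tolerance = 1e-10)
    expect_equal(e$se[e$method == "egger_slope"], oracle$se_slope,
                 tolerance = 1e-10)
    expect_equal(e$se[e$method == "egger_intercept"], oracle$se_intercept,
                 tolerance = 1e-10)
  }
})

test_that("Egger recodes exposure orientation to nonnegative effects", {
  # negating a variant's (bx, by) jointly must not change the fit
  bx <- c(0.1, 0.2, 0.4, 0.3)
  by <- 0.01 + 0.3 * bx + c(0.001, -0.002, 0.001, 0)
  dat1 <- make_harmonized(bx, 0.01, by, 0.02)
  dat2 <- dat1
  dat2$beta_exposure[2] <- -dat2$beta_exposure[2]
  dat2$beta_outcome[2] <- -dat2$beta_outcome[2]
  e1 <- mr_egger(dat1)
  e2 <- mr_egger(dat2)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-12)
  expect_equal(e1$se, e2$se, tolerance = 1e-12)
})

test_that("Egger guards instrument count and degenerate designs", {
  expect_error(mr_egger(make_harmonized(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.02)),
               class = "cardiomr_error_insufficient_instruments")
  expect_error(mr_egger(make_harmonized(rep(0.2, 4), 0.01, rnorm(4), 0.02)),
               class = "cardiomr_error_degenerate_design")
})

test_that("median point estimates follow the interpolation rule", {
  # odd count, equal weights: plain middle ratio
  dat <- make_harmonized(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.3), 0.02)
  e <- mr_median(dat, "simple", n_boot = 50, seed = 1)
  expect_equal(e$beta, 0.2, tolerance = 1e-12)

  # two ratios with normalized weights (0.25, 0.75): hand evaluation of the
  # interpolation 0.1 + 0.2 * (0.5 - 0.125) / (0.625 - 0.125) = 0.25
  expect_equal(cardiomr:::weighted_median(c(0.1, 0.3), c(0.25, 0.75)), 0.25,
               tolerance = 1e-12)

  # constant ratios: estimate is that constant for any weights
  const <- make_harmonized(c(0.5, 1, 2), 0.01, 0.13 * c(0.5, 1, 2),
                           c(0.01, 0.05, 0.02))
  expect_equal(mr_median(const, "weighted", n_boot = 50, seed = 2)$beta, 0.13,
               tolerance = 1e-12)
})

test_that("weighted median with equal weights equals the simple median", {
  # equal bx and equal outcome se => identical inverse-variance weights
  dat <- make_harmonized(rep(0.3, 5), 0.01, c(0.02, 0.09, 0.05, 0.07, 0.01),
                         0.02)
  wm <- mr_median(dat, "weighted", n_boot = 50, seed = 3)
  sm <- mr_median(dat, "simple", n_boot = 50, seed = 3)
  expect_equal(wm$beta, sm$beta, tolerance = 1e-12)
})

test_that("median bootstrap is seed-reproducible and seed-stable", {
  h <- sim_harmonized(11, n_variants = 25)
  a <- mr_median(h, "weighted", n_boot = 1000, seed = 42)
  b <- mr_median(h, "weighted", n_boot = 1000, seed = 42)
  expect_identical(a$se, b$se)
  c_ <- mr_median(h, "weighted", n_boot = 1000, seed = 43)
  expect_lt(abs(a$se - c_$se) / a$se, 0.10)
  # the bootstrap must not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(mr_median(h, "simple", n_boot = 50, seed = 1))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("median estimators guard their preconditions", {
  small <- make_harmonized(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.02)
  expect_error(mr_median(small, n_boot = 10, seed = 1),
               class = "cardiomr_error_insufficient_instruments")
  zero <- make_harmonized(c(0, 0.2, 0.3), 0.01, c(0.1, 0.2, 0.3), 0.02)
  expect_error(mr_median(zero, n_boot = 10, seed = 1),
               class = "cardiomr_error_domain")
  ok <- make_harmonized(c(0.1, 0.2, 0.3), 0.01, c(0.1, 0.2, 0.3), 0.02)
  expect_error(mr_median(ok, n_boot = 10), class = "cardiomr_error_domain")
})

test_that("negating every outcome effect negates estimates, ses unchanged", {
  h <- sim_harmonized(13, n_variants = 30)
  neg <- h
  neg$beta_outcome <- -neg$beta_outcome
  for (model in c("fixed", "random")) {
    a <- mr_ivw(h, model)
    b <- mr_ivw(neg, model)
    expect_equal(b$beta, -a$beta, tolerance = 1e-12)
    expect_equal(b$se, a$se, tolerance = 1e-12)
  }
  ea <- mr_egger(h); eb <- mr_egger(neg)
  expect_equal(eb$beta, -ea$beta, tolerance = 1e-12)
  expect_equal(eb$se, ea$se, tolerance = 1e-12)
  # medians: point estimate negates exactly; bootstrap se agrees in
  # distribution (checked within tolerance, not identity)
  ma <- mr_median(h, "weighted", n_boot = 500, seed = 5)
  mb <- mr_median(neg, "weighted", n_boot = 500, seed = 5)
  expect_equal(mb$beta, -ma$beta, tolerance = 1e-12)
  expect_lt(abs(mb$se - ma$se) / ma$se, 0.15)
})

test_that("the estimator battery stacks methods with shared labels", {
  h <- sim_harmonized(17, n_variants = 20)
  est <- mr_estimates(h, seed = 9, n_boot = 100)
  expect_setequal(
    est$method,
    c("ivw_random", "egger_slope", "egger_intercept", "weighted_median",
      "simple_median")
  )
  expect_true(all(est$k == nrow(h)))
  td <- tidy(est)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(est)
  expect_equal(gl$beta_ivw, est$beta[est$method == "ivw_random"])
})
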