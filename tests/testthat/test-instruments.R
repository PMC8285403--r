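test_that("significance filter is strict and order-preserving", {
  x <- make_assoc(c("rs1", "rs2", "rs3"), "A", "G", 0.1, 0.01,
                  p_value = c(4e-8, 5e-8, 6e-8))
  kept <- select_instruments(x, 5e-8)
  expect_equal(kept$variant_id, "rs1")
  all_pass <- select_instruments(x, 1e-7)
  expect_identical(all_pass, x)
  expect_equal(nrow(select_instruments(x, 1e-12)), 0L)
})

test_that("greedy pruning keeps the lowest-p variant of a linked pair", {
  x <- make_assoc(c("s1", "s2"), "A", "G", 0.1, 0.01,
                  p_value = c(1e-10, 1e-9))
  ld <- ld_reference(data.frame(id_a = "s1", id_b = "s2", r2 = 0.5))
  expect_equal(ld_prune(x, ld, 0.01)$variant_id, "s1")

  indep <- ld_reference(data.frame(id_a = "s1", id_b = "s2", r2 = 0.001))
  expect_setequal(ld_prune(x, indep, 0.01)$variant_id, c("s1", "s2"))
})

test_that("pruning a linked chain keeps the hand-derived greedy set", {
  # Greedy by hand: accept s1 (lowest p), discard s2 (r2 0.5 with s1);
  # s3 survives (r2 0.001 with s1): accepted set {s1, s3}.
  x <- make_assoc(c("s1", "s2", "s3"), "A", "G", 0.1, 0.01,
                  p_value = c(1e-12, 1e-10, 1e-8))
  ld <- ld_reference(data.frame(
    id_a = c("s1", "s2", "s1"), id_b = c("s2", "s3", "s3"),
    r2 = c(0.5, 0.5, 0.001)
  ))
  expect_equal(ld_prune(x, ld, 0.01)$variant_id, c("s1", "s3"))
})

test_that("pruned sets are mutually independent and tie-stable", {
  sim <- generate_dataset(sim_config(
    n_variants = 24, ld_block_sizes = c(5, 5, 4), within_block_r2 = 0.6,
    seed = 8
  ))
  pruned <- ld_prune(sim$exposure, sim$ld, 0.01)
  ids <- pruned$variant_id
  pairs <- utils::combn(ids, 2)
  expect_true(all(ld_r2(sim$ld, pairs[1, ], pairs[2, ]) < 0.01))

  tied <- make_assoc(c("b", "a"), "A", "G", 0.1, 0.01, p_value = c(1e-9, 1e-9))
  ld2 <- ld_reference(data.frame(id_a = "a", id_b = "b", r2 = 0.9))
  expect_equal(ld_prune(tied, ld2, 0.01)$variant_id, "a")
  expect_equal(ld_prune(tied[2:1, ], ld2, 0.01)$variant_id, "a")
})

test_that("strict mode rejects variants unknown to the LD reference", {
  x <- make_assoc("sX", "A", "G", 0.1, 0.01, p_value = 1e-9)
  ld <- ld_reference(data.frame(id_a = "s1", id_b = "s2", r2 = 0.5))
  expect_error(ld_prune(x, ld, 0.01, strict = TRUE),
               class = "cardiomr_error_unknown_variant")
  expect_equal(nrow(ld_prune(x, ld, 0.01)), 1L)
})

test_that("proxy search applies the strict threshold and tie rules", {
  oc <- make_assoc(c("p1", "p2", "p3"), "A", "G", 0.1, 0.02)
  ld <- ld_reference(data.frame(
    id_a = c("t1", "t1", "t2", "t3", "t3"),
    id_b = c("p1", "p2", "p1", "p1", "p2"),
    r2 = c(0.95, 0.92, 0.85, 0.93, 0.93)
  ))
  subs <- substitute_proxies(c("t1", "t2"), ld, oc)
  expect_equal(subs$proxy_id[subs$target_id == "t1"], "p1")
  expect_equal(subs$r2[subs$target_id == "t1"], 0.95)
  expect_true(is.na(subs$proxy_id[subs$target_id == "t2"]))

  # exact r2 tie: lexicographic fallback
  tie <- substitute_proxies("t3", ld, oc)
  expect_equal(tie$proxy_id, "p1")

  # the 0.9 threshold is strict
  edge <- ld_reference(data.frame(id_a = "t4", id_b = "p1", r2 = 0.9))
  expect_true(is.na(substitute_proxies("t4", edge, oc)$proxy_id))
})

test_that("instrument F-statistic follows the regression form", {
  expect_equal(instrument_f_statistic(0.5, 103, 1), 101)
  expect_equal(instrument_f_statistic(0, 103, 1), 0)
  expect_equal(instrument_f_statistic(0.15, 65556, 104), 111.0594,
               tolerance = 1e-6)
  expect_error(instrument_f_statistic(0.5, 3, 2),
               class = "cardiomr_error_domain")
  expect_error(instrument_f_statistic(1, 100, 1),
               class = "cardiomr_error_domain")
  # monotonicity
  expect_gt(instrument_f_statistic(0.2, 1000, 5),
            instrument_f_statistic(0.1, 1000, 5))
  expect_gt(instrument_f_statistic(0.1, 2000, 5),
            instrument_f_statistic(0.1, 1000, 5))
  expect_lt(instrument_f_statistic(0.1, 1000, 10),
            instrument_f_statistic(0.1, 1000, 5))
})

test_that("per-variant F equals the squared Wald z and is scale-invariant", {
  expect_equal(per_variant_f(0.1, 0.01), 100)
  expect_equal(per_variant_f(0, 0.01), 0)
  beta <- rnorm(20)
  se <- abs(rnorm(20)) + 0.01
  expect_equal(per_variant_f(beta, se), (beta / se)^2)
  expect_equal(per_variant_f(3.7 * beta, 3.7 * se), per_variant_f(beta, se))
  expect_error(per_variant_f(0.1, 0), class = "cardiomr_error_domain")
})

test_that("analytic power is exact at the null and monotone", {
  expect_identical(mr_power_binary(50000, 0.1, 0.05, 1, alpha = 0.05), 0.05)
  expect_gt(mr_power_binary(1e7, 0.1, 0.2, 1.2), 0.999)
  expect_gt(mr_power_binary(100000, 0.1, 0.05, 1.2),
            mr_power_binary(50000, 0.1, 0.05, 1.2))
  expect_gt(mr_power_binary(50000, 0.1, 0.10, 1.2),
            mr_power_binary(50000, 0.1, 0.05, 1.2))
  expect_gt(mr_power_binary(50000, 0.1, 0.05, 1.3),
            mr_power_binary(50000, 0.1, 0.05, 1.2))
  # symmetric in the direction of effect
  expect_equal(mr_power_binary(50000, 0.1, 0.05, 1.25),
               mr_power_binary(50000, 0.1, 0.05, 1 / 1.25))
  expect_error(mr_power_binary(50000, 0.1, 0.05, -1),
               class = "cardiomr_error_domain")
})

test_that("diagnostics bundle matches its parts", {
  d <- instrument_diagnostics(0.15, 65556, 104, n_outcome = 463456,
                              case_fraction = 9006 / 463456)
  expect_equal(d$f_statistic, instrument_f_statistic(0.15, 65556, 104))
  expect_equal(d$power, mr_power_binary(463456, 9006 / 463456, 0.15, 1.2))
})
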