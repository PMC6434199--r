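# fprp_engine: SE recovery, Wald p, power at the observed critical value,
# FPRP and its category

test_that("se_from_ci inverts the reported interval", {
  expect_equal(se_from_ci(1.33, 1.66), 0.056539, tolerance = 1e-4)
  expect_equal(se_from_ci(0.55, 0.80), 0.095587, tolerance = 1e-4)
  # symmetric intervals around OR = 1
  for (k in c(1.2, 2, 5, 10)) {
    expect_equal(se_from_ci(1 / k, k), log(k) / 1.959964, tolerance = 1e-6)
  }
  # ci_level generalization: 90% interval uses 1.6449
  expect_equal(se_from_ci(1, exp(2 * 1.644854 * 0.1), ci_level = 0.90), 0.1,
               tolerance = 1e-6)
  expect_error(se_from_ci(1.5, 1.5), "degenerate")
})

test_that("observed_p is a two-sided Wald p with deep-tail accuracy", {
  expect_equal(observed_p(1, 0.1), 1)
  # frozen from z = log(1.38)/se, se from CI (1.20, 1.59)
  se <- se_from_ci(1.20, 1.59)
  expect_equal(observed_p(1.38, se), 7.25e-6, tolerance = 2e-2)
  se2 <- se_from_ci(1.921, 3.320)
  expect_equal(observed_p(2.525, se2), 3.2e-11, tolerance = 5e-2)
  # protective folding: OR and 1/OR give the same p
  expect_equal(observed_p(0.67, 0.1), observed_p(1 / 0.67, 0.1))
  # far tail: matches the log-scale evaluation, no catastrophic cancellation
  z <- 37
  expect_equal(observed_p(exp(z * 0.05), 0.05),
               2 * exp(pnorm(z, lower.tail = FALSE, log.p = TRUE)),
               tolerance = 1e-10)
  expect_gt(observed_p(exp(z * 0.05), 0.05), 0)
})

test_that("power matches printed table values and the on-target identity", {
  expect_lt(abs(power_to_detect(1.49, se_from_ci(1.33, 1.66)) - 0.548),
            0.002)
  expect_lt(abs(power_to_detect(3.997, se_from_ci(1.614, 9.900)) - 0.017),
            0.002)
  # estimate exactly on the target: power = 1/2 + Phi(-2 z_t)
  for (se in c(0.05, 0.2, 0.5)) {
    z_t <- log(1.5) / se
    expect_equal(power_to_detect(1.5, se), 0.5 + pnorm(-2 * z_t),
                 tolerance = 1e-12)
  }
  # protective OR folds to the risk scale
  expect_equal(power_to_detect(0.67, 0.0646), power_to_detect(1 / 0.67, 0.0646))
})

test_that("power agrees with a Monte-Carlo rejection oracle", {
  set.seed(42)
  n_draws <- 1e5
  for (i in 1:5) {
    or_point <- exp(runif(1, -0.7, 0.7))
    se <- runif(1, 0.05, 0.4)
    z_obs <- abs(log(or_point)) / se
    draws <- rnorm(n_draws, mean = log(1.5) / se, sd = 1)
    mc <- mean(abs(draws) >= z_obs)
    mc_se <- sqrt(mc * (1 - mc) / n_draws)
    expect_lt(abs(power_to_detect(or_point, se) - mc), 3 * mc_se + 1e-9)
  }
})

test_that("fprp_value reproduces printed cells and limiting cases", {
  cox <- fprp_value(observed_p(1.45, se_from_ci(1.23, 1.71)),
                    power_to_detect(1.45, se_from_ci(1.23, 1.71)))
  expect_equal(round_half_up(cox, 3), 0.015)
  mthfr <- fprp_value(observed_p(1.843, se_from_ci(1.414, 2.402)),
                      power_to_detect(1.843, se_from_ci(1.414, 2.402)))
  expect_equal(round_half_up(mthfr, 3), 0.087)
  # certain prior truth
  expect_equal(fprp_value(0.03, 0.8, prior = 1), 0)
  # doubly-degenerate input falls back to 0 with a warning
  expect_warning(out <- fprp_value(0, 0, prior = 0.5), "undefined")
  expect_equal(out, 0)
})

test_that("fprp is monotone in p_obs, power and prior, and bounded", {
  p_grid <- c(1e-8, 1e-5, 1e-3, 0.01, 0.05, 0.3, 1)
  pow_grid <- c(0.01, 0.1, 0.5, 0.9, 0.999)
  prior_grid <- c(1e-5, 1e-3, 0.05, 0.5)
  for (pow in pow_grid) for (pr in prior_grid) {
    vals <- fprp_value(p_grid, pow, pr)
    expect_true(all(diff(vals) > 0))          # increasing in p_obs
    expect_true(all(vals >= 0 & vals <= 1))
  }
  for (p in p_grid) for (pr in prior_grid) {
    expect_true(all(diff(fprp_value(p, pow_grid, pr)) < 0))  # dec. in power
  }
  for (p in p_grid) for (pow in pow_grid) {
    v <- vapply(prior_grid, function(pr) fprp_value(p, pow, pr), 0)
    expect_true(all(diff(v) < 0))             # decreasing in prior
  }
  # power strictly inside (0,1) wherever it is resolvable in double
  # precision: it saturates to 1 once the deficit z exceeds ~8, and equals
  # 1 exactly at OR = 1 (critical value 0 always rejects)
  pw <- power_to_detect(exp(setdiff(seq(-2, 2, by = 0.25), 0)), 0.3)
  expect_true(all(pw > 0 & pw < 1))
})

test_that("fprp_assess composes, categorizes and flags noteworthiness", {
  rec <- fprp_assess(meta_fix())
  hot <- rec[rec$gene == "HOTAIR", ]
  expect_equal(round_half_up(hot$fprp, 3), 0.000)
  expect_equal(hot$fprp_category, "strong")
  expect_true(hot$noteworthy)

  il18 <- rec[rec$gene == "IL-18", ]
  expect_equal(il18$fprp_category, "weak")
  expect_false(il18$noteworthy)

  null_rec <- fprp_assess(one_record(or_point = 1, ci_low = 0.9,
                                     ci_high = 1.11))
  expect_gt(null_rec$fprp, 0.99)
  expect_equal(null_rec$fprp_category, "weak")

  # rows without a CI stay NA instead of erroring
  no_ci <- one_record()
  no_ci$ci_low <- NA_real_
  expect_true(is.na(fprp_assess(no_ci)$fprp))
  expect_equal(nrow(fprp_assess(rec[0, ])), 0L)
})

test_that("category boundaries follow the 0.05 / 0.2 bins", {
  cfg <- fprp_config()
  expect_equal(evigrade:::.fprp_category(c(0.049, 0.05, 0.2, 0.201), cfg),
               c("strong", "moderate", "moderate", "weak"))
})
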