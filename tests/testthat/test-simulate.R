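# synthetic_data: seeded determinism, model calibration, pipeline closure

test_that("identical spec + seed reproduces identical records", {
  spec <- simulation_spec(k_studies = 6, seed = 99L)
  a <- simulate_association(spec)
  b <- simulate_association(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "studies"), attr(b, "studies"))
  # and a different seed gives different draws
  c_ <- simulate_association(simulation_spec(k_studies = 6, seed = 100L))
  expect_false(identical(a$or_point, c_$or_point))
})

test_that("control exposure follows the genetic model (Hardy-Weinberg)", {
  p <- 0.3
  for (model in c("allelic", "dominant", "recessive")) {
    expected <- switch(model, allelic = p, dominant = 1 - (1 - p)^2,
                       recessive = p^2)
    units <- if (model == "allelic") 2L else 1L
    spec <- simulation_spec(k_studies = 200, n_cases = 300, n_controls = 300,
                            control_maf = p, true_or = 1, model = model,
                            seed = 5L)
    tab <- attr(simulate_association(spec), "studies")
    m <- 300 * units
    phat <- sum(tab$c) / (nrow(tab) * m)
    mc_se <- sqrt(expected * (1 - expected) / (nrow(tab) * m))
    expect_lt(abs(phat - expected), 4 * mc_se)
  }
})

test_that("null and effect calibration: pooled OR recovers the truth", {
  # null: pooled log OR within 3 pooled-SE of 0
  null_spec <- simulation_spec(k_studies = 300, n_cases = 500,
                               n_controls = 500, true_or = 1, seed = 21L)
  rec <- simulate_association(null_spec)
  expect_lt(abs(log(rec$or_point)),
            3 * se_from_ci(rec$ci_low, rec$ci_high))

  # effect: true OR 1.5 at large n
  eff_spec <- simulation_spec(k_studies = 500, n_cases = 2000,
                              n_controls = 2000, true_or = 1.5, seed = 22L)
  rec2 <- simulate_association(eff_spec)
  expect_lt(abs(log(rec2$or_point) - log(1.5)),
            3 * se_from_ci(rec2$ci_low, rec2$ci_high))
})

test_that("between-study heterogeneity drives I-squared upward", {
  i2 <- function(tau, seeds) {
    vapply(seeds, function(s) {
      spec <- simulation_spec(k_studies = 5, n_cases = 1000,
                              n_controls = 1000, true_or = 1.3, tau = tau,
                              seed = s)
      simulate_association(spec)$i_squared
    }, 0)
  }
  seeds <- 1:200
  hom <- i2(0, seeds)
  het <- i2(0.3, seeds + 1000L)
  expect_lt(median(hom), 10)
  expect_gt(median(het), median(hom))
})

test_that("publication-bias censoring inflates Egger asymmetry", {
  base <- simulation_spec(k_studies = 12,
                          n_cases = rep(c(50, 800), 6),
                          n_controls = rep(c(50, 800), 6),
                          true_or = 1.0, seed = 31L)
  cens <- base; cens$censor_small_nonsig <- TRUE
  int_free <- vapply(1:60, function(s) {
    b <- base; b$seed <- 1000L + s
    meta_summary(attr(simulate_association(b), "studies")$log_or,
                 attr(simulate_association(b), "studies")$se)$egger_intercept
  }, 0)
  int_cens <- vapply(1:60, function(s) {
    b <- cens; b$seed <- 1000L + s
    rec <- simulate_association(b)
    attr(rec, "studies")
    rec$egger_p
    meta_summary(attr(rec, "studies")$log_or,
                 attr(rec, "studies")$se)$egger_intercept
  }, 0)
  expect_gt(abs(mean(int_cens)), abs(mean(int_free)))
})

test_that("simulated records close the pipeline: validate, grade, assess", {
  spec <- simulation_spec(k_studies = 8, n_cases = 800, n_controls = 800,
                          true_or = 1.6, seed = 12L)
  rec <- simulate_association(spec)
  expect_s3_class(rec, "association_records")
  expect_length(validate_records(rec, stop_on_error = FALSE), 0L)
  out <- assess_evidence(rec)
  expect_true(out$venice_level %in% c("strong", "moderate", "weak",
                                      "ungraded"))
  expect_true(out$final_level %in% c("strong", "moderate", "weak",
                                     "ungraded"))
  expect_true(is.finite(out$fprp))
})

test_that("k = 1 record equals its single study", {
  spec <- simulation_spec(k_studies = 1, n_cases = 400, n_controls = 400,
                          seed = 77L)
  rec <- simulate_association(spec)
  tab <- attr(rec, "studies")
  expect_equal(log(rec$or_point), tab$log_or)
  expect_equal(se_from_ci(rec$ci_low, rec$ci_high), tab$se,
               tolerance = 1e-6)
  expect_equal(rec$n_studies, 1)
})

test_that("null noteworthiness rate sits below the significance rate", {
  spec <- simulation_spec(k_studies = 5, n_cases = 500, n_controls = 500,
                          true_or = 1, seed = 400L)
  out <- null_noteworthiness_rate(spec, n_replicates = 300)
  expect_lt(out$rate_noteworthy, out$rate_significant + 1e-12)
  expect_lt(out$rate_noteworthy, 0.01)
  # determinism of the whole replication loop
  out2 <- null_noteworthiness_rate(spec, n_replicates = 300)
  expect_identical(out, out2)
})
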