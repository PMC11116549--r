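# Cohort generator and the analytic counterfactual oracle.

test_that("spec validation rejects bad marginals and misnamed coefficients", {
  expect_error(
    cohort_spec(10, factors = list(g = c(a = 0.5, b = 0.4)),
                flags = c(f = 0.1),
                treatment_coefs = list(), outcome_coefs = list()),
    "marginal of factor 'g'")
  expect_error(
    cohort_spec(10, factors = list(g = c(a = 0.5, b = 0.5)),
                flags = c(f = 0.1),
                treatment_coefs = list(t2 = c(nonexistent = 1)),
                outcome_coefs = list()),
    "treatment_coefs\\$t2")
  expect_error(
    cohort_spec(0, factors = list(), flags = c(f = 0.1),
                treatment_coefs = list(), outcome_coefs = list()),
    "n_patients")
  expect_error(
    cohort_spec(10, factors = list(), flags = c(f = 0.1),
                treatment_coefs = list(),
                outcome_coefs = list(alpha2 = c(1, 2))),
    "alpha2")
})

test_that("design columns follow the documented reference-coded layout", {
  spec <- two_flag_spec()
  expect_identical(spec_design_columns(spec), c("(Intercept)", "f1", "f2"))
  expect_identical(
    spec_design_columns(study_cohort_spec())[1:5],
    c("(Intercept)", "age_group66-75", "age_group46-65", "age_group<=45",
      "sexMale"))
})

test_that("identical spec and seed give a byte-identical cohort", {
  a <- generate_cohort(benchmark_spec(500, seed = 42))
  b <- generate_cohort(benchmark_spec(500, seed = 42))
  expect_identical(a, b)
  c <- generate_cohort(benchmark_spec(500, seed = 43))
  expect_false(identical(a, c))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_cohort(benchmark_spec(200, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("null assignment law gives near-uniform arms and null outcome law near-half survival", {
  spec <- cohort_spec(
    n_patients = 20000,
    factors = list(g = c(a = 0.5, b = 0.5)),
    flags = c(f = 0.4),
    treatment_coefs = list(),
    outcome_coefs = list(),
    seed = 7)
  co <- generate_cohort(spec)
  shares <- tabulate(co$treatment + 1L, 4) / nrow(co)
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_true(all(abs(shares - 0.25) < 3 * se))
  se_y <- sqrt(0.25 / 20000)
  expect_lt(abs(mean(co$y5_survival) - 0.5), 3 * se_y)
})

test_that("study-scale spec reproduces the study treatment shares within 2%", {
  co <- generate_cohort(study_cohort_spec(seed = 2))
  shares <- tabulate(co$treatment + 1L, 4) / nrow(co)
  expect_true(all(abs(shares - c(0.4830, 0.1135, 0.3070, 0.0966)) < 0.02))
  expect_lt(abs(mean(co$y5_survival) - 0.78), 0.02)
})

test_that("follow-up is five years for survivors and in (0, 5] for deaths", {
  co <- generate_cohort(benchmark_spec(2000, seed = 3))
  expect_true(all(co$followup_years[co$y5_survival == 1] == 5.0))
  d <- co$followup_years[co$y5_survival == 0]
  expect_true(all(d > 0 & d <= 5))
})

test_that("null treatment effect gives equal true means and exactly zero interaction", {
  spec <- cohort_spec(
    n_patients = 10,
    factors = list(g = c(a = 0.6, b = 0.4)),
    flags = c(f = 0.3),
    treatment_coefs = list(),
    outcome_coefs = list(alpha1 = c("(Intercept)" = 0.4, f = -0.7)),
    seed = 1)
  te <- true_counterfactuals(spec)
  expect_equal(max(te$true_means) - min(te$true_means), 0, tolerance = 1e-15)
  expect_lt(abs(te$true_ddi), 1e-12)
  expect_true(all(te$true_means >= 0 & te$true_means <= 1))
})

test_that("closed-form truth equals a hand enumeration on a two-flag law", {
  spec <- two_flag_spec()
  te <- true_counterfactuals(spec, method = "closed_form_average")
  # independent oracle: average the logistic over the four cells by hand
  cells <- expand.grid(f1 = 0:1, f2 = 0:1)
  w <- ifelse(cells$f1 == 1, 0.3, 0.7) * ifelse(cells$f2 == 1, 0.6, 0.4)
  eta0 <- 0.2 + 0.5 * cells$f1 - 0.4 * cells$f2
  hand <- c(sum(w * plogis(eta0)),
            sum(w * plogis(eta0 + 0.3)),
            sum(w * plogis(eta0 - 0.2)),
            sum(w * plogis(eta0 + 0.6 + 0.25 * cells$f1)))
  expect_equal(unname(te$true_means), hand, tolerance = 1e-12)
  expect_equal(te$true_ddi,
               hand[4] - hand[3] - hand[2] + hand[1], tolerance = 1e-12)
})

test_that("monte carlo truth agrees with the closed form within 4 mc errors", {
  spec <- two_flag_spec()
  cf <- true_counterfactuals(spec, method = "closed_form_average")
  mc <- true_counterfactuals(spec, n_mc = 20000, method = "monte_carlo")
  expect_true(all(abs(mc$true_means - cf$true_means) < 4 * mc$mc_error))
  expect_error(true_counterfactuals(spec, n_mc = 0, method = "monte_carlo"),
               "n_mc")
})

test_that("cohort CSV and spec YAML round-trip", {
  spec <- benchmark_spec(100, seed = 9)
  co <- generate_cohort(spec)
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f, spec = spec)
  expect_equal(back$treatment, co$treatment)
  expect_equal(levels(back$age_band), levels(co$age_band))
  expect_equal(back$followup_years, co$followup_years, tolerance = 1e-12)

  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 50",
    "seed: 4",
    "factors:",
    "  g: {a: 0.6, b: 0.4}",
    "flags: {f: 0.25}",
    "treatment_coefs:",
    "  t1: {'(Intercept)': -0.5, f: 0.3}",
    "outcome_coefs:",
    "  alpha1: {'(Intercept)': 1.0}",
    "  alpha2: [0.1, 0.0, 0.2]"), yml)
  s2 <- read_cohort_spec(yml)
  expect_s3_class(s2, "cohort_spec")
  expect_equal(s2$n_patients, 50L)
  expect_equal(unname(s2$treatment_coefs$t1["f"]), 0.3)
  expect_equal(s2$outcome_coefs$alpha2, c(0.1, 0, 0.2))
  expect_equal(nrow(generate_cohort(s2)), 50)
})
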