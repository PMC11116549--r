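# Built-in cohort specifications: the study-scale cohort emulation and a
# compact benchmark law used for double-robustness and coverage studies.

#' Treatment strategy taxonomy
#'
#' The four mutually exclusive treatment strategies, indexed 0..3:
#' no drug treatment, Memantine monotherapy, Donepezil monotherapy, and the
#' Donepezil+Memantine combination.
#'
#' @return character vector of the four strategy labels in index order.
#' @export
treatment_levels <- function() {
  c("None", "Memantine", "Donepezil", "Donepezil+Memantine")
}

# Empirical marginals of the emulated cohort (fractions of 12,744).
study_marginals <- function() {
  list(
    factors = list(
      age_group = c("76-85" = 10264, "66-75" = 1834, "46-65" = 607,
                    "<=45" = 39) / 12744,
      sex = c(Female = 7967, Male = 4772, Unknown = 5) / 12744,
      race = c(Caucasian = 10341, Unknown = 1210, `African American` = 808,
               Asian = 279, Hispanic = 44,
               `American Indian or Alaska Native` = 42,
               `Pacific Islander` = 20) / 12744,
      marital = c(Single = 6258, Married = 4531, Unknown = 1088,
                  Divorced = 867) / 12744
    ),
    flags = c(cerebral_infarction = 1841, diabetes = 1477,
              overweight_obesity = 213, hypertensive_disease = 1622,
              other_heart_disease = 3022, kidney_disease = 3507) / 12744
  )
}

# Intercepts calibrated (by exact enumeration over the covariate support) so
# that under misspec_scenario = "none" the marginal treatment shares equal
# 6155/1446/3912/1231 of 12,744 and the true counterfactual survival means
# equal (0.780, 0.781, 0.765, 0.830). See the methods vignette.
.study_calib <- list(
  t_intercepts = c(t1 = -1.5146940167557843, t2 = -0.59625459369418088,
                   t3 = -1.8278583216188311),
  y_intercept = 1.6252511857283478,
  alpha2 = c(0.022822360707970602, -0.081982461392001521,
             0.29374001940616135)
)

#' Study-scale synthetic cohort specification
#'
#' A [cohort_spec()] emulating the structure of the AD study cohort:
#' categorical demographics (age group at diagnosis, sex, race, marital
#' status) and six comorbidity flags with the study's marginal frequencies,
#' treatment assignment calibrated so the four strategy shares are
#' 48.30/11.35/30.70/9.66% of patients, and an outcome law whose true
#' counterfactual five-year survival means are (0.780, 0.781, 0.765, 0.830)
#' with overall observed survival near 78%. Non-intercept coefficients induce
#' moderate confounding through age, sex, marital status and the
#' comorbidities.
#'
#' @param n_patients cohort size (default 12744, the study scale).
#' @param seed integer seed.
#' @param misspec_scenario passed to [cohort_spec()]; the hidden term is the
#'   product of the heart-disease and kidney-disease flags.
#' @return a `cohort_spec`.
#' @export
study_cohort_spec <- function(n_patients = 12744, seed = 1L,
                              misspec_scenario = "none") {
  m <- study_marginals()
  cal <- .study_calib
  cohort_spec(
    n_patients = n_patients,
    factors = m$factors,
    flags = m$flags,
    treatment_coefs = list(
      t1 = c("(Intercept)" = unname(cal$t_intercepts["t1"]),
             `age_group66-75` = 0.15, sexMale = -0.10, maritalMarried = 0.20,
             other_heart_disease = 0.08, kidney_disease = -0.05,
             hypertensive_disease = 0.05),
      t2 = c("(Intercept)" = unname(cal$t_intercepts["t2"]),
             `age_group66-75` = 0.25, `age_group46-65` = 0.10,
             sexMale = -0.05, maritalMarried = 0.20, diabetes = 0.08,
             hypertensive_disease = 0.15, kidney_disease = 0.08),
      t3 = c("(Intercept)" = unname(cal$t_intercepts["t3"]),
             `age_group66-75` = 0.30, sexMale = 0.15, maritalMarried = 0.45,
             maritalDivorced = -0.25, cerebral_infarction = -0.10,
             other_heart_disease = -0.12)
    ),
    outcome_coefs = list(
      alpha1 = c("(Intercept)" = cal$y_intercept,
                 `age_group66-75` = 0.45, `age_group46-65` = 0.90,
                 `age_group<=45` = 1.20, sexMale = -0.35,
                 maritalMarried = 0.15, raceUnknown = 0.10,
                 cerebral_infarction = -0.35, diabetes = -0.25,
                 overweight_obesity = -0.10, hypertensive_disease = -0.15,
                 other_heart_disease = -0.40, kidney_disease = -0.55),
      alpha2 = cal$alpha2,
      alpha3 = list(
        t1 = c(kidney_disease = -0.05),
        t2 = c(diabetes = -0.05),
        t3 = c(other_heart_disease = 0.10, `age_group66-75` = 0.08)
      )
    ),
    misspec_scenario = misspec_scenario,
    misspec = list(flags = c("other_heart_disease", "kidney_disease"),
                   treatment = c(0, 0, 1.5),
                   outcome_main = -1.2, outcome_arm3 = 0.8),
    seed = seed
  )
}

# Benchmark intercepts, calibrated the same way (shares 48.30/11.35/30.70/
# 9.66%, true means 0.780/0.781/0.765/0.830 under scenario "none").
.benchmark_calib <- list(
  t_intercepts = c(t1 = -1.8243282952297844, t2 = -0.67604941645240346,
                   t3 = -3.1724926704530336),
  y_intercept = 2.3669839466152465,
  alpha2 = c(0.0063306070210518896, -0.036461351717073154,
             0.22704145371736861)
)

#' Compact benchmark specification for estimator studies
#'
#' A small covariate law (one three-level age band, three comorbidity flags)
#' with the same treatment shares and true counterfactual means as
#' [study_cohort_spec()], cheap enough to refit thousands of times. Used by
#' the double-robustness and bootstrap-coverage studies; the hidden
#' misspecification term is the heart-disease x kidney-disease product, with
#' coefficients strong enough to make the singly robust estimators visibly
#' biased at n = 50,000.
#'
#' @param n_patients cohort size.
#' @param seed integer seed.
#' @param misspec_scenario passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
benchmark_spec <- function(n_patients = 50000, seed = 1L,
                           misspec_scenario = "none") {
  cal <- .benchmark_calib
  cohort_spec(
    n_patients = n_patients,
    factors = list(age_band = c(mid = 0.5, old = 0.3, young = 0.2)),
    flags = c(hypertension = 0.45, heart_disease = 0.50,
              kidney_disease = 0.45),
    treatment_coefs = list(
      t1 = c("(Intercept)" = unname(cal$t_intercepts["t1"]),
             age_bandold = 0.3, heart_disease = 0.9, kidney_disease = -0.9),
      t2 = c("(Intercept)" = unname(cal$t_intercepts["t2"]),
             age_bandold = 0.4, age_bandyoung = -0.2, heart_disease = -0.7,
             kidney_disease = 0.9),
      t3 = c("(Intercept)" = unname(cal$t_intercepts["t3"]),
             age_bandold = 0.5, heart_disease = 1.1, kidney_disease = 1.1,
             hypertension = 0.3)
    ),
    outcome_coefs = list(
      alpha1 = c("(Intercept)" = cal$y_intercept,
                 age_bandold = -0.6, age_bandyoung = 0.5,
                 hypertension = -0.3, heart_disease = -0.7,
                 kidney_disease = -0.9),
      alpha2 = cal$alpha2,
      alpha3 = list(t2 = c(kidney_disease = -0.1),
                    t3 = c(heart_disease = 0.2))
    ),
    misspec_scenario = misspec_scenario,
    misspec = list(flags = c("heart_disease", "kidney_disease"),
                   treatment = c(0.5, -0.5, 0.8),
                   outcome_main = -2.0, outcome_arm3 = 1.5),
    seed = seed
  )
}
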