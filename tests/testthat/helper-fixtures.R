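# Shared fixtures, all built in code.

# Ten-row patient table exercising every eligibility filter:
# rows 1-2 diagnosed outside 2016, row 3 missing marital status, rows 4-5
# treatment switchers, row 6 Rivastigmine monotherapy (outside the
# four-strategy taxonomy), rows 7-10 eligible (one per strategy).
toy_filter_records <- function() {
  data.frame(
    patient_id = sprintf("T%02d", 1:10),
    first_dx_date = as.Date(c("2015-06-01", "2017-03-15", "2016-02-01",
                              "2016-04-01", "2016-05-01", "2016-06-01",
                              "2016-07-01", "2016-08-01", "2016-09-01",
                              "2016-10-01")),
    age_group = rep("76-85", 10),
    sex = rep("Female", 10),
    race = rep("Caucasian", 10),
    marital = c(rep("Single", 2), NA, rep("Single", 7)),
    med_history = c("None", "Donepezil", "None",
                    "Donepezil|Donepezil+Memantine", "None|Memantine",
                    "Rivastigmine",
                    "None", "Memantine", "Donepezil", "Donepezil+Memantine"),
    stringsAsFactors = FALSE
  )
}

# A records table that is already fully eligible, one row per strategy.
eligible_records <- function(n_per_arm = 1) {
  labs <- treatment_levels()
  data.frame(
    patient_id = sprintf("E%03d", seq_len(4 * n_per_arm)),
    first_dx_date = as.Date("2016-03-01"),
    age_group = "66-75", sex = "Male", race = "Unknown", marital = "Married",
    med_history = rep(labs, each = n_per_arm),
    stringsAsFactors = FALSE
  )
}

# Tiny two-flag generating law with hand-enumerable support (4 cells).
two_flag_spec <- function(n = 100, seed = 1) {
  cohort_spec(
    n_patients = n,
    factors = list(),
    flags = c(f1 = 0.3, f2 = 0.6),
    treatment_coefs = list(t1 = c("(Intercept)" = -0.2),
                           t2 = c("(Intercept)" = 0.1),
                           t3 = c("(Intercept)" = -0.5)),
    outcome_coefs = list(
      alpha1 = c("(Intercept)" = 0.2, f1 = 0.5, f2 = -0.4),
      alpha2 = c(0.3, -0.2, 0.6),
      alpha3 = list(t3 = c(f1 = 0.25))),
    seed = seed
  )
}

# Analysis matrix built directly from vectors (no records table needed).
raw_matrix <- function(Y, A, L) {
  if (is.null(colnames(L))) colnames(L) <- paste0("x", seq_len(ncol(L)))
  enc <- lapply(setdiff(colnames(L), "(Intercept)"),
                function(cl) list(type = "flag", columns = cl))
  names(enc) <- setdiff(colnames(L), "(Intercept)")
  structure(list(Y = as.numeric(Y), A = as.integer(A), L = L,
                 encoding = enc),
            class = "analysis_matrix")
}

# Benchmark law with the treatment-by-covariate interactions zeroed, used by
# the bootstrap-coverage study together with a mains-only working model.
coverage_spec <- function(n, seed) {
  s <- benchmark_spec(n, seed)
  s$outcome_coefs$alpha3 <- lapply(s$outcome_coefs$alpha3, function(v) v * 0)
  s
}
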