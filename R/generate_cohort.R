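# Cohort simulation and the analytic counterfactual oracle.

#' Simulate an EHR-like analysis cohort
#'
#' Draws `spec$n_patients` patient records: covariates independently from the
#' spec's marginals, treatment from the baseline-category multinomial logit
#' implied by `treatment_coefs`, and the five-year survival indicator from the
#' Bernoulli outcome law implied by `outcome_coefs`. Survivors get a follow-up
#' time of exactly 5 years; deaths get a uniform(0, 5] death time (synthetic
#' plumbing that supports crude mortality-rate computation; the estimators use
#' only the binary indicator). A first-diagnosis date uniform over 2016 and a
#' single-regimen medication history are attached so that generated cohorts
#' pass through [apply_study_filters()] unchanged.
#'
#' The whole table is reproducible from `spec$seed`: identical spec and seed
#' give a byte-identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return a data.frame with columns `patient_id`, `first_dx_date`, the
#'   spec's covariates, `med_history`, `treatment` (integer 0..3),
#'   `y5_survival` (0/1) and `followup_years`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  local_seed(spec$seed, {
    frame <- spec_draw_covariates(spec, n)
    P <- spec_treatment_probs(frame, spec)
    u <- stats::runif(n)
    c1 <- P[, 1]
    c2 <- c1 + P[, 2]
    c3 <- c2 + P[, 3]
    treatment <- (u > c1) + (u > c2) + (u > c3)
    b <- matrix(0, n, 4)
    for (i in 0:3) b[, i + 1] <- spec_outcome_prob(frame, spec, i)
    pr <- b[cbind(seq_len(n), treatment + 1L)]
    y <- stats::rbinom(n, 1L, pr)
    death_time <- stats::runif(n, 0, 5)
    followup <- ifelse(y == 1L, 5.0, death_time)
    dx <- as.Date("2016-01-01") + sample(0:365, n, replace = TRUE)
    out <- data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      first_dx_date = dx,
      stringsAsFactors = FALSE
    )
    out <- cbind(out, frame)
    out$med_history <- treatment_levels()[treatment + 1L]
    out$treatment <- as.integer(treatment)
    out$y5_survival <- as.integer(y)
    out$followup_years <- followup
    out
  })
}

#' True counterfactual survival under the generating law
#'
#' Computes the ground-truth counterfactual means E(Y^{a=i}) = E[b_i(L)] for
#' i = 0..3 under a spec's outcome law, by the double-expectation identity:
#' the known arm-i success probability is averaged over the covariate
#' distribution. With a purely categorical covariate support the average is an
#' exact enumeration over all cells (`closed_form_average`); with a continuous
#' covariate (or on request) it is a Monte Carlo average over fresh covariate
#' draws, with a reported standard error.
#'
#' Note the truth respects `misspec_scenario`: if the hidden flag-product term
#' is part of the true outcome mechanism it is part of the truth here too.
#'
#' @param spec a [cohort_spec()].
#' @param n_mc number of Monte Carlo covariate draws (used when
#'   `method = "monte_carlo"`; must be >= 1 there).
#' @param method `"auto"` (enumerate when the support is finite and small,
#'   else Monte Carlo), `"closed_form_average"`, or `"monte_carlo"`.
#' @return object of class `true_effects`: `true_means` (4), `true_rds`
#'   (3, combined arm minus arms 0..2), `true_ddi`, `method`, and `mc_error`
#'   (per-arm standard errors; zeros for the closed form).
#' @export
true_counterfactuals <- function(spec, n_mc = 10000,
                                 method = c("auto", "closed_form_average",
                                            "monte_carlo")) {
  stopifnot(inherits(spec, "cohort_spec"))
  method <- match.arg(method)
  n_cells <- prod(vapply(spec$factors, length, 1L)) * 2^length(spec$flags)
  if (method == "auto") {
    method <- if (is.null(spec$continuous) && n_cells <= 2e5)
      "closed_form_average" else "monte_carlo"
  }
  if (method == "closed_form_average") {
    if (!is.null(spec$continuous))
      stop_drc("drc_config",
               "closed_form_average is unavailable with a continuous covariate")
    lv <- lapply(spec$factors, names)
    fl <- stats::setNames(rep(list(0:1), length(spec$flags)),
                          names(spec$flags))
    frame <- expand.grid(c(lv, fl), KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    for (nm in names(spec$factors))
      frame[[nm]] <- factor(frame[[nm]], levels = names(spec$factors[[nm]]))
    w <- rep(1, nrow(frame))
    for (nm in names(spec$factors))
      w <- w * spec$factors[[nm]][as.integer(frame[[nm]])]
    for (nm in names(spec$flags)) {
      p <- spec$flags[[nm]]
      w <- w * ifelse(frame[[nm]] == 1, p, 1 - p)
    }
    means <- vapply(0:3, function(i)
      sum(w * spec_outcome_prob(frame, spec, i)), numeric(1))
    mc_error <- rep(0, 4)
  } else {
    if (n_mc < 1)
      stop_drc("drc_argument", "n_mc must be a positive integer")
    res <- local_seed(spec$seed + 1L, {
      frame <- spec_draw_covariates(spec, n_mc)
      vals <- vapply(0:3, function(i) spec_outcome_prob(frame, spec, i),
                     numeric(n_mc))
      vals <- matrix(vals, nrow = n_mc)
      list(means = colMeans(vals),
           se = apply(vals, 2, stats::sd) / sqrt(n_mc))
    })
    means <- res$means
    mc_error <- res$se
  }
  names(means) <- as.character(0:3)
  structure(
    list(true_means = means,
         true_rds = stats::setNames(means[4] - means[1:3],
                                    c("vs_none", "vs_memantine", "vs_donepezil")),
         true_ddi = unname(means[4] - means[3] - means[2] + means[1]),
         method = method,
         mc_error = mc_error),
    class = "true_effects")
}

#' @export
print.true_effects <- function(x, ...) {
  cat("<true_effects> (", x$method, ")\n", sep = "")
  cat("  means:", paste(sprintf("%.4f", x$true_means), collapse = " "), "\n")
  cat("  rds:  ", paste(sprintf("%.4f", x$true_rds), collapse = " "), "\n")
  cat("  ddi:  ", sprintf("%.4f", x$true_ddi), "\n")
  invisible(x)
}

#' Write / read a simulated cohort as CSV
#'
#' Plain-text round trip for cohort tables. The header schema is the
#' [generate_cohort()] column set; factor columns are written as character and
#' restored as factors with the level order of `spec` when provided.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @param spec optional `cohort_spec` used to restore factor level order.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, spec = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(x$first_dx_date)) x$first_dx_date <- as.Date(x$first_dx_date)
  if (!is.null(spec)) {
    for (nm in names(spec$factors))
      x[[nm]] <- factor(x[[nm]], levels = names(spec$factors[[nm]]))
  }
  x
}
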