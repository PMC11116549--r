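# Specification object for the synthetic EHR-like cohort generator.
#
# A cohort_spec fixes the joint law of one simulated study: independent
# categorical demographics and binary comorbidity flags with given marginals,
# a baseline-category multinomial-logit treatment assignment over the encoded
# covariates, and a Bernoulli five-year-survival outcome whose logit carries
# covariate main effects, treatment main effects and treatment-by-covariate
# interactions. An optional "hidden" transform (the product of two comorbidity
# flags) can enter the true assignment and/or outcome mechanism while staying
# out of every analyst model, which is what makes double-robustness testable.

#' Construct a synthetic cohort specification
#'
#' @param n_patients number of patients to simulate (>= 1).
#' @param factors named list of named probability vectors, one per categorical
#'   covariate. Level order is meaningful: the first level is the reference
#'   level of the design encoding.
#' @param flags named numeric vector of binary comorbidity prevalences.
#' @param treatment_coefs list with elements `t1`, `t2`, `t3`: named numeric
#'   vectors of baseline-category logit coefficients (treatment 0 is the
#'   reference). Names must be design column names (see
#'   [spec_design_columns()]); unnamed entries default to 0, so sparse
#'   specification is allowed.
#' @param outcome_coefs list with elements `alpha1` (named vector over design
#'   columns, covariate main effects incl. intercept), `alpha2` (length-3
#'   treatment main effects for arms 1..3), and optional `alpha3` (list of
#'   named vectors `t1`,`t2`,`t3` of treatment-by-covariate interaction
#'   coefficients over non-intercept columns).
#' @param misspec_scenario one of `"none"`, `"propensity_wrong"`,
#'   `"outcome_wrong"`, `"both_wrong"`: whether the hidden flag-product term
#'   enters the true treatment mechanism, the true outcome mechanism, or both.
#' @param misspec list describing the hidden term: `flags` (two flag names
#'   whose product is the hidden covariate), `treatment` (length-3 coefficients
#'   added to the three treatment logits), `outcome_main` (coefficient on the
#'   outcome logit in every arm), `outcome_arm3` (extra coefficient under the
#'   combined treatment).
#' @param continuous optional list `(name =, mean =, sd =)` adding one
#'   continuous covariate; its square enters the design as `<name>_sq`.
#' @param seed integer seed driving every draw for this spec.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()], [true_counterfactuals()], [study_cohort_spec()]
#' @export
cohort_spec <- function(n_patients,
                        factors,
                        flags,
                        treatment_coefs,
                        outcome_coefs,
                        misspec_scenario = c("none", "propensity_wrong",
                                             "outcome_wrong", "both_wrong"),
                        misspec = NULL,
                        continuous = NULL,
                        seed = 1L) {
  misspec_scenario <- match.arg(misspec_scenario)
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1)
    stop_drc("drc_config", "n_patients must be a positive integer")
  n_patients <- as.integer(n_patients)

  if (!is.list(factors) ||
      (length(factors) && (is.null(names(factors)) ||
                           any(names(factors) == ""))))
    stop_drc("drc_config", "factors must be a named list of probability vectors")
  for (nm in names(factors)) {
    p <- factors[[nm]]
    if (is.null(names(p)) || any(names(p) == ""))
      stop_drc("drc_config", "factor '%s' needs named level probabilities", nm)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop_drc("drc_config",
               "marginal of factor '%s' must be nonnegative and sum to 1 (got %.15f)",
               nm, sum(p))
  }
  if (length(flags) && (is.null(names(flags)) || any(names(flags) == "")))
    stop_drc("drc_config", "flags must be a named prevalence vector")
  if (any(flags < 0 | flags > 1))
    stop_drc("drc_config", "flag prevalences must lie in [0, 1]")
  if (!is.null(continuous)) {
    continuous$mean <- continuous$mean %||% 0
    continuous$sd <- continuous$sd %||% 1
    if (is.null(continuous$name))
      stop_drc("drc_config", "continuous covariate needs a name")
  }

  spec <- structure(
    list(n_patients = n_patients, factors = factors, flags = flags,
         treatment_coefs = NULL, outcome_coefs = NULL,
         misspec_scenario = misspec_scenario,
         misspec = misspec, continuous = continuous, seed = as.integer(seed)),
    class = "cohort_spec")

  cols <- spec_design_columns(spec)
  expand <- function(v, block) {
    if (is.null(v)) v <- numeric(0)
    full <- stats::setNames(numeric(length(cols)), cols)
    if (length(v)) {
      bad <- setdiff(names(v), cols)
      if (length(bad))
        stop_drc("drc_config",
                 "coefficient block '%s' names unknown design columns: %s",
                 block, paste(bad, collapse = ", "))
      full[names(v)] <- v
    }
    full
  }
  tc <- lapply(c("t1", "t2", "t3"), function(a)
    expand(treatment_coefs[[a]], paste0("treatment_coefs$", a)))
  names(tc) <- c("t1", "t2", "t3")
  spec$treatment_coefs <- tc

  a1 <- expand(outcome_coefs$alpha1, "outcome_coefs$alpha1")
  a2 <- outcome_coefs$alpha2 %||% numeric(3)
  if (length(a2) != 3)
    stop_drc("drc_config",
             "outcome_coefs$alpha2 must have length 3 (arms 1..3), got %d",
             length(a2))
  ni <- setdiff(cols, "(Intercept)")
  a3 <- lapply(c("t1", "t2", "t3"), function(a) {
    v <- outcome_coefs$alpha3[[a]]
    if (is.null(v)) v <- numeric(0)
    bad <- setdiff(names(v), ni)
    if (length(bad))
      stop_drc("drc_config",
               "coefficient block 'outcome_coefs$alpha3$%s' names unknown non-intercept columns: %s",
               a, paste(bad, collapse = ", "))
    full <- stats::setNames(numeric(length(ni)), ni)
    if (length(v)) full[names(v)] <- v
    full
  })
  names(a3) <- c("t1", "t2", "t3")
  spec$outcome_coefs <- list(alpha1 = a1, alpha2 = as.numeric(a2), alpha3 = a3)

  if (misspec_scenario != "none") {
    ms <- spec$misspec
    if (is.null(ms) || length(ms$flags) != 2 ||
        !all(ms$flags %in% names(flags)))
      stop_drc("drc_config",
               "misspec$flags must name two of the spec's comorbidity flags")
    ms$treatment <- ms$treatment %||% numeric(3)
    ms$outcome_main <- ms$outcome_main %||% 0
    ms$outcome_arm3 <- ms$outcome_arm3 %||% 0
    if (length(ms$treatment) != 3)
      stop_drc("drc_config", "misspec$treatment must have length 3")
    spec$misspec <- ms
  }
  spec
}

#' Design column names implied by a cohort specification
#'
#' Reference ("drop first level") encoding: an intercept, then for each factor
#' one indicator per non-reference level (named `<factor><level>` as
#' [stats::model.matrix()] names them), then the binary flags, then any
#' continuous covariate and its square (`<name>_sq`).
#'
#' @param spec a `cohort_spec` (only its `factors`/`flags`/`continuous` fields
#'   are used).
#' @return character vector of design column names.
#' @export
spec_design_columns <- function(spec) {
  cols <- "(Intercept)"
  for (nm in names(spec$factors))
    cols <- c(cols, paste0(nm, names(spec$factors[[nm]])[-1]))
  cols <- c(cols, names(spec$flags))
  if (!is.null(spec$continuous))
    cols <- c(cols, spec$continuous$name, paste0(spec$continuous$name, "_sq"))
  cols
}

# Design matrix for a covariate frame laid out per spec_design_columns().
spec_design <- function(frame, spec) {
  n <- nrow(frame)
  cols <- spec_design_columns(spec)
  X <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  X[, "(Intercept)"] <- 1
  for (nm in names(spec$factors)) {
    lv <- names(spec$factors[[nm]])
    for (l in lv[-1]) X[, paste0(nm, l)] <- as.numeric(frame[[nm]] == l)
  }
  for (nm in names(spec$flags)) X[, nm] <- frame[[nm]]
  if (!is.null(spec$continuous)) {
    nm <- spec$continuous$name
    X[, nm] <- frame[[nm]]
    X[, paste0(nm, "_sq")] <- frame[[nm]]^2
  }
  X
}

# Draw a covariate frame of n rows (assumes RNG state already set).
spec_draw_covariates <- function(spec, n) {
  out <- list()
  for (nm in names(spec$factors)) {
    p <- spec$factors[[nm]]
    out[[nm]] <- factor(sample(names(p), n, replace = TRUE, prob = p),
                        levels = names(p))
  }
  for (nm in names(spec$flags))
    out[[nm]] <- stats::rbinom(n, 1L, spec$flags[[nm]])
  if (!is.null(spec$continuous)) {
    cn <- spec$continuous
    out[[cn$name]] <- stats::rnorm(n, cn$mean, cn$sd)
  }
  as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
}

# Hidden flag-product covariate (0/1) for the misspecification scenarios.
spec_hidden_term <- function(frame, spec) {
  f <- spec$misspec$flags
  frame[[f[1]]] * frame[[f[2]]]
}

# True treatment-assignment probabilities (n x 4) for a covariate frame.
spec_treatment_probs <- function(frame, spec) {
  X <- spec_design(frame, spec)
  B <- cbind(spec$treatment_coefs$t1, spec$treatment_coefs$t2,
             spec$treatment_coefs$t3)
  eta <- X %*% B
  if (spec$misspec_scenario %in% c("propensity_wrong", "both_wrong")) {
    h <- spec_hidden_term(frame, spec)
    eta <- eta + outer(h, spec$misspec$treatment)
  }
  full <- cbind(0, eta, deparse.level = 0)
  m <- full[cbind(seq_len(nrow(full)), max.col(full, ties.method = "first"))]
  e <- exp(full - m)
  p <- e / rowSums(e)
  colnames(p) <- as.character(0:3)
  p
}

# True outcome success probability b_i(L) for arm i (0..3) on a frame.
spec_outcome_prob <- function(frame, spec, arm) {
  X <- spec_design(frame, spec)
  eta <- drop(X %*% spec$outcome_coefs$alpha1)
  if (arm > 0) {
    a <- paste0("t", arm)
    eta <- eta + spec$outcome_coefs$alpha2[arm] +
      drop(X[, -1, drop = FALSE] %*% spec$outcome_coefs$alpha3[[a]])
  }
  if (spec$misspec_scenario %in% c("outcome_wrong", "both_wrong")) {
    h <- spec_hidden_term(frame, spec)
    eta <- eta + h * spec$misspec$outcome_main
    if (arm == 3) eta <- eta + h * spec$misspec$outcome_arm3
  }
  stats::plogis(eta)
}

#' Read a cohort specification from a YAML config file
#'
#' The file mirrors the [cohort_spec()] arguments: scalar `n_patients` and
#' `seed`, mappings `factors` (level: probability), `flags`, sparse coefficient
#' mappings under `treatment_coefs` (`t1`..`t3`) and `outcome_coefs`
#' (`alpha1`, `alpha2`, `alpha3`), and optional `misspec_scenario`/`misspec`/
#' `continuous` blocks.
#'
#' @param path path to a YAML file.
#' @return a `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  to_vec <- function(x) if (is.null(x)) NULL else unlist(x)
  oc <- y$outcome_coefs %||% list()
  cohort_spec(
    n_patients = y$n_patients,
    factors = lapply(y$factors, unlist),
    flags = to_vec(y$flags) %||% numeric(0),
    treatment_coefs = lapply(y$treatment_coefs %||% list(), unlist),
    outcome_coefs = list(alpha1 = to_vec(oc$alpha1),
                         alpha2 = to_vec(oc$alpha2) %||% numeric(3),
                         alpha3 = lapply(oc$alpha3 %||% list(), unlist)),
    misspec_scenario = y$misspec_scenario %||% "none",
    misspec = if (!is.null(y$misspec))
      list(flags = unlist(y$misspec$flags),
           treatment = to_vec(y$misspec$treatment),
           outcome_main = y$misspec$outcome_main %||% 0,
           outcome_arm3 = y$misspec$outcome_arm3 %||% 0),
    continuous = y$continuous,
    seed = y$seed %||% 1L
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  n_patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  factors:", paste(names(x$factors), collapse = ", "), "\n")
  cat("  flags:", paste(names(x$flags), collapse = ", "), "\n")
  cat("  misspec_scenario:", x$misspec_scenario, "\n")
  invisible(x)
}
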