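# Outcome stage: logistic model with treatment main effects and
# treatment-by-covariate interactions, counterfactual predictions b_i(L),
# and the plug-in g-formula (standardized) means.

# Outcome design: covariate block, three treatment dummies, and (optionally)
# dummy-by-covariate products over the non-intercept columns.
build_outcome_design <- function(L, A, interactions = TRUE) {
  n <- nrow(L)
  Td <- matrix(0, n, 3, dimnames = list(NULL, paste0("T", 1:3)))
  for (i in 1:3) Td[, i] <- as.numeric(A == i)
  X <- cbind(L, Td)
  if (interactions && ncol(L) > 1) {
    Lni <- L[, -1, drop = FALSE]
    for (i in 1:3) {
      M <- Lni * Td[, i]
      colnames(M) <- paste0("T", i, ":", colnames(Lni))
      X <- cbind(X, M)
    }
  }
  X
}

#' Fit the outcome logistic regression
#'
#' Maximum-likelihood logistic regression of the five-year survival indicator
#' on the covariates, three treatment indicators (treatment 0 reference) and,
#' by default, all treatment-by-covariate interactions:
#' logit P(Y=1|A,L) = alpha1' L + alpha2' A + alpha3' AL.
#' Fitted by the same Newton-Raphson solver and tolerances as the propensity
#' model (binary case).
#'
#' @param mat an [analysis_matrix()].
#' @param interactions include the treatment-by-covariate block (default
#'   `TRUE`).
#' @param ridge optional L2 penalty, the recommended fallback under
#'   separation.
#' @param max_iter Newton iteration cap.
#' @param init optional coefficient warm start (full coefficient vector),
#'   e.g. from a fit on the full data when refitting bootstrap resamples.
#' @return object of class `outcome_fit` with the coefficient partition
#'   `alpha1` (covariates incl. intercept), `alpha2` (treatment main
#'   effects), `alpha3` (3 x (p-1) interaction matrix, or `NULL`), plus
#'   `loglik`, `converged`, `n_iter`, `interactions`, `encoding`.
#' @export
fit_outcome <- function(mat, interactions = TRUE, ridge = 0, max_iter = 100L,
                        init = NULL) {
  if (length(unique(mat$Y)) < 2)
    stop_drc("drc_estimation",
             "outcome has a single class; the logistic model is undefined")
  X <- build_outcome_design(mat$L, mat$A, interactions)
  if (ridge == 0) {
    qr_rank <- qr(X)$rank
    if (qr_rank < ncol(X))
      stop_drc("drc_estimation",
               "outcome design is rank deficient (rank %d < %d columns)",
               qr_rank, ncol(X))
  }
  fit <- mlogit_newton(X, as.integer(mat$Y), K = 2L, ridge = ridge,
                       max_iter = max_iter, beta_init = init)
  if (!fit$converged)
    stop_drc("drc_estimation",
             paste0("outcome fit did not converge in %d iterations ",
                    "(score norm %.3g); consider a small ridge penalty"),
             fit$n_iter, fit$score_norm)
  if (ridge == 0 && max(abs(fit$beta)) > 15)
    stop_drc("drc_estimation",
             paste0("separation detected in the outcome model ",
                    "(|coefficient| > 15); refit with a small ridge ",
                    "penalty, e.g. ridge = 1e-4"))
  cf <- drop(fit$beta)
  p <- ncol(mat$L)
  alpha1 <- cf[seq_len(p)]
  alpha2 <- cf[p + 1:3]
  alpha3 <- NULL
  if (interactions && p > 1) {
    ni <- colnames(mat$L)[-1]
    alpha3 <- matrix(cf[(p + 4):length(cf)], nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("T", 1:3), ni))
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 loglik = fit$loglik, converged = fit$converged,
                 n_iter = fit$n_iter, interactions = interactions,
                 encoding = mat$encoding,
                 l_columns = colnames(mat$L)),
            class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat("<outcome_fit> p =", length(x$alpha1), "+", length(x$alpha2),
      if (!is.null(x$alpha3)) paste("+", length(x$alpha3)) else "",
      " loglik =", format(x$loglik), "\n")
  invisible(x)
}

#' Counterfactual success probabilities b_i(L)
#'
#' Evaluates the fitted outcome logistic with treatment set to `treatment`
#' for every row, regardless of the treatment actually received.
#'
#' @param fit an `outcome_fit`.
#' @param L covariate design matrix with the columns the fit was estimated
#'   on.
#' @param treatment a single treatment index 0..3.
#' @return numeric vector of per-row probabilities in (0, 1).
#' @export
predict_b <- function(fit, L, treatment) {
  if (!(length(treatment) == 1 && treatment %in% 0:3))
    stop_drc("drc_argument", "treatment must be a single index in 0..3")
  if (!identical(colnames(L), fit$l_columns))
    stop_drc("drc_encoding",
             "design columns do not match the fitted encoding")
  eta <- drop(L %*% fit$alpha1)
  if (treatment > 0) {
    eta <- eta + fit$alpha2[treatment]
    if (!is.null(fit$alpha3))
      eta <- eta + drop(L[, -1, drop = FALSE] %*% fit$alpha3[treatment, ])
  }
  stats::plogis(eta)
}

#' Standardized (plug-in g-formula) counterfactual means
#'
#' For each treatment, the average of [predict_b()] over all rows:
#' (1/n) sum_k b_i(L_k).
#'
#' @param fit an `outcome_fit`.
#' @param L covariate design matrix.
#' @return named numeric vector of four standardized means, each in (0, 1).
#' @export
standardized_means <- function(fit, L) {
  vapply(0:3, function(i) mean(predict_b(fit, L, i)), numeric(1)) |>
    stats::setNames(as.character(0:3))
}
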