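# Propensity stage: multinomial-logit treatment model, assignment
# probabilities, Horvitz-Thompson IP-weighted counterfactual means, and
# covariate balance in the weighted pseudo-population.

#' Fit the multinomial-logit propensity model
#'
#' Maximum-likelihood fit of the baseline-category logit
#' log[P(A=i|L)/P(A=0|L)] = beta_i' L, i = 1..3, by Newton-Raphson with
#' step-halving. Convergence is declared when the maximum absolute score
#' falls below 1e-8 or the parameter change below 1e-10, so refits are
#' deterministic and invariant to row order.
#'
#' @param mat an [analysis_matrix()].
#' @param ridge optional L2 penalty (default 0 = plain MLE); a small ridge
#'   (e.g. 1e-4) is the recommended fallback when separation is detected.
#' @param max_iter Newton iteration cap.
#' @param init optional coefficient warm start (p x 3 matrix), e.g. from a
#'   fit on the full data when refitting bootstrap resamples.
#' @return object of class `propensity_fit`: `betas` (p x 3 coefficient
#'   matrix, treatment 0 reference), `loglik`, `converged`, `n_iter`,
#'   `encoding`.
#' @export
fit_multinomial <- function(mat, ridge = 0, max_iter = 100L, init = NULL) {
  counts <- tabulate(mat$A + 1L, 4L)
  if (any(counts == 0))
    stop_drc("drc_estimation", "empty treatment arm(s): %s",
             paste(which(counts == 0) - 1L, collapse = ", "))
  if (ridge == 0) {
    qr_rank <- qr(mat$L)$rank
    if (qr_rank < ncol(mat$L))
      stop_drc("drc_estimation",
               "covariate design is rank deficient (rank %d < %d columns)",
               qr_rank, ncol(mat$L))
  }
  fit <- mlogit_newton(mat$L, mat$A, K = 4L, ridge = ridge,
                       max_iter = max_iter, beta_init = init)
  if (!fit$converged)
    stop_drc("drc_estimation",
             paste0("propensity fit did not converge in %d iterations ",
                    "(score norm %.3g); consider a small ridge penalty"),
             fit$n_iter, fit$score_norm)
  if (ridge == 0 && max(abs(fit$beta)) > 15)
    stop_drc("drc_estimation",
             paste0("separation detected in the propensity model ",
                    "(|coefficient| > 15); refit with a small ridge ",
                    "penalty, e.g. ridge = 1e-4"))
  structure(list(betas = structure(fit$beta,
                                   dimnames = list(colnames(mat$L),
                                                   c("t1", "t2", "t3"))),
                 loglik = fit$loglik, converged = fit$converged,
                 n_iter = fit$n_iter, encoding = mat$encoding),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit> p =", nrow(x$betas),
      " loglik =", format(x$loglik), " iters =", x$n_iter, "\n")
  invisible(x)
}

#' Predicted treatment-assignment probabilities
#'
#' Evaluates the fitted softmax pi_i(L) for every row, with max-subtraction
#' for overflow safety. Rows are nonnegative and sum to one.
#'
#' @param fit a `propensity_fit`.
#' @param L covariate design matrix with the same columns the fit was
#'   estimated on.
#' @return n x 4 matrix of probabilities, columns `"0"`..`"3"`.
#' @export
predict_probs <- function(fit, L) {
  if (!identical(colnames(L), rownames(fit$betas)))
    stop_drc("drc_encoding",
             "design columns do not match the fitted encoding")
  p <- mlogit_probs(L, fit$betas)
  colnames(p) <- as.character(0:3)
  p
}

#' Horvitz-Thompson IP-weighted counterfactual means
#'
#' For each treatment i, (1/n) * sum over all patients of
#' I{A_k = i} Y_k / pi_i(L_k). The estimator is unnormalized, so values may
#' fall outside [0, 1] in finite samples; they are reported as-is.
#'
#' @param mat an [analysis_matrix()].
#' @param probs n x 4 assignment probability matrix from [predict_probs()].
#' @param floor positivity warning threshold: fitted own-arm probabilities
#'   below it trigger a warning (default 1e-3). Exact zeros are an error.
#' @return named numeric vector of four IP-weighted means.
#' @export
ht_means <- function(mat, probs, floor = 1e-3) {
  n <- length(mat$Y)
  own <- probs[cbind(seq_len(n), mat$A + 1L)]
  if (any(own == 0))
    stop_drc("drc_positivity",
             "zero fitted probability for the received treatment at row(s): %s",
             paste(utils::head(which(own == 0), 10), collapse = ", "))
  if (any(own < floor))
    warning(sprintf("%d fitted own-arm probabilities below %g (near-positivity violation)",
                    sum(own < floor), floor))
  vapply(0:3, function(i)
    sum((mat$A == i) * mat$Y / probs[, i + 1L]) / n,
    numeric(1)) |> stats::setNames(as.character(0:3))
}

#' Covariate balance in the IP-weighted pseudo-population
#'
#' For every covariate and every pair of treatment arms, the standardized
#' mean difference between the weighted arm distributions: difference of
#' (normalized) weighted means divided by the pooled weighted standard
#' deviation, sqrt((v_i + v_j)/2). A multi-level categorical is summarized
#' by the indicator column with the largest absolute SMD (signed value
#' reported); per-column values are kept in the `"columns"` attribute.
#'
#' @param mat an [analysis_matrix()].
#' @param probs n x 4 assignment probability matrix; pass a matrix of ones
#'   (scaled to rows summing to 4) for unweighted SMDs, or use
#'   `weights = NULL`.
#' @param weights optional n-vector of weights overriding `1/probs`; when
#'   `NULL` (default) each arm-i subject gets weight `1/pi_i(L)`.
#' @return data.frame with one row per covariate and one column per arm pair
#'   (`"0_vs_1"`, ...); attribute `"columns"` holds the per-design-column
#'   SMDs.
#' @export
smd_balance <- function(mat, probs = NULL, weights = NULL) {
  n <- length(mat$Y)
  if (is.null(weights)) {
    if (is.null(probs))
      stop_drc("drc_argument", "provide probs or weights")
    weights <- 1 / probs[cbind(seq_len(n), mat$A + 1L)]
  }
  cols <- setdiff(colnames(mat$L), "(Intercept)")
  pairs <- utils::combn(0:3, 2)
  wstats <- function(x, w) {
    sw <- sum(w)
    m <- sum(w * x) / sw
    v <- sum(w * (x - m)^2) / sw
    c(m, v)
  }
  col_smd <- matrix(NA_real_, length(cols), ncol(pairs),
                    dimnames = list(cols, apply(pairs, 2, function(p)
                      paste0(p[1], "_vs_", p[2]))))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ri <- mat$A == i; rj <- mat$A == j
    for (cl in cols) {
      si <- wstats(mat$L[ri, cl], weights[ri])
      sj <- wstats(mat$L[rj, cl], weights[rj])
      pooled <- sqrt((si[2] + sj[2]) / 2)
      col_smd[cl, k] <- if (pooled == 0) {
        if (si[1] == sj[1]) 0 else NA_real_
      } else (si[1] - sj[1]) / pooled
    }
  }
  cov_rows <- lapply(names(mat$encoding), function(nm) {
    cc <- mat$encoding[[nm]]$columns
    vapply(seq_len(ncol(pairs)), function(k) {
      v <- col_smd[cc, k]
      if (all(is.na(v))) return(NA_real_)
      v[which.max(abs(v))]
    }, numeric(1))
  })
  out <- as.data.frame(do.call(rbind, cov_rows))
  names(out) <- colnames(col_smd)
  out <- cbind(covariate = names(mat$encoding), out)
  rownames(out) <- NULL
  attr(out, "columns") <- col_smd
  out
}
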