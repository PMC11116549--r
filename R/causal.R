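# Doubly robust combination of the two nuisance models, and the derived
# effect measures: risk differences, relative percent changes, risk ratios,
# and the additive drug-drug interaction.

#' Doubly robust (AIPW) counterfactual means
#'
#' For each treatment i, the augmented inverse-probability-weighted mean
#' (1/n) sum_k [ b_i(L_k) + I{A_k = i} / pi_i(L_k) * (Y_k - b_i(L_k)) ].
#' The estimator reduces exactly to the standardized mean when the
#' augmentation residuals vanish and to the Horvitz-Thompson mean when
#' b_i is identically zero. Values are not clipped to [0, 1]; out-of-range
#' values (a finite-sample weighting artifact) trigger a warning.
#'
#' @param mat an [analysis_matrix()].
#' @param probs n x 4 assignment probability matrix ([predict_probs()]).
#' @param bhat n x 4 matrix of outcome predictions, column i+1 holding
#'   b_i(L) ([predict_b()] per arm).
#' @return named numeric vector of four DR means.
#' @export
dr_means <- function(mat, probs, bhat) {
  n <- length(mat$Y)
  if (!is.matrix(probs) || nrow(probs) != n || ncol(probs) != 4 ||
      !is.matrix(bhat) || nrow(bhat) != n || ncol(bhat) != 4)
    stop_drc("drc_alignment",
             "probs and bhat must be n x 4 matrices aligned with the data")
  own <- probs[cbind(seq_len(n), mat$A + 1L)]
  if (any(own == 0))
    stop_drc("drc_positivity",
             "zero fitted probability for the received treatment at row(s): %s",
             paste(utils::head(which(own == 0), 10), collapse = ", "))
  out <- vapply(0:3, function(i) {
    ind <- as.numeric(mat$A == i)
    mean(bhat[, i + 1L] + ind / probs[, i + 1L] * (mat$Y - bhat[, i + 1L]))
  }, numeric(1))
  names(out) <- as.character(0:3)
  if (any(out < 0 | out > 1))
    warning("doubly robust mean(s) outside [0, 1] (finite-sample weighting artifact)")
  out
}

#' Run the full estimation pipeline on one cohort
#'
#' Fits the propensity and outcome models and returns the three sets of
#' counterfactual means: IP-weighted (Horvitz-Thompson), standardized
#' (plug-in g-formula) and doubly robust.
#'
#' @param mat an [analysis_matrix()].
#' @param interactions include treatment-by-covariate interactions in the
#'   outcome model (default `TRUE`).
#' @param ridge L2 penalty passed to both fits (default 0).
#' @param positivity_floor warning threshold for small own-arm probabilities.
#' @param warm_start optional list with elements `propensity` and `outcome`
#'   holding coefficient warm starts for the two fits (used by the
#'   bootstrap to speed up resample refits).
#' @return object of class `counterfactual_set`: `means_ip`, `means_st`,
#'   `means_dr` (four values each), `n`, and the two fits.
#' @export
counterfactual_set <- function(mat, interactions = TRUE, ridge = 0,
                               positivity_floor = 1e-3, warm_start = NULL) {
  pfit <- fit_multinomial(mat, ridge = ridge,
                          init = warm_start$propensity)
  ofit <- fit_outcome(mat, interactions = interactions, ridge = ridge,
                      init = warm_start$outcome)
  probs <- predict_probs(pfit, mat$L)
  bhat <- vapply(0:3, function(i) predict_b(ofit, mat$L, i),
                 numeric(length(mat$Y)))
  bhat <- matrix(bhat, ncol = 4)
  structure(
    list(means_ip = ht_means(mat, probs, floor = positivity_floor),
         means_st = stats::setNames(colMeans(bhat), as.character(0:3)),
         means_dr = dr_means(mat, probs, bhat),
         n = length(mat$Y),
         propensity_fit = pfit, outcome_fit = ofit),
    class = "counterfactual_set")
}

#' @export
print.counterfactual_set <- function(x, ...) {
  cat("<counterfactual_set> n =", x$n, "\n")
  m <- rbind(IP = x$means_ip, ST = x$means_st, DR = x$means_dr)
  print(round(m, 4))
  invisible(x)
}

#' Effect measures from four counterfactual means
#'
#' Returns, taking the combined arm (3) as the index treatment:
#' risk differences `rds` RD_s = mean_3 - mean_s for s = 0, 1, 2; relative
#' percent increases `rel_pct` = 100 * RD_s / mean_s; risk ratios
#' `rrs` = mean_3 / mean_s; and the additive drug-drug interaction
#' `ddi` = mean_3 - mean_2 - mean_1 + mean_0.
#'
#' @param means numeric vector of four counterfactual means (arms 0..3).
#' @return object of class `effect_set` (a list with `rds`, `rel_pct`,
#'   `ddi`, `rrs`, `means`). Entries with a zero denominator are `NA`.
#' @export
effects <- function(means) {
  if (length(means) != 4 || !all(is.finite(means)))
    stop_drc("drc_argument", "means must be four finite values")
  means <- unname(means)
  cmp <- c("vs_none", "vs_memantine", "vs_donepezil")
  rds <- stats::setNames(means[4] - means[1:3], cmp)
  denom_ok <- means[1:3] != 0
  rel <- ifelse(denom_ok, 100 * rds / means[1:3], NA_real_)
  rrs <- ifelse(denom_ok, means[4] / means[1:3], NA_real_)
  structure(list(rds = rds,
                 rel_pct = stats::setNames(rel, cmp),
                 ddi = means[4] - means[3] - means[2] + means[1],
                 rrs = stats::setNames(rrs, cmp),
                 means = stats::setNames(means, as.character(0:3))),
            class = "effect_set")
}

#' @export
print.effect_set <- function(x, ...) {
  cat("<effect_set>\n")
  cat("  RD: ", paste(sprintf("%s=%.3f", names(x$rds), x$rds),
                      collapse = "  "), "\n")
  cat("  RR: ", paste(sprintf("%s=%.3f", names(x$rrs), x$rrs),
                      collapse = "  "), "\n")
  cat("  DDI:", sprintf("%.3f", x$ddi), "\n")
  invisible(x)
}
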