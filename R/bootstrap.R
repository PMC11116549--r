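# Nonparametric bootstrap of the full estimation pipeline, with percentile
# and Bonferroni-adjusted confidence intervals.

#' Empirical percentile interval
#'
#' Percentiles by linear interpolation between the closest order statistics
#' (the type-7 quantile definition: at probability p the value is
#' x_(h) + (h - floor(h)) (x_(h+1) - x_(h)) with h = (n-1) p + 1).
#'
#' @param samples numeric vector (at least 2 finite values).
#' @param level_lo,level_hi lower and upper probability levels.
#' @return numeric length-2 interval.
#' @export
percentile_ci <- function(samples, level_lo = 0.025, level_hi = 0.975) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2)
    stop_drc("drc_argument", "need at least 2 finite samples")
  unname(stats::quantile(samples, c(level_lo, level_hi), type = 7))
}

#' Bootstrap the doubly robust pipeline
#'
#' Resamples patients with replacement to the original sample size, refits
#' both the propensity and the outcome model on every replicate, and records
#' eight statistics: the four DR counterfactual means, the three risk
#' differences against the combined arm, and the additive drug-drug
#' interaction. Replicates with an empty treatment arm or a failed fit are
#' counted in `failed_reps` and excluded from the percentiles (never
#' redrawn, which would bias the distribution); more than 10% failures is
#' an error.
#'
#' Confidence intervals: naive 95% percentile intervals for all eight
#' statistics; Bonferroni-adjusted intervals using a family of k = 4 for the
#' means (levels 0.00625 / 0.99375) and k = 3 for the risk differences
#' (0.05/3 split two-sided). The interaction gets a naive interval only (its
#' Bonferroni slot repeats the naive interval).
#'
#' @param mat an [analysis_matrix()].
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed (one stream drives all resampling).
#' @param interactions,ridge passed to the model fits.
#' @param level nominal two-sided level for the naive intervals (0.95).
#' @return object of class `bootstrap_result`: `n_reps`, `replicates`
#'   (B_ok x 8 matrix), `estimate` (the 8 statistics on the original data),
#'   `naive_ci` and `bonferroni_ci` (2 x 8 matrices), `failed_reps`,
#'   `failure_reasons`, `seed`.
#' @export
bootstrap_effects <- function(mat, B = 500, seed = 1L, interactions = TRUE,
                              ridge = 0, level = 0.95) {
  if (B < 2) stop_drc("drc_argument", "B must be at least 2")
  n <- length(mat$Y)

  cs_full <- counterfactual_set(mat, interactions = interactions,
                                ridge = ridge, positivity_floor = 0)
  ofit <- cs_full$outcome_fit
  warm <- list(
    propensity = cs_full$propensity_fit$betas,
    outcome = c(ofit$alpha1, ofit$alpha2,
                if (!is.null(ofit$alpha3)) as.vector(t(ofit$alpha3))))
  stat8 <- function(m, ws = warm) {
    cs <- counterfactual_set(m, interactions = interactions, ridge = ridge,
                             positivity_floor = 0, warm_start = ws)
    ef <- effects(cs$means_dr)
    c(cs$means_dr, ef$rds, ddi = ef$ddi)
  }
  ef_full <- effects(cs_full$means_dr)
  est <- c(cs_full$means_dr, ef_full$rds, ddi = ef_full$ddi)
  stat_names <- c(paste0("mean_", 0:3),
                  paste0("rd_", names(est)[5:7]), "ddi")
  names(est) <- stat_names

  reps <- matrix(NA_real_, B, 8, dimnames = list(NULL, stat_names))
  reasons <- character(0)
  local_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      sub <- am_subset(mat, idx)
      if (any(tabulate(sub$A + 1L, 4L) == 0)) {
        reasons <- c(reasons, "empty arm")
        next
      }
      val <- tryCatch(suppressWarnings(stat8(sub)),
                      error = function(e) conditionMessage(e))
      if (is.character(val)) {
        reasons <- c(reasons, val)
      } else {
        reps[b, ] <- val
      }
    }
  })
  ok <- stats::complete.cases(reps)
  failed <- sum(!ok)
  if (failed > 0.10 * B)
    stop_drc("drc_inference",
             paste0("%d of %d bootstrap replicates failed (> 10%%); ",
                    "consider a larger sample, fewer strata, or a ridge ",
                    "penalty"),
             failed, B)
  reps_ok <- reps[ok, , drop = FALSE]

  a <- (1 - level) / 2
  naive <- vapply(seq_len(8), function(j)
    percentile_ci(reps_ok[, j], a, 1 - a), numeric(2))
  a4 <- (1 - level) / 4 / 2
  a3 <- (1 - level) / 3 / 2
  bonf <- naive
  for (j in 1:4) bonf[, j] <- percentile_ci(reps_ok[, j], a4, 1 - a4)
  for (j in 5:7) bonf[, j] <- percentile_ci(reps_ok[, j], a3, 1 - a3)
  dimnames(naive) <- dimnames(bonf) <- list(c("lower", "upper"), stat_names)

  structure(list(n_reps = B, replicates = reps_ok, estimate = est,
                 naive_ci = naive, bonferroni_ci = bonf,
                 failed_reps = failed, failure_reasons = reasons,
                 seed = as.integer(seed), level = level),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> B =", x$n_reps, " failed =", x$failed_reps, "\n")
  tab <- rbind(estimate = x$estimate, x$naive_ci, x$bonferroni_ci)
  rownames(tab) <- c("estimate", "naive_lower", "naive_upper",
                     "bonferroni_lower", "bonferroni_upper")
  print(round(tab, 4))
  invisible(x)
}
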