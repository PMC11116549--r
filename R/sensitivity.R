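# E-value sensitivity analysis on the risk-ratio scale, and population-level
# extrapolation of lives extended.

# VanderWeele-Ding E-value transform for RR >= 1.
# Note: the transform is RR + sqrt(RR * (RR - 1)); the version with
# sqrt(RR * (1 - RR)) sometimes seen in print is imaginary for RR > 1 and is
# a typographical slip -- this form reproduces the standard published values
# (e.g. RR 1.064 -> 1.325, RR 1.085 -> 1.389).
evalue_transform <- function(rr) rr + sqrt(rr * (rr - 1))

#' E-value for unmeasured confounding
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need to have with both the
#' treatment and the outcome to fully explain away an observed risk ratio.
#' For RR < 1 the ratio (and its interval) is inverted before the transform,
#' per the standard convention. The confidence-interval E-value is computed
#' from the CI bound closer to the null; it is 1 when the interval crosses 1.
#'
#' @param rr observed risk ratio (> 0).
#' @param ci optional length-2 confidence interval for `rr`.
#' @return object of class `evalue_result`: `rr`, `rr_ci`, `evalue_point`,
#'   `evalue_ci` (`NA` when no interval is supplied).
#' @export
evalue <- function(rr, ci = NULL) {
  if (!is.finite(rr) || rr <= 0)
    stop_drc("drc_domain", "risk ratio must be a positive number")
  orig_rr <- rr
  orig_ci <- ci
  if (rr < 1) {
    rr <- 1 / rr
    if (!is.null(ci)) ci <- rev(1 / ci)
  }
  point <- evalue_transform(rr)
  eci <- NA_real_
  if (!is.null(ci)) {
    if (length(ci) != 2 || any(!is.finite(ci)) || any(ci <= 0))
      stop_drc("drc_domain", "ci must be two positive finite bounds")
    eci <- if (ci[1] <= 1 && ci[2] >= 1) 1 else evalue_transform(ci[1])
  }
  structure(list(rr = orig_rr, rr_ci = orig_ci,
                 evalue_point = point, evalue_ci = eci),
            class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, ...) {
  cat(sprintf("<evalue_result> RR = %.3f  E-value = %.3f",
              x$rr, x$evalue_point))
  if (!is.na(x$evalue_ci)) cat(sprintf("  E-value(CI) = %.3f", x$evalue_ci))
  cat("\n")
  invisible(x)
}

#' Risk ratios of the combined arm against each comparator
#'
#' RR_s = mean_3 / mean_s for s = 0, 1, 2, at full precision (round only for
#' reporting).
#'
#' @param means four counterfactual means (arms 0..3).
#' @return named numeric vector of three risk ratios; `NA` where the
#'   comparator mean is zero.
#' @export
risk_ratios_from_means <- function(means) {
  if (length(means) != 4)
    stop_drc("drc_argument", "means must have length 4")
  means <- unname(means)
  out <- ifelse(means[1:3] != 0, means[4] / means[1:3], NA_real_)
  stats::setNames(out, c("vs_none", "vs_memantine", "vs_donepezil"))
}

#' Population-level extrapolation of lives extended
#'
#' Per comparator group, the number of prevalent patients whose five-year
#' survival the combined treatment would extend:
#' count_s = population_size x proportion_s x RD_s, rounded to the nearest
#' `round_to` (half up). The total is the sum of the rounded group counts;
#' a projection to a future population scales the *unrounded* total by the
#' population ratio before rounding.
#'
#' @param population_size current number of prevalent patients.
#' @param group_proportions three fractions of that population on each
#'   comparator strategy (no drug, Memantine, Donepezil); must lie in [0, 1]
#'   and sum to at most 1.
#' @param rds three risk differences of the combined arm against each
#'   comparator. Negative values (a harm scenario) are allowed with a
#'   warning.
#' @param projected_population optional future population size for the
#'   projection.
#' @param round_to rounding unit for reported counts (default 1000).
#' @return list with `per_group` (named rounded counts), `total`,
#'   `per_group_unrounded`, `total_unrounded`, and `projection` (`NA`
#'   without `projected_population`).
#' @export
population_extrapolation <- function(population_size, group_proportions, rds,
                                     projected_population = NULL,
                                     round_to = 1000) {
  if (length(group_proportions) != 3 || length(rds) != 3)
    stop_drc("drc_argument", "need three group proportions and three RDs")
  if (any(group_proportions < 0 | group_proportions > 1) ||
      sum(group_proportions) > 1 + 1e-12)
    stop_drc("drc_argument",
             "group proportions must lie in [0, 1] and sum to at most 1")
  if (any(rds < 0))
    warning("negative risk difference(s): extrapolated counts are negative (harm scenario)")
  raw <- population_size * unname(group_proportions) * unname(rds)
  rounded <- round_half_up(raw / round_to) * round_to
  nm <- c("no_drug", "memantine", "donepezil")
  projection <- NA_real_
  if (!is.null(projected_population))
    projection <- round_half_up(
      sum(raw) * projected_population / population_size / round_to) * round_to
  list(per_group = stats::setNames(rounded, nm),
       total = sum(rounded),
       per_group_unrounded = stats::setNames(raw, nm),
       total_unrounded = sum(raw),
       projection = projection)
}
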