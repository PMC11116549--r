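---
title: "Doubly robust estimation of multi-arm treatment effects on five-year survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubly robust estimation of multi-arm treatment effects on five-year survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

`drcausal` estimates counterfactual five-year survival probabilities
$E(Y^{a=i})$, $i = 0,\dots,3$, under four mutually exclusive treatment
strategies for Alzheimer's disease patients — no drug treatment, Memantine
monotherapy, Donepezil monotherapy, and the Donepezil+Memantine combination —
from an observational patient-level table with outcome $Y$ (the five-year
survival indicator), treatment $A \in \{0,1,2,3\}$, and confounders $L$
(age group at diagnosis, sex, race, marital status, and six comorbidity
flags).

Three estimators are computed side by side:

1. **IP weighting (Horvitz–Thompson).** A baseline-category multinomial
   logit $\log[P(A=i \mid L)/P(A=0 \mid L)] = \beta_i^\top L$ supplies
   assignment probabilities $\hat\pi_i(L)$, and
   $\hat E_{IP}(Y^{a=i}) = \frac1n \sum_k I\{A_k = i\}\, Y_k / \hat\pi_i(L_k)$.
   The estimator is deliberately unnormalized, so individual values can fall
   outside $[0,1]$ in finite samples; they are reported as-is with a warning
   rather than clipped, because the doubly robust combination depends on the
   raw algebra.
2. **Standardization (plug-in g-formula).** A logistic outcome model
   $\operatorname{logit} P(Y = 1 \mid A, L) = \alpha_1^\top L + \alpha_2^\top A
   + \alpha_3^\top A L$ — three treatment indicators with reference arm 0 and,
   by default, a full block of treatment-by-covariate interactions, so the
   arm-specific response surfaces are free — yields counterfactual
   predictions $\hat b_i(L)$, and
   $\hat E_{ST}(Y^{a=i}) = \frac1n \sum_k \hat b_i(L_k)$.
3. **Doubly robust (AIPW).**
   $\hat E_{DR}(Y^{a=i}) = \frac1n \sum_k \big[ \hat b_i(L_k) +
   \frac{I\{A_k=i\}}{\hat\pi_i(L_k)} (Y_k - \hat b_i(L_k)) \big]$,
   consistent when *either* nuisance model is correctly specified. Two
   algebraic reduction identities are enforced by tests at $10^{-12}$:
   with $\hat b_i \equiv 0$ the DR mean equals the Horvitz–Thompson mean,
   and with residual-free predictions it equals the standardized mean.

Derived measures take the combination arm as index: risk differences
$RD_s = E(Y^{a=3}) - E(Y^{a=s})$, relative increases $100\,RD_s/E(Y^{a=s})$,
risk ratios $E(Y^{a=3})/E(Y^{a=s})$, and the additive drug–drug interaction
$DDI = E(Y^{a=3}) - E(Y^{a=2}) - E(Y^{a=1}) + E(Y^{a=0})$, the departure of
the joint effect from additivity of the monotherapy effects on the risk
difference scale.

## Model fitting and numerical choices

Both nuisance models are fitted by one Newton–Raphson solver on the full
likelihood (the binary outcome model is the two-class case), with
step-halving, convergence on the score norm ($\max |s| < 10^{-8}$) or a
vanishing parameter step ($< 10^{-10}$). This makes every fit deterministic
and invariant to row order at the tolerance of the convergence criterion,
which the bootstrap and the test suite rely on. The solver is cross-checked
in the tests against `nnet::multinom` and `stats::glm.fit` on the same
designs.

Error contracts are explicit: an empty treatment arm, a rank-deficient
design, a single-class outcome, or non-convergence each raise a typed error.
Separation (any $|\hat\beta| > 15$ in an unpenalized fit) is an error that
recommends the configurable fallback: a small L2 penalty
(`ridge = 1e-4`), which leaves common coefficients essentially untouched but
keeps rare-cell coefficients finite. At the study scale ($n = 12{,}744$ with
a seven-level race factor whose rarest level has $\approx 20$ patients and
an interaction-rich outcome design), unpenalized maximum likelihood
genuinely separates for many realizations, so study-scale analyses in the
tests and the acceptance script use `ridge = 1e-4` throughout; desk-scale
fixtures use the plain MLE.

Categorical covariates are reference-coded ("drop first"); characters are
ordered by decreasing frequency so the reference level is the most
prevalent, while explicit factor levels are respected. "Unknown" is a valid
level, not a missing value. A continuous covariate, when present, enters
with its square — the cohort emulated here is fully categorical, so this
path exists as a configuration switch only.

Positivity: fitted own-arm probabilities of exactly zero are an error;
probabilities below $10^{-3}$ trigger a warning, and no trimming is done by
default.

## Balance diagnostics

`smd_balance()` reports, for each covariate and each of the six arm pairs,
the standardized mean difference in the weighted pseudo-population:
difference of weight-normalized arm means over the pooled weighted standard
deviation $\sqrt{(v_i + v_j)/2}$. A multi-level categorical is summarized by
its worst indicator column (the signed value of the largest absolute SMD),
so a ten-covariate analysis yields a 10 x 6 table; per-column values remain
available as an attribute. The max-over-indicators convention is a package
choice made so that one number is reported per covariate, including the
seven-level race factor; it is conservative relative to averaging.

## Bootstrap inference

`bootstrap_effects()` resamples patients with replacement to the original
$n$, refits *both* nuisance models per replicate (warm-started at the
full-data coefficients, which changes nothing at the convergence tolerance
but roughly halves the iteration count), and records eight statistics: four
DR means, three risk differences, and the DDI. Percentiles use linear
interpolation between order statistics (the type-7 quantile rule, fixed and
documented; on samples $1..100$ the 2.5th/97.5th percentiles are
$3.475$ and $97.525$). Naive intervals are 2.5/97.5 percentile; Bonferroni
adjustment divides the error rate by the family size — $k = 4$ for the means
family (levels $0.00625$ and $0.99375$) and $k = 3$ for the risk-difference
family; the DDI is reported with a naive interval only. Replicates with an
empty arm or a failed fit are excluded and counted — never redrawn, which
would bias the percentile distribution — and more than 10% failures is an
error suggesting a larger sample or the ridge fallback.

## Sensitivity analysis and extrapolation

The E-value is the minimum risk-ratio strength of association an unmeasured
confounder would need with both treatment and outcome to explain an observed
ratio away: $RR + \sqrt{RR(RR-1)}$ for $RR \ge 1$, with protective ratios
inverted first. (The variant with $\sqrt{RR(1-RR)}$ occasionally seen in
print is imaginary for $RR > 1$; the implemented form reproduces the
standard published values, e.g. $1.064 \to 1.325$ and $1.085 \to 1.389$.)
The confidence-interval E-value transforms the bound closer to the null and
is 1 when the interval crosses 1. A round-trip test verifies the
"explain-away" identity: the bias factor $E^2/(2E-1)$ implied by the E-value
returns the ratio exactly to 1. One reporting subtlety: transforming a CI
bound that was itself rounded to three decimals can differ in the third
decimal from transforming the unrounded bound (1.045 gives 1.2619, which
prints as 1.262 rather than 1.261); the package computes from whatever bound
it is given at full precision and rounds only for display.

Population extrapolation multiplies a prevalent-population size by each
comparator group's share and risk difference, rounding each group count to
the nearest thousand (half-up) *before* summing — the convention that makes
the published-style group counts add up to their printed total — while a
projection to a future population scales the unrounded total first. With
6.5 million prevalent patients, shares (0.4830, 0.3070, 0.1135) and risk
differences (0.050, 0.049, 0.065) this yields 157,000 / 98,000 / 48,000,
total 303,000, and 652,000 at a 14-million projection.

## The synthetic cohort generator

Real EHR cohorts of this kind are licensed and not redistributable, so the
package ships a generator whose defaults emulate the study conditions and
whose ground truth is analytically computable.

A `cohort_spec` fixes: independent categorical demographics and binary
comorbidity flags with given marginals (the built-in `study_cohort_spec()`
uses the study's empirical marginals at $n = 12{,}744$); a multinomial-logit
assignment law; and a Bernoulli outcome law with covariate, treatment, and
interaction coefficients. Intercepts of both laws were calibrated once, by
exact enumeration over the finite covariate support, so that the marginal
treatment shares equal 48.30 / 11.35 / 30.70 / 9.66 percent and the true
counterfactual means equal $(0.780, 0.781, 0.765, 0.830)$ — hence true risk
differences $(0.050, 0.049, 0.065)$ and a true DDI of $0.064$ — with overall
observed survival near 78%. Non-intercept coefficients are moderate and sign-
plausible (older age groups and comorbidities lower survival; marriage and
combination treatment raise treatment propensity), inducing genuine
confounding. Survivors get exactly 5 follow-up years; deaths draw a
uniform(0, 5] death time, which exists purely so crude mortality rates per
1000 patient-years are computable — the estimators only use the binary
indicator, and no claim is made about a realistic death-time law.

`true_counterfactuals()` averages the known arm-specific success probability
over the covariate law, by exhaustive enumeration of the support (exact; the
default cohort has 21,504 cells) or by Monte Carlo with a reported standard
error when a continuous covariate makes the support infinite.

**What the generator does not emulate:** visit-level EHR structure,
treatment switching trajectories, covariate correlation (covariates are
independent by default; correlation would be a configuration extension),
informative censoring, or calendar-time effects. Passing tests on this
synthetic law therefore validate the *estimation machinery* — not the
substantive conclusions one would draw from any particular real cohort.

### Misspecification scenarios

Double robustness is only testable when one can break one model at a time.
The spec's `misspec_scenario` plants a hidden term — the product of the
heart-disease and kidney-disease flags — into the true assignment law
(`propensity_wrong`), the true outcome law (`outcome_wrong`), or both
(`both_wrong`), while every analyst model sees only main effects and
treatment interactions, never the flag product. Because the constituent
flags are themselves confounders, the omitted product makes the
corresponding analyst model genuinely misspecified while leaving the other
model exactly correct.

The compact `benchmark_spec()` (one three-level factor, three flags, same
treatment shares and true means as the study-scale law) is used for the
estimator studies because it can be refitted tens of thousands of times. Its
hidden-term coefficients (assignment $0.5, -0.5, 0.8$; outcome $-2.0$ with
$+1.5$ under the combination) were calibrated once so that the *matching*
singly robust estimator is biased far beyond Monte Carlo noise at
$n = 50{,}000$ (tens of standard errors) without inflating the doubly
robust estimator's second-order finite-sample bias above its Monte Carlo
uncertainty. The acceptance study runs 200 replications per scenario at
$n = 50{,}000$ and checks that the doubly robust estimator stays within 3
Monte Carlo standard errors of the truth whenever at least one model is
correct, while the broken singly robust estimator exceeds 3.

### Bootstrap coverage study

Coverage of the nominal 95% percentile interval for the true risk
difference (combination vs no drug) is estimated with 150 outer replications
of cohorts of $n = 1{,}000$, each bootstrapped with $B = 500$ resamples. At
this scale the interaction-rich outcome model would separate in a
substantial fraction of resamples, so the coverage study uses the benchmark
law with the interaction block zeroed and a mains-only working model (still
correctly specified) plus the `ridge = 1e-4` fallback; coverage is required
to land in $[0.90, 0.99]$. These problem sizes are the package's desk-scale
choice; the machinery runs unchanged at $B = 10{,}000$ and study-scale $n$.

## Eligibility filtering

`apply_study_filters()` applies, in order: first-diagnosis calendar window
(inclusive whole-date boundaries, default calendar year 2016, which given a
data horizon at the end of 2021 guarantees five years of follow-up);
complete demographics (an explicit "Unknown" level is valid, absence is
not); switcher removal; restriction to the four-strategy taxonomy; and a
minimum strategy share of 0.5%, evaluated on the post-switcher cohort. A
"switcher" is a patient whose medication history maps to more than one
distinct regimen — under the default strict rule monotherapy followed by the
combination counts as a switch; the configurable
`augmentation_as_combo` rule instead resolves such histories to the
combination. The per-step in/out counts are returned as a machine-readable
report, and the whole filter is idempotent.

The comorbidity flags are taken as given (whether a comorbidity recorded
after treatment start is a legitimate confounder is a methodological
ambiguity the pipeline does not resolve), and no ICD-code parsing is done:
the analysis table is the entry point.

## Known limitations

* Treatment is a single time-fixed strategy; switchers are excluded rather
  than modelled (no marginal structural model for time-varying treatment).
* Survival is a five-year indicator; no hazard modelling beyond crude
  person-year rates.
* The relative-increase denominators are the comparator means; published
  tables sometimes print percentages whose provenance (rounded vs unrounded
  inputs) differs in the last digit, and the package always computes from
  the stated rule at full precision.
* The Horvitz–Thompson estimator's unnormalized weights make it noisy in
  small arms; the Hajek-normalized variant is deliberately not substituted
  because the DR algebra assumes the unnormalized form.
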