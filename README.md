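# drcausal

Doubly robust estimation of the causal effect of four Alzheimer's-disease
treatment strategies — no drug, Memantine monotherapy, Donepezil monotherapy,
and the Donepezil+Memantine combination — on the probability of five-year
survival, from an observational patient-level cohort.

## Who this is for

Epidemiologists and biostatisticians analysing multi-arm treatment effects
on a binary outcome in the presence of measured confounding, and anyone who
needs a fully testable reference implementation of the augmented
inverse-probability-weighted (AIPW) pipeline: real EHR cohorts of this kind
are licensed, so the package ships a synthetic cohort generator with
analytically known ground truth that stands in for the data at every stage.

## The method

With outcome $Y$ (five-year survival), treatment $A \in \{0,1,2,3\}$ and
confounders $L$, three estimators of the counterfactual means $E(Y^{a=i})$
are computed:

* **IP weighting** via a multinomial logit
  $\log[P(A{=}i\mid L)/P(A{=}0\mid L)] = \beta_i^\top L$ and the
  Horvitz–Thompson estimator
  $\hat E_{IP}(Y^{a=i}) = \frac1n\sum_k I\{A_k{=}i\}Y_k/\hat\pi_i(L_k)$;
* **standardization** (plug-in g-formula) via a logistic outcome model with
  treatment-by-covariate interactions,
  $\hat E_{ST}(Y^{a=i}) = \frac1n\sum_k \hat b_i(L_k)$;
* the **doubly robust** combination
  $\hat E_{DR}(Y^{a=i}) = \frac1n\sum_k [\hat b_i(L_k) +
  \frac{I\{A_k=i\}}{\hat\pi_i(L_k)}(Y_k - \hat b_i(L_k))]$,
  consistent if either model is correctly specified.

On top of these: risk differences and risk ratios against the combination
arm, the additive drug–drug interaction
$DDI = E(Y^{a=3})-E(Y^{a=2})-E(Y^{a=1})+E(Y^{a=0})$, nonparametric bootstrap
percentile confidence intervals with Bonferroni adjustment, standardized
mean-difference balance diagnostics, E-value sensitivity analysis, and
population-level extrapolation of lives extended. Eligibility filtering
(diagnosis window, complete demographics, switcher removal, four-strategy
taxonomy, minimum strategy share) turns a raw patient table into the
analysis cohort.

## Worked example

```r
library(drcausal)

spec     <- study_cohort_spec(seed = 42)      # study-scale synthetic cohort
cohort   <- generate_cohort(spec)             # 12,744 patients
filtered <- apply_study_filters(cohort)       # eligibility filters (no-ops here)
mat      <- analysis_matrix(filtered$records) # Y, A, and encoded L
cs       <- counterfactual_set(mat, ridge = 1e-4)
cs
#> <counterfactual_set> n = 12744
#>         0      1      2      3
#> IP 0.7849 0.7638 0.7603 0.8443
#> ST 0.7848 0.7637 0.7604 0.8435
#> DR 0.7847 0.7639 0.7603 0.8441
effects(cs$means_dr)
#> <effect_set>
#>   RD:  vs_none=0.059  vs_memantine=0.080  vs_donepezil=0.084
#>   RR:  vs_none=1.076  vs_memantine=1.105  vs_donepezil=1.110
#>   DDI: 0.105
true_counterfactuals(spec)
#> <true_effects> (closed_form_average)
#>   means: 0.7800 0.7810 0.7650 0.8300
#>   rds:   0.0500 0.0490 0.0650
#>   ddi:   0.0640
```

The three estimator rows agree to ~0.001 (both nuisance models are correctly
specified here), and the doubly robust estimates scatter around the
generator's exact truth with sampling noise of about $\pm 0.01$–$0.02$ at
this single-cohort size. `ridge = 1e-4` is the documented fallback for the
quasi-separation that rare covariate levels (e.g. a 0.16% race level)
produce at study scale.

Downstream, from published-scale inputs:

```r
ex <- population_extrapolation(6.5e6, c(0.4830, 0.3070, 0.1135),
                               c(0.050, 0.049, 0.065),
                               projected_population = 14e6)
ex$per_group   # 157,000  98,000  48,000
ex$total       # 303,000
ex$projection  # 652,000
evalue(1.085)$evalue_point  # 1.389
```

`bootstrap_effects(mat, B = 500, seed = 1, ridge = 1e-4)` bootstraps the
whole pipeline (both models refitted per resample) and returns naive and
Bonferroni-adjusted percentile intervals for the four means, three risk
differences, and the DDI. A thin command-line front end with subcommands
`simulate`, `filter`, `estimate`, `bootstrap`, `sensitivity`, `extrapolate`
and `report` is installed at `inst/cli/drcausal.R`.

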