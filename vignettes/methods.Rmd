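---
title: "Models and methods behind mpescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpescreen)
```

`mpescreen` analyzes matched case-control studies in which each case's
tumor belongs to one of several mutually exclusive molecular subtypes
(the motivating setting: colorectal cancer classified by *KRAS* and
*BRAF* mutation status). This vignette documents the statistical models,
the defaults and why they were chosen, the numerical choices, and the
limits of what the synthetic-data tests demonstrate.

## 1. The matched design and the conditional likelihood

The unit of analysis is the matched set: one case and `controls_per_case`
controls (default 2) sharing sex, cohort, fasting status, year of
sampling, and age. With set-level matching, the natural estimator is
conditional logistic regression, whose likelihood conditions on one case
per set and thereby eliminates all set-level nuisance parameters:

$$\ell(\beta) = \sum_s w_s\Big[\eta_{\text{case}(s)} -
  \log \sum_{i \in s} e^{\eta_i}\Big], \qquad \eta_i = x_i^\top\beta .$$

At $\beta = 0$ this is exactly $\sum_s \log(1/m_s)$ for set sizes $m_s$,
which the implementation and tests use as a closed-form anchor. The
maximizer is found by damped Newton iterations with analytic gradient and
observed information; steps are halved (up to 30 times) whenever the
likelihood would decrease, and convergence requires a gradient
infinity-norm below $10^{-8}$. Coefficients drifting beyond $|\beta| > 15$
on the per-SD / per-allele scales signal an unbounded likelihood
(complete separation) and raise an error naming the offending term rather
than returning a spurious estimate. Standard errors are inverse observed
information; 95% CIs are $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$.

Subtype-specific ORs fit this likelihood on the subsets of sets whose
case has each subtype, with controls traveling with their case. Exposure
scales: biomarkers enter per 1 SD of the *control* log-concentration
distribution (plasma concentrations are right-skewed, so the SD contrast
is defined on the log scale); SNPs enter per variant allele.

**Heterogeneity.** The likelihood-ratio test compares a model with
subtype-specific exposure coefficients against one with a shared
coefficient; `df = #subtypes − 1`. Adjustment-covariate coefficients stay
subtype-specific in *both* models, so the test isolates the exposure
term; a `shared_nuisance` switch provides the alternative convention. The
choice matters little in practice but the subtype-specific-nuisance
version cannot attribute covariate heterogeneity to the exposure.

**Cochran's Q** with inverse-variance weights checks that per-cohort
log-ORs agree before cohorts are pooled.

## 2. Network screening

Step 1 screens all exposures simultaneously to limit multiple testing: a
discrete Bayesian network over tertile-coded biomarkers, dominant-coded
SNPs, categorical covariates, and one 4-level outcome node
(`control`/`KRAS`/`BRAF`/`WT`). The outcome enters as a single node rather
than indicator nodes; this keeps the subtype contrasts in one conditional
distribution and matches how the class variable is usually handled in
discrete networks.

The score is AIC in "log-likelihood minus penalty" form: for child $X$
with $r$ levels and parent set $\Pi$ with $q$ observed configurations,

$$\text{score}(X \mid \Pi) = \sum_{j,k} N_{jk}\log\frac{N_{jk}}{N_{j\cdot}}
  - (r-1)\,q ,$$

summed over nodes (decomposability is asserted to $10^{-9}$ in tests).
Parameter counting uses configurations *observed* in the data;
configurations never seen contribute no free parameters. This matches the
behavior of standard discrete-network software and avoids punishing
sparse categorical covariates for empty cells; a full-Cartesian count
would only make the search more conservative.

Search is greedy hill climbing from the empty graph over single-arc
additions, deletions, and reversals, accepting the best strictly
improving move, with acyclicity checked by depth-first search and ties
broken deterministically (lexicographic order) so runs are seed-stable.
Because AIC's penalty of 1 per parameter corresponds to admitting an arc
when the deviance gain exceeds 2, a truly null pair acquires a spurious
arc with probability $\Pr(\chi^2_1 > 2) \approx 0.16$ in any one fit —
the bootstrap stage exists precisely to average this noise away.

**Bootstrap averaging.** `n_bootstrap` row resamples (same size, with
replacement) are each re-learned; the edge confidence of a pair is the
exact fraction of replicates containing an arc between them *in either
direction*. Direction-agnostic confidence is used because the screening
question is association, not orientation (many DAGs are
score-equivalent); per-direction fractions are retained for display.
Rows, not matched sets, are resampled by default: the network stage
treats the data as a flat table in which the matching factors are
themselves nodes; a `set_id` argument enables set-level resampling for
users who prefer to preserve the matching clusters.

**Inclusion threshold.** The ideal confidence distribution puts mass $t$
at 0 (noise) and $1-t$ at 1 (signal), with CDF $F_t(x) = t$ on $[0,1)$.
$\hat t$ minimizes the $L_1$ distance between the empirical confidence
CDF and $F_t$ — a weighted median of the empirical CDF's step heights,
weighted by the lengths of the intervals they span — and the threshold is
the inverse-ECDF $\hat t$-quantile of the confidences. Edges strictly
above the threshold are included. When all confidences coincide the
threshold degenerates and inclusion is all-or-none; this is reported, not
hidden.

**Step-1 → step-2 handoff.** Exposures whose edge confidence to the
outcome exceeds the threshold are carried to the univariate stage; when
none passes, the single top-ranked exposure is carried anyway — a
screening stage that selects nothing would otherwise silently end the
analysis, and a top-ranked-but-subthreshold variable is exactly the case
where univariate confirmation is informative.

## 3. Selection bias and inverse-probability weighting

Tumor tissue is not retrievable for every case, and availability may
depend on case characteristics (stage, site, age, calendar period).
Restricting to cases with tumor data conditions on availability and can
bias subtype-specific ORs. The sensitivity analysis models availability
among cases by logistic regression, then refits the conditional logistic
models with weights: 1 for controls, $1/\hat p_i$ for cases with tumor
data, 0 for cases without (their sets contribute nothing). Cases missing
an availability covariate are excluded from the weight model and receive
weight 0, with counts reported.

Balance is checked by refitting the availability model weighted by
$1/\hat p_i$ (available) and $1/(1-\hat p_i)$ (unavailable): if the model
captures the selection mechanism the weighted pseudo-population is
balanced and all covariate coefficients are near 0. Because the weights
derive from the same model's MLE, this refit is a near-fixed point under
correct specification — coefficients are close to zero by construction,
not merely statistically — which is why "all p above 0.2" is a reasonable
pass criterion. Reported SEs are model-based (matching the complete-case
comparison); weighting strictly invalidates them, and the comparison
report is of point estimates, not tests. Weight truncation is available
but off by default.

## 4. Case-case replication

Among cases only, a baseline-category multinomial logit of subtype
(reference: wild-type) on the per-allele exposure gives, per mutated
subtype, a ratio of odds ratios — asymptotically the ratio of that
subtype's case-control OR to the wild-type OR, an identity the test suite
verifies on shared-mechanism simulations. The fit is delegated to
`nnet::multinom` (tight tolerances, `reltol = 1e-12`); the saturated
binary-exposure closed form (RORs = cross-product ratios of the 2×K
table) serves as an independent oracle in tests. The heterogeneity LRT
reported per exposure is the 2-df test of both non-reference slopes equal
to zero — "the exposure does not shift subtype composition" — which is
the contrast a single table-wide p-value most plausibly summarizes; a
1-df equal-slopes variant is provided. No covariate adjustment is applied
by default (adjustment is available via an argument).

## 5. The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
emulated study conditions:

* 488 matched sets, 1:2 matching; subtype probabilities
  (KRAS, BRAF, WT) = (0.26, 0.24, 0.50).
* 14 one-carbon-metabolism biomarkers plus neopterin, multivariate
  log-normal with a one-factor correlation structure (default loading 0.4,
  i.e. pairwise correlation 0.16 — modest biological correlation); log-scale
  means and SDs of plausible plasma magnitude.
* 17 SNPs at Hardy-Weinberg proportions with European-range MAFs; the
  `rs1021737` variant multiplies cystathionine concentrations by 1.07 per
  allele (the transsulfuration-pathway functional effect the analysis
  should detect).
* Matching: sex, cohort (70/30 split), 3-level fasting status, and
  sampling year shared within set; age within a ±2-year caliper. The
  caliper is an assumption — the emulated design states its matching
  factors but not the caliper width — and is configurable.
* Outcome: within each set a subtype is drawn from `subtype_probs`, then
  the case is selected among members with probability
  $\propto \exp(\sum_e \beta_{e,\text{subtype}}\, x_{ie})$, i.e. by the
  same within-set conditional logit the estimator assumes. This makes
  parameter recovery a clean test of the fitting code rather than of an
  approximation; subtypes are mutually exclusive by construction (no
  double mutants).
* Tumor-data availability: logistic in case covariates; the true subtype
  is retained in a `subtype_true` column so bias corrections can be
  scored. Missingness elsewhere is MCAR per exposure (0–3%).
* Seeding: one master seed is split into per-component streams
  (`derive_seeds`), so any sub-generator is reproducible in isolation.

What the generator does **not** emulate: assay measurement error beyond
log-normal noise, batch effects, informative missingness in exposures
(only the tumor-data channel is informative, via `availability_spec`),
age/period structure in exposures, or CIMP/MSI phenotypes — those side
analyses reuse the same machinery with a different label column. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated design, not robustness to misspecification.

## 6. Numerical and convention choices

* **Quantiles / tertiles.** Cutpoints are inverse-ECDF (type 1) quantiles
  of the *controls*, with right-closed assignment (a value equal to a
  cutpoint stays in the lower group). On 1..9 this yields cutpoints
  (3, 6) and exact thirds. Applied identically to cases and controls; a
  no-spread variable raises a degenerate-rule error rather than producing
  a single-level factor. Age and sampling year use control-based
  quartiles (control-only for consistency with the biomarker rules;
  pooled quantiles differ negligibly under 1:2 matching).
* **BMI bands** `<25`, `[25, 30)`, `>=30` (left-closed).
* **Creatinine** is mg/dL in the Cockcroft-Gault formula; a µmol/L switch
  divides by 88.4.
* **Heterogeneity LRT statistic** is clamped at 0 against floating-point
  underflow; the reduced model is nested by construction.
* **Problem sizes in tests.** Oracle-equivalence runs use 200 random
  3-variable datasets (the exhaustive 25-DAG oracle); calibration uses
  1000 null replicates of 120 sets (matched) and 300 cases (case-case);
  recovery uses 2000–3000 sets. The acceptance script pools 6–8
  independent replicates of the recovery designs by inverse variance to
  report stable point estimates while each replicate stays at the stated
  study scale.

## 7. Known limitations

* Hill climbing is a local search; on ≤3 variables it provably attains
  the global optimum in ≥95% of random datasets (tested), but on larger
  graphs local optima are possible. Bootstrap averaging mitigates, not
  eliminates, this.
* The conditional-likelihood engine expects exactly one case per set;
  m:n matching is out of scope.
* IPW corrects only selection on *modeled* covariates; the balance check
  validates the model's internal consistency, not ignorability itself.
* Model-based SEs under weighting understate uncertainty; treat IPW CIs
  as sensitivity output, not primary inference.
* No imputation: exposures are complete-case per analysis, lifestyle
  covariates use an explicit `missing` category.
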