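# mpescreen

Multivariate screening and subtype-specific risk models for matched
molecular-epidemiology studies.

## The problem

In molecular pathological epidemiology, a single cancer diagnosis hides
etiologically distinct subtypes — for colorectal cancer, tumors carrying
mutually exclusive activating *KRAS* (codon 12/13) or *BRAF* (V600E)
mutations versus wild-type tumors. A risk factor can raise the risk of one
subtype while lowering another, and pooling subtypes can wash the signal
out. `mpescreen` implements the full analytic pipeline for relating
exposure biomarkers (e.g. one-carbon-metabolism plasma markers) and
germline variants to the risk of mutually exclusive tumor subtypes in a
**nested, matched case-control study**, together with a synthetic cohort
generator so every stage is testable against known ground truth.

The pipeline has two steps plus sensitivity and replication analyses:

1. **Multivariate screening** by discrete Bayesian networks. All tertile-
   discretized biomarkers, dichotomized SNPs, covariates, and a 4-level
   outcome node (control / KRAS / BRAF / WT) are modeled jointly. Structure
   is learned by greedy hill climbing maximizing the decomposable AIC score
   (per node: multinomial log-likelihood minus one per free parameter) over
   arc additions, deletions, and reversals. Networks from *B* nonparametric
   bootstrap resamples are averaged: the *edge confidence* of a variable
   pair is the fraction of replicates in which an arc joins them. An
   inclusion threshold *t* is estimated by L1-matching the empirical
   confidence CDF to an idealized two-point (noise-at-0 / signal-at-1)
   mixture; exposures are ranked by edge confidence to the outcome node.
2. **Univariate follow-up** by conditional logistic regression. For each
   selected exposure, subtype-specific odds ratios per 1 SD of log
   concentration (biomarkers) or per variant allele (SNPs) are estimated
   from the matched sets whose case has that subtype, maximizing the exact
   conditional likelihood sum over sets of `eta_case - log(sum exp(eta))`.
   Heterogeneity across subtypes is tested by a likelihood-ratio test of
   subtype-specific versus shared exposure coefficients
   (df = #subtypes − 1), and agreement across the underlying cohorts by
   Cochran's Q.
3. **Selection-bias sensitivity analysis** by inverse-probability
   weighting: tumor-data availability among cases is modeled by logistic
   regression; the conditional logistic likelihood is reweighted by 1 for
   controls, 1/p̂ᵢ for cases with tumor data, 0 for cases without; a
   weighted refit of the availability model checks covariate balance.
4. **Case-case replication** by baseline-category multinomial logistic
   regression among cases only: the exponentiated slope per allele is the
   ratio of odds ratios (ROR) of each mutated subtype versus wild-type,
   with a 2-df likelihood-ratio heterogeneity test.

The synthetic cohort generator draws matched sets (one case and *k*
controls sharing sex, cohort, fasting status, sampling year, and age
within ±2 years), correlated multivariate log-normal biomarkers,
Hardy-Weinberg genotypes, and assigns the case *within* each set by a
conditional logit on the configured subtype-specific effects — so the
generating mechanism matches the estimator and parameter recovery is
unbiased by construction.

## Worked example

```r
library(mpescreen)

cfg <- sim_config(
  n_cases = 500, seed = 2026,
  effect_spec = list(rs1021737 = c(log(0.72), log(1.56), log(0.94))),
  availability_spec = list(intercept = 1.5, coefficients = c(age_dx = 0.02)))

res <- run_full_pipeline(cfg, n_bootstrap = 100,
  bn_biomarkers = c("folate", "cystathionine", "homocysteine", "vitamin_B12"),
  bn_snps = c("rs1021737", "rs1801133", "rs234706"))
print(res)
```

```
Two-step subtype-risk analysis pipeline
  1500 subjects (500 cases); 1293 complete-case rows in network stage
  edge-inclusion threshold 0.490; selected exposure(s): rs1021737, vitamin_B12, rs1801133
  Bonferroni-adjusted level: 0.00714
Subtype-specific conditional logistic ORs for rs1021737
 subtype n_cases n_controls                or
    KRAS     113        221 0.54 (0.36, 0.82)
    BRAF     127        248 2.30 (1.61, 3.29)
      WT     222        436 0.96 (0.75, 1.23)
Heterogeneity LRT: chi2 = 31.746 on 2 df, p = 0.0000
...
```

The generator planted opposite per-allele effects of the `rs1021737`
variant on the KRAS-mutated (OR 0.72) and BRAF-mutated (OR 1.56) subtypes
and none elsewhere. The network stage ranks that SNP first (edge
confidence 0.92, above the estimated threshold 0.49), the univariate stage
recovers the opposed subtype-specific ORs with a significant heterogeneity
test, the IPW sensitivity analysis shows the selection induced by
age-dependent tumor-data availability is ignorable here
(`res$ipw$comparison`: mean |Δ log OR| ≈ 0.002), and the case-case
replication among cases only gives concordant RORs
(`res$case_case$rs1021737`: 0.61 and 1.83 vs. the implied 0.72/0.96 and
1.56/0.96). Two null variables also cross the threshold at this modest
sample size — screening is a ranking device, not a test, which is why
step 2 exists.

A command-line wrapper for the simulator and pipeline is installed under
`inst/scripts/mpescreen-cli.R`:

```sh
Rscript inst/scripts/mpescreen-cli.R pipeline --config cfg.yaml --seed 1 --out outdir
```

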