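# lncPairRisk

Prognostic survival signatures from **rank-based lncRNA pair indicators**.

## The problem

Prognostic gene signatures built on absolute expression values are fragile:
they depend on normalisation, platform and batch, and rarely transfer
between cohorts. A rank-based alternative encodes, for every pair of
candidate long noncoding RNAs (A, B) and every sample, a single bit

```
C(A,B) = 1  if expr(A) > expr(B) in that sample,  else 0
```

so the feature depends only on the *within-sample ordering* of two genes
and is invariant to any strictly increasing per-sample transform of
expression. `lncPairRisk` implements the complete pipeline around this
idea for stemness-related lncRNAs in tumor cohorts:

1. screen lncRNAs that are differentially expressed between normal and
   tumor tissue (moderated t, |log2FC| > 1, BH FDR < 0.01) **and**
   coexpressed with at least one stemness-related gene (Spearman
   |rho| > 0.4, p <= 0.05, tumor samples);
2. enumerate all candidate pairs into a 0/1 indicator matrix and keep
   *valid* pairs whose one-fraction lies strictly between 20% and 80%;
3. select a signature: univariate Cox screen (Wald p < 0.05) → 1000
   repetitions of 10-fold cross-validated Lasso-Cox keeping pairs selected
   in more than 100 repetitions → backward-AIC multivariate Cox;
4. compute the per-sample risk score `sum_k coef_k * C_k`, find the
   cutoff minimising the AIC of the dichotomised Cox model over the
   operating points of the 1-year time-dependent ROC curve, and stratify
   patients;
5. evaluate: Kaplan-Meier / log-rank, time-dependent AUC at 1/2/3 years,
   and univariate + multivariate Cox independence analysis against
   clinical covariates; compare external feature tables between risk
   groups with Mann-Whitney U and Spearman correlation.

A synthetic-cohort generator (`simulate_cohort()`) plants coexpression,
differential expression and pair-driven hazards with a machine-readable
truth record, so the whole pipeline is verifiable without any download.

## Worked example

```r
library(lncPairRisk)

sim <- simulate_cohort(sim_config(n_tumor = 250, n_normal = 30,
                                  n_lnc = 60, n_srg = 20,
                                  frac_de = 0.7, frac_coexpressed = 0.7,
                                  seed = 7))
fit <- pair_signature(sim$expr, sim$clinical, sim$srg_ids,
                      control = signature_control(n_reps = 50,
                                                  freq_min = 5),
                      seed = 7)
fit
```

```
Prognostic lncRNA-pair signature
  funnel: lncRNAs = 60, de_lncRNAs = 42, coexpressed_lncRNAs = 42,
          candidates = 28, pairs_enumerated = 378, pairs_valid = 240,
          pairs_screened = 53, pairs_lasso = 29, pairs_signature = 14
  signature pairs: 14; cutoff = 1.968 (aic)
  risk groups: low = 126, high = 124
  AUC: 1y = 0.848, 2y = 0.861, 3y = 0.854
  log-rank p = 9.82e-29
```

The funnel line reports how many genes/pairs survive each stage (counts
can only shrink). Here the fitted signature holds 14 pairs — including all
three planted pairs (`sim$truth$true_pairs`) — the AIC-optimal cutoff
1.968 splits the cohort 126/124, the 1-year time-dependent AUC is 0.85,
and the log-rank test separates the risk groups at p ~ 1e-28, as expected
for the planted log hazard ratios of 1, 0.9 and 0.8.

Useful methods on the fit: `summary()` (per-pair HR, 95% CI, Wald p, plus
the independence table), `coef()`, `predict(fit, new_expr)` /
`predict(fit, new_expr, type = "group")`, `plot(fit, "km" | "roc" |
"cutoff")`, `residuals()` (martingale), `write_signature()` /
`read_signature()` for JSON round-trips, and `write_risk_table()`.

Every stage is also exported on its own (`differential_expression()`,
`coexpression_screen()`, `select_desrlnc()`, `build_pair_matrix()`,
`filter_valid_pairs()`, `fit_cox()`, `univariate_screen()`,
`lasso_frequency_select()`, `stepwise_cox()`, `compute_riskscore()`,
`time_dependent_roc()`, `aic_optimal_cutoff()`, `stratify()`,
`kaplan_meier()`, `independence_cox()`, `group_compare()`,
`rank_correlation()`), and plain-TSV readers/writers are provided for
interoperability. See the methods vignette
(`vignettes/pair-signature-methods.Rmd`) for the model, estimators,
parameter meanings and design choices.

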