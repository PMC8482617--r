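---
title: "Methods: rank-based lncRNA pair signatures for survival risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based lncRNA pair signatures for survival risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncPairRisk)
```

## The problem and the model

Expression-based prognostic signatures usually combine absolute expression
levels, which makes them sensitive to normalisation, platform and batch.
This package instead builds signatures from *pair indicators*: for an
ordered pair of long noncoding RNAs $(A, B)$ and a sample $s$,

$$ C_{AB}(s) = \mathbf{1}\{ \mathrm{expr}_A(s) > \mathrm{expr}_B(s) \}, $$

i.e. a within-sample rank comparison. Any strictly increasing per-sample
transform of expression — quantile scaling, log transforms, library-size
normalisation — leaves every indicator, and therefore the whole signature,
unchanged. The price is a loss of quantitative information; the gain is a
classifier that travels across cohorts without renormalisation.

The fitted risk model is a Cox proportional-hazards model on a small set of
selected pair indicators. The per-sample risk score is

$$ \mathrm{Riskscore}(s) = \sum_k \hat\beta_k \, C_{A_k B_k}(s), $$

with $\hat\beta_k$ the multivariate Cox coefficients of the final model,
and patients are dichotomised at a cutoff chosen by an AIC search (below).

## Pipeline stages and their parameters

`pair_signature()` runs the stages in order; each is also exported on its
own. Defaults are collected in `signature_control()`.

1. **Differential expression** (`differential_expression()`), tumor vs
   normal on `log2(x + 1)`. The default statistic is a moderated t: the
   pooled two-group variance $s_g^2$ (df $d$) is shrunk toward an
   empirical-Bayes prior $(d_0, s_0^2)$ estimated by the method of moments
   from the spread of the log variances, giving posterior variance
   $(d_0 s_0^2 + d s_g^2)/(d_0 + d)$ and a t reference with $d_0 + d$
   degrees of freedom (capped at the pooled residual df across genes).
   Setting `prior_df = 0` recovers the ordinary pooled-variance t exactly,
   and a Welch t is available for cross-checking. A gene is called at
   $|\log_2 \mathrm{FC}| > 1$ and BH-adjusted $p < 0.01$ (both strict).
2. **Coexpression screen** (`coexpression_screen()`): Spearman correlation
   (mid-ranks, t-approximation p-value) of every lncRNA against every
   stemness-related gene, on tumor samples only — normals carry no disease
   context and the survival cohort is the tumor set. A lncRNA is kept when
   some partner reaches $|\rho| > 0.4$ with $p \le 0.05$. The absolute
   value admits repressive coexpression; `signed = TRUE` restricts to
   positive correlation. Candidates are the intersection of both screens;
   because the two filters are per-gene, their order is irrelevant.
3. **Pairing** (`build_pair_matrix()`, `filter_valid_pairs()`): all
   $K(K-1)/2$ unordered candidate couples in lexicographic order, ties
   scored 0 ("higher than" is strict; ties are measure-zero for continuous
   data but occur with zeros). A pair is *valid* when its one-fraction on
   the survival cohort lies strictly between 20% and 80%: a pair that is
   (almost) always 0 or 1 cannot rank patients.
4. **Univariate Cox screen** (`univariate_screen()`): one single-covariate
   Cox model per valid pair, keeping Wald $p < 0.05$. No multiplicity
   correction by default — the stage is a pre-filter for the penalised
   selection, not an inference; `screen_adjust = "bh"` is available.
5. **Repeated Lasso-Cox selection** (`lasso_frequency_select()`):
   `n_reps = 1000` independent repetitions of 10-fold cross-validated
   L1-penalised Cox regression, each with a freshly randomised fold
   assignment drawn from its own seed (spawned from the master seed). The
   penalty grid has 100 log-spaced values from the smallest penalty that
   nulls every coefficient down to 0.01 of it; each repetition picks the
   penalty minimising the cross-validated partial-likelihood deviance (the
   plain minimum — the one-standard-error rule is available via
   `lambda_rule = "1se"`) and votes for the pairs with nonzero
   coefficients. Pairs with frequency above `freq_min = 100` are selected.
   This frequency thresholding is a stability selection: it asks which
   pairs are chosen robustly across fold noise rather than in one lucky
   split.
6. **Backward-AIC stepwise Cox** (`stepwise_cox()`): from the full
   multivariate model on the selected pairs, repeatedly remove the
   covariate whose removal most decreases $\mathrm{AIC} = -2\log PL + 2k$,
   stopping when no removal helps. Exactly collinear columns are pruned
   first, keeping the earliest in canonical order. The surviving
   multivariate coefficients are the signature.
7. **Cutoff** (`aic_optimal_cutoff()`): candidate cutoffs are the
   operating points of the 1-year time-dependent ROC curve (midpoints of
   sorted unique scores) whose induced groups each hold at least 10% of
   the cohort; for each, a single-covariate Cox model on
   $\mathbf{1}\{\mathrm{score} > c\}$ is fitted and the minimum-AIC cutoff
   is returned (ties toward the smaller cutoff). A Youden-index
   alternative (`cutoff_method = "youden"`) maximises
   sensitivity + specificity − 1 on the same curve. The group-size guard
   exists because extreme splits give formally finite but meaningless AIC
   values.
8. **Evaluation**: Kaplan-Meier curves with the log-rank test
   (`kaplan_meier()`), and univariate plus multivariate Cox models of the
   continuous score against available clinical covariates
   (`independence_cox()`), with ordinal grade (1-3) and stage (1-4) coded
   numerically.

Ties in all Cox models use the Efron correction, which is the more
accurate choice when day-scale survival times coincide; Breslow is
available. Two-group feature comparisons downstream (`group_compare()`)
use the two-sided Mann-Whitney U test — exact enumeration when both groups
have at most 8 tie-free values, otherwise the mid-rank normal
approximation with continuity correction — with BH adjustment across
features; `rank_correlation()` provides Spearman rho with the
t-approximation p-value for score-vs-feature associations such as tumor
mutation burden. Externally computed tables (drug IC50, immunophenoscore,
mutation burden) are consumed as features, never recomputed.

## The time-dependent ROC estimator

Horizons use the cumulative/dynamic definition: at horizon $h$, cases are
subjects with an observed event by $h$ and controls those surviving past
$h$. Censoring before $h$ is handled with subgroup Kaplan-Meier survival
$\hat S$:

$$ \mathrm{Sens}(c) = \frac{(1 - \hat S(h \mid X > c))\,\hat P(X > c)}
                          {1 - \hat S(h)}, \qquad
   \mathrm{Spec}(c) = \frac{\hat S(h \mid X \le c)\,\hat P(X \le c)}
                          {\hat S(h)}. $$

This is the simple deterministic KM-based estimator; it can produce
locally non-monotone curves, which are clipped to $[0,1]$ and integrated
by trapezoid in decreasing-threshold order (sorting by coordinates would
let floating-point noise reorder vertical staircase segments). With no
censoring before the horizon the AUC reduces exactly to the Mann-Whitney
concordance between case and control scores, which the tests assert to
1e-10. Nearest-neighbour smoothing variants are out of scope.

## The synthetic cohort generator

`simulate_cohort()` generates the statistical structure the pipeline
assumes, with a machine-readable truth record so every stage has a
recoverable answer:

- log2-scale Gaussian expression exponentiated to a positive, heavy-tailed
  scale (FPKM-like); gene baselines uniform on log2 [2, 6] for lncRNAs;
- a fraction of lncRNAs loads on the latent factor of one stemness gene;
  the loading is chosen so the *expected Spearman* correlation equals
  `latent_corr` (the Pearson correlation of the underlying Gaussians is
  $2\sin(\pi\rho_S/6)$);
- a fraction of lncRNAs gains `de_log2fc` (default 2) in tumor samples;
- survival for tumor samples is exponential with hazard
  $\lambda_0 \exp\left(\sum_k \beta_k C_{A_k B_k}\right)$ acting through
  planted pair indicators, so the pipeline's feature space contains the
  truth exactly; censoring is exponential, and normals carry no survival
  record;
- planted pair members are forced into both screens and share a baseline
  mean, which keeps the planted pair valid (one-fraction near 1/2);
- `age`, `grade`, `stage` are generated independent of the hazard, i.e.
  as null covariates for the independence analysis.

Defaults mirror the shape of the reference cohort: 375 tumor and 32 normal
samples, 42 stemness genes, baseline hazard 1/1500 per day and censoring
rate 1/3000 per day (roughly two-thirds of subjects experience the event),
three planted pairs with log hazard ratios 1, 0.9 and 0.8. What the
generator does **not** emulate: count-level noise (negative binomial
overdispersion), batch effects, gene-length and library-size artefacts,
or correlated censoring. Tests passing on these cohorts therefore
demonstrate the statistical machinery, not robustness to every failure
mode of real RNA-seq.

## Numerical and design choices

- **Determinism.** All randomness flows from one master seed; the Lasso
  stage spawns one seed per repetition, so identical inputs and seed give
  byte-identical outputs (asserted down to file hashes in the tests).
  Signature JSON stores coefficients both as decimal numbers and as hex
  floats so deserialisation is bit-exact.
- **Strictness conventions.** DE calls use strict inequalities on both
  fold change and FDR; the validity interval (0.2, 0.8) is open, per
  "more than ... but less than"; `stratify()` assigns scores equal to the
  cutoff to the low-risk group ("higher than" is strict throughout).
- **Degenerate inputs.** Genes identical in every sample get $p = 1$ and
  direction `ns`; constant vectors in the correlation screen are skipped
  with a warning (rho undefined); pair columns constant on the survival
  cohort are dropped from the univariate screen with a message; constant
  or collinear covariates in `fit_cox()` raise errors naming the columns;
  monotone-likelihood (separation) warnings are flagged on the fit.
- **Path tolerance.** The repeated-selection loop runs the coordinate
  descent at tolerance 1e-5 rather than glmnet's one-off default: the
  repetitions only vote on membership, the frequencies at the 10%
  threshold are insensitive to the looser path (the selected sets differ
  on well under 1% of repetition-level votes), and the final
  coefficients are refit exactly by the stepwise Cox stage.
- **Cutoff search behaviour.** A minimum-AIC scan over a few hundred
  correlated thresholds is a maximally-selected statistic: with two
  planted risk strata it recovers the partition to within a couple of
  samples but the numeric cutoff can sit just inside a stratum. The tests
  therefore check the recovered partition (at most 2% misassigned), which
  is the property that matters for downstream survival contrasts.
- **Problem sizes in the test-suite.** The verification suite runs the
  full pipeline on cohorts of 150-400 tumor samples with 30-80 lncRNAs
  and the selection stage scaled to 100 repetitions with frequency
  threshold 10 (the 1000/100 defaults shrunk ten-fold together), 20
  replicate seeds for recovery and error-rate properties. These sizes
  give stable Monte-Carlo estimates for every asserted property while
  keeping a full run of the suite on one core practical.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(n_tumor = 250, n_normal = 30,
                                  n_lnc = 60, n_srg = 20,
                                  frac_de = 0.7, frac_coexpressed = 0.7,
                                  seed = 7))
fit <- pair_signature(sim$expr, sim$clinical, sim$srg_ids,
                      control = signature_control(n_reps = 100,
                                                  freq_min = 10),
                      seed = 7)
print(fit)
summary(fit)
plot(fit, "km")
predict(fit, sim$expr, type = "group")
```

## Known limitations

- The pair space grows quadratically in the candidate count; beyond a few
  hundred candidates the univariate screen dominates runtime.
- The univariate screen is unadjusted by design (mirroring common
  practice in this signature family); with thousands of valid pairs it
  passes ~5% of nulls, and the burden of sparsification rests on the
  stability selection.
- The KM-based ROC estimator is not guaranteed monotone and carries no
  confidence bands; incident/dynamic ROC variants are out of scope.
- Proportional hazards is assumed throughout; no diagnostics for
  time-varying effects are provided (martingale residuals are exposed via
  `residuals()`).
- The selection path (screen at raw $p$, minimum-deviance penalty,
  backward AIC) is one defensible choice among several; the alternatives
  (BH-adjusted screen, one-standard-error rule, Youden cutoff) are
  exposed as options rather than silently fixed.
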