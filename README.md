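# ptckit

Prognostic gene selection, molecular subtyping and recurrence-risk
stratification for papillary thyroid cancer (PTC) transcriptomics.

Most PTCs are cured by surgery; a minority recur, and the clinical risk
systems used to decide on surgery extent, radioactive iodine and follow-up
intensity explain that minority poorly. `ptckit` implements a
transcriptome-driven pipeline for this problem:

1. **Ensemble survival feature selection** (`highlifer()`): genes are
   ranked by their univariate Cox Wald statistic
   \(W_g = (\hat\beta_g/\mathrm{se}_g)^2\) for progression-free survival
   within repeated "virtual cohorts" (20 rounds of 70% subsamples without
   replacement), with multi-gene partial Cox fits over random gene
   combinations as a stability layer. A gene is selected when it ranks in
   the top 200 in ≥ 90% of rounds and its median Wald exceeds
   max(½·max median Wald, 4.7). The run is repeated on the
   definitive-outcome subset (recurrence at any time, or ≥ 36 months of
   event-free follow-up) and the union of the two selections is returned
   with provenance flags.
2. **Partial Cox regression** (`partial_cox()`): a PLS-style
   latent-component survival model — per-gene weights are univariate Cox
   coefficients with previous components as offsets, scores are deflated
   out, and a final Cox fit on K scores is back-substituted into one
   composite per-gene coefficient vector for risk prediction.
3. **Molecular subtyping** (`cluster_samples()`, `assign_subtype_labels()`,
   `two_step_classifier()`): hierarchical clustering (1 − Pearson, Ward) of
   samples over the selected genes into three subtypes; Type 3 anchors to
   the hazard-increasing correlated gene block, Type 1 is the cluster with
   the inverse pattern, Type 2 the remainder; a two-step random forest
   (Type 3 vs rest, then Type 1 vs Type 2) classifies new samples, with
   stratified 10-fold CV reporting per-step accuracy.
4. **Risk stratification** (`assign_risk_class()`,
   `compare_stratifiers()`): high risk iff Type 3 or an advanced tumor
   (> 4 cm or N1); evaluated against subtype-only and a binarized ATA
   baseline by 5-year time-dependent AUROC with
   inverse-probability-of-censoring weights.
5. **Synthetic cohorts** (`simulate_cohort()`): proportional-hazards
   recurrence with planted prognostic genes, three subtype expression
   blocks (Type 1 the inverse of Type 3), censoring, and
   subtype-correlated clinical covariates — so everything above is testable
   with known ground truth.

The survival and categorical statistics used throughout (`fit_cox`,
`kaplan_meier`, `log_rank_test`, `pearson_chi_square`, `fisher_exact_2x2`,
`kruskal_wallis`, `cumulative_dynamic_auc`) are exported as plain functions.

## Worked example

```r
library(ptckit)

ch <- simulate_cohort(simulation_config(n_samples = 300, n_genes = 500,
                                        log_hazard_ratios = 0.8, seed = 1))
hl <- highlifer(ch$expression, ch$time, ch$event,
                highlifer_config(top_k = 100, seed = 1))
print(hl)
#> Ensemble prognostic gene selection
#>   genes scored:    500
#>   rounds per pass: 20
#>   selected:       10 (pass1 0, pass2 0, both 10)

sum(ch$true_prognostic_genes %in% hl$selected_genes)
#> [1] 10

xs <- ch$expression[, hl$selected_genes]
cl <- cluster_samples(xs, k = 3)
lab <- assign_subtype_labels(cl, xs, coef(hl$model))
risk <- assign_risk_class(lab$subtype, ch$clinical$tumor_size_cm,
                          ch$clinical$n_stage)
log_rank_test(ch$time, ch$event, risk)
#> log-rank: statistic = 103.8245, df = 1, p = 2.210506e-24
```

All 10 planted prognostic genes are recovered by the two-pass selection
(`pass = "both"` means both passes agreed); the clustering-derived subtypes
combined with tumor size and nodal status split the cohort into risk
classes with clearly separated progression-free survival (the log-rank
p-value above).

The command-line front end lives at `inst/cli/ptckit.R`:

```sh
Rscript inst/cli/ptckit.R simulate --out cohort/
Rscript inst/cli/ptckit.R select-genes --expr cohort/expression.tsv \
    --surv cohort/survival.tsv --out selection.tsv
```

See `vignettes/ptc-prognostic-classifier.Rmd` for the model, its
assumptions, parameter meanings and the design decisions.

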