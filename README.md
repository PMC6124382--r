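# samgsrl

Pathway-guided feature selection for **two-class longitudinal gene
expression data** via two-level gene-set reduction (SAMGSR), with its
longitudinal and per-time-point comparators, a classifier-based
evaluation protocol, cross-validated tuning of the reduction cutoff,
and a self-contained synthetic benchmark.

## Who this is for

Analysts with a longitudinal expression study — every gene measured on
every subject at a shared grid of time points, subjects labelled with a
binary phenotype — who want a small, interpretable set of
(gene, time point) pairs separating the classes, and who have (or can
skip) a pathway collection such as MSigDB C2 in GMT format.

## The method in brief

For gene *i* at time *j* the moderated SAM statistic is

    d_ij = (x̄_d(ij) − x̄_c(ij)) / (s_(ij) + s0_j)

with class means, a time-point-specific pooled SD and a
time-point-specific fudge constant.  A feature set *F* (a pathway
across all time points, or one gene's time profile) scores
`SAMGS(F) = Σ_{(i,j)∈F} d_ij²`, tested by permuting phenotype labels at
the subject level (all of a subject's time points move together) and
screened with Benjamini–Hochberg q-values.  The *reduction* step ranks
a significant set's features by evidence and finds the smallest core
whose residual first becomes non-significant (permutation p-value
`c_k` > cutoff).  The **two-level** selector applies reduction first to
genes within significant pathways, then to time points within the
retained genes; the **longitudinal** selector treats each gene's time
profile as its own gene set (no pathways); the **per-time-point**
selector runs classical single-time reduction on each slice.

Selected signatures are evaluated by fitting one probabilistic
classifier per time point (default: ridge-penalized logistic
regression; any fit/predict-probability pair can be plugged in),
averaging the per-time-point posteriors per subject, and reporting
misclassification error, generalized Brier score (GBS), belief
confusion metric (BCM) and area under the precision–recall curve
(AUPR).  The reduction cutoff is tuned by stratified 5-fold CV over
0.05, 0.10, …, 0.50.

See `vignettes/samgsrl-methods.Rmd` for assumptions, parameter
defaults, numerical choices and known limitations.

## Worked example

A tiny synthetic cohort with one causal (gene, time) cell, selection,
evaluation and tuning:

```r
library(samgsrl)

cfg <- sim_config("custom", n_genes = 40, n_subjects = 60, block_size = 5,
                  replicates = 1,
                  logit_terms = data.frame(gene = "CAUSAL",
                                           timepoint = "T2", coef = 10))
backbone <- make_backbone(cfg, seed = 11)
labels <- simulate_outcome(backbone, cfg$logit_terms, seed = 12)
expr <- long_expr_set(backbone, labels)
expr
#> long_expr_set: 40 genes x 60 subjects x 5 time points
#>   phenotype: uncomplicated=27, complicated=33 (positive class: complicated)
#>   time points: T1, T2, T3, T4, T5

sig <- two_level_select(expr, collection = sim_gene_sets(cfg),
                        q_cutoff = 0.05, c_cutoff = 0.2, B = 499, seed = 13)
sig
#> samgsr_signature [two_level]: 10 (gene, time) pairs, 4 unique genes
#>         gene timepoint    method
#> 1     CAUSAL        T2 two_level
#> 2     CAUSAL        T3 two_level
#> ...
```

The causal gene is recovered (its planted time point T2 first, plus
neighbouring time points that inherit signal through the within-subject
AR(1) correlation) along with a few correlated block-mates — the
"redundant gene" behaviour typical of filter-style selectors.

```r
metrics <- evaluate_signature(expr, sig)
metrics$averaged
#> metrics [averaged]: error=0.183 GBS=0.177 BCM=0.589 AUPR=0.940
```

Averaged-posterior classification gets ~18% error and an AUPR of 0.94:
the signature separates the classes well, while BCM near 0.59 shows the
posteriors are calibrated but not extreme at this sample size.

```r
cv_tune_cutoff(expr, method = "two_level", collection = sim_gene_sets(cfg),
               grid = c(0.1, 0.2, 0.3), B = 199, seed = 14)
#> [1] 0.2
#> attr(,"cv_errors")
#>       0.1       0.2       0.3
#> 0.2137529 0.1983683 0.2011655
```

With real files instead, use `read_expression("expr.tsv", "pheno.tsv")`
(columns named `subject:timepoint`) and
`align_gene_sets(read_gmt("c2.gmt"), expr)`.

## Command line

```sh
inst/cli/samgsrl select --expr expr.tsv --pheno pheno.tsv --gmt sets.gmt \
    --method two_level --q_cutoff 0.05 --c_cutoff 0.2 --perms 1000 \
    --seed 1 --out signature.tsv
```

Subcommands `select`, `tune`, `evaluate`, `simulate`; all accept
`--config cfg.yaml` with flag overrides.  Each run writes a
reproducibility manifest next to its output; `rerun_manifest()` replays
it bitwise.

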