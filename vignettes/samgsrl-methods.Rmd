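---
title: "Pathway-guided feature selection for longitudinal expression data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-guided feature selection for longitudinal expression data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samgsrl)
```

## The problem

A two-class longitudinal expression study measures every gene on every
subject at a shared grid of time points (think of blood transcriptomes
drawn repeatedly after a traumatic injury, with subjects split into
complicated and uncomplicated recoveries).  The analyst wants a small
set of (gene, time point) pairs that separates the classes.  Screening
each time point separately ignores the within-subject correlation and
misses genes whose per-time effects are individually mild but
concordant across time; screening gene by gene ignores the pathway
structure that groups co-functioning genes.

`samgsrl` implements a two-level gene-set-reduction selector that uses
both sources of structure, together with two comparators that each use
only one of them, and an evaluation / simulation harness around them.

## The statistics

**Per-cell SAM statistic.**  For gene $i$ at time point $j$,

$$d_{ij} = \frac{\bar x_{d(ij)} - \bar x_{c(ij)}}{s_{(ij)} + s_{0j}},$$

where $\bar x_{d(ij)}$ and $\bar x_{c(ij)}$ are the class means,
$s_{(ij)}$ is a pooled standard deviation and $s_{0j}$ a small positive
"fudge" constant that keeps low-variance genes from dominating.  Both
$s_{(ij)}$ and $s_{0j}$ are computed separately at each time point,
because measurement variability changes over time.

Two conventions were genuinely open:

* *Pooling.*  The default `pooling = "within"` uses the classic
  two-sample pooled within-class scatter scaled like a standard error
  of a mean difference,
  $s_{(ij)} = \sqrt{\tfrac{1/n_d + 1/n_c}{n_d+n_c-2}\,(SS_d + SS_c)}$.
  An `"all"` option substitutes the total scatter of all samples pooled
  together; it is less powerful for strong effects (the separation
  itself inflates the denominator) and is provided because the
  description of the source method is ambiguous on this point.
* *Fudge.*  No selection rule for $s_{0j}$ is prescribed by the method
  this package implements, and the original percentile-search is
  deliberately not reproduced.  The default is the median of
  $s_{(ij)}$ over genes at time $j$ — a stable, common surrogate — with
  a machine-epsilon-scaled floor so the constant is always strictly
  positive (degenerate all-constant data produces a warning, not an
  error).  A `"fixed"` constant is available.

**Set statistic.**  A feature set $F$ (a pathway's member genes across
all time points, or one gene's time profile) scores

$$\mathrm{SAMGS}(F) = \sum_{(i,j) \in F} d_{ij}^2 .$$

**Permutation test.**  Significance comes from permuting phenotype
labels at the *subject* level: all time points of a subject move
together, so within-subject correlation is preserved under the null.
The full statistic matrix — including $s_{(ij)}$ and $s_{0j}$ — is
recomputed inside every permutation; a regression test pins this.  The
p-value uses the add-one estimator $p = (1 + \#\{S^{(b)} \ge S^{obs}\})
/ (B+1)$, with ties counted as exceedances (conservative).  One seeded
permutation stream is shared by every set tested in a run, so set
results are mutually comparable, and the same frozen stream serves all
steps of one reduction.  Set-level screening adjusts the p-values with
Benjamini–Hochberg (the source does not name an FDR method) and keeps
sets with $q \le$ `q_cutoff` (default 0.05).

A numerical subtlety worth recording: the class sums are computed with
*direct* indicator products for both classes rather than
total-minus-diseased subtraction.  This makes $d$ negate bitwise under
relabeling of the classes, so $d^2$ — and with it every permutation
tie — is exactly invariant to which class is called "diseased".  With
the subtraction shortcut, permutations that mirror the observed split
differ from it by one ulp and the tie counts drift.

**Reduction.**  Within a significant set, features are ranked by
evidence and the set is partitioned into a core $R_k$ (top $k$) and a
residual $\bar R_k$.  For $k = 1, 2, \dots$ the permutation p-value
$c_k$ of the residual is computed; the chosen core size $k^\ast$ is the
smallest $k$ whose residual is non-significant for the first time
($c_k$ strictly greater than `c_cutoff`).  Edge rules: a singleton set
is its own core with no test; if no residual ever becomes
non-significant, the whole set is the core ($k^\ast = S$ — the source
does not cover this edge).  Note the direction: a *larger* cutoff
demands a less significant residual before stopping, so $k^\ast$ is
nondecreasing in the cutoff.

Ranking keys: at the time-point level, $|d_{ij}|$; at the gene level a
gene aggregates its time course as $\sqrt{\sum_j d_{ij}^2}$, consistent
with how it contributes to the set statistic (the source diagrams do
not state a gene-level key for longitudinal data).  Ties keep input
order (stable sort), a fixed deterministic rule.

## The three selectors

* **Two-level** (`two_level_select`): SAMGS screen over the pathway
  collection; gene-level reduction of each significant pathway; union
  of the core genes (a gene in several pathways enters once); then
  time-point reduction of each union gene, treating its time profile
  as a gene set.  No per-gene significance screen is re-applied between
  the levels — every union gene proceeds, per the source's flow.  With
  a single time point, level 2 returns the gene at its only time point
  without testing.
* **Longitudinal** (`longitudinal_select`): the pathway-free
  comparator.  Every gene's time profile is its own set; SAMGS screen
  with BH over genes; then time-point reduction per significant gene.
  On a collection of singleton sets the two-level algorithm collapses
  to exactly this (tested).
* **Per-time-point** (`per_timepoint_select`): classical single-time
  reduction run independently on each time slice, results united and
  tagged by time point.  It deliberately ignores the longitudinal
  structure and serves as the baseline the other two improve on.

## Evaluation protocol

The selectors do not estimate coefficients, so a probabilistic
classifier is fitted per time point on that time point's selected
genes, and each test subject gets a posterior probability of the
positive class per time point plus the arithmetic *average* across
time points (the integrated evaluation that credits mild-but-concordant
genes).  A time point with no selected features yields uninformative
0.5 posteriors with a warning.

**Classifier.**  The evaluation contract accepts any fit /
predict-probability pair.  The environment this package targets has no
SVM implementation installed, so the default is ridge-penalized
logistic regression (`glmnet`, fixed $\lambda = 0.1$, `alpha = 0`) — a
calibrated linear decision boundary that stays well defined when the
signature is larger than the cohort.  The penalty is fixed rather than
cross-validated to keep evaluation deterministic; it is a reported,
replaceable default, not a tuned value.

**Metrics.**  Four metrics on $[0,1]$, reconstructed so the stated
range/optimum properties hold (the source cites but does not reproduce
the formulas):

* misclassification error at threshold 0.5, with posteriors of exactly
  0.5 classified positive (fixed tie rule);
* generalized Brier score
  $\mathrm{GBS} = \frac{1}{2n}\sum_s\sum_{k \in \{+,-\}} (p_{sk} -
  \mathbf 1\{y_s = k\})^2$ (0 optimal; uniform 0.5 posteriors give
  exactly 0.25);
* belief confusion metric $\mathrm{BCM} = \frac{1}{n}\sum_s p_{s,y_s}$
  (1 optimal; uniform posteriors give 0.5);
* AUPR, trapezoidal over recall with the diseased class positive,
  thresholds swept through the distinct posterior values with an anchor
  at recall 0 carrying the first cut's precision.

**Tuning.**  `cv_tune_cutoff` searches `c_cutoff` over
$0.05, 0.10, \dots, 0.50$ by stratified 5-fold cross-validation
(stratification is our choice; the source does not say), minimizing the
misclassification error of the *averaged* posteriors (the integrated
protocol; whether the source tuned on per-time or averaged posteriors
is unstated).  Ties go to the smallest cutoff.  A fold that loses a
class is redrawn with a sub-seed, at most 10 times.  One permutation
stream per fold is shared across the whole grid, since the stream does
not depend on the cutoff.

## The synthetic benchmark

The generator emulates a two-class longitudinal cohort without any
external data:

* **Backbone** (`make_backbone`): per subject, a genes $\times$ time
  Gaussian matrix with separable correlation — AR(1) across the 5 time
  points (`rho_time`, default 0.6) and exchangeable correlation within
  consecutive blocks of 20 genes (`rho_gene`, default 0.3), realised
  through a shared per-block AR(1) factor; then standardized per
  (gene, time point).  Defaults: 1000 genes, 43 subjects (mirroring a
  25 + 18 training cohort), 5 time points, 50 replicates.  The
  correlation blocks double as the pathway collection, so pathway
  structure is aligned with correlation structure.  Covariates are
  standardized before entering the outcome model, keeping the printed
  coefficients on a comparable scale (the source's scaling is
  unstated).
* **Outcome** (`simulate_outcome`): subject labels are Bernoulli draws
  from $\mathrm{logit}^{-1}(\eta)$ with $\eta$ a fixed linear
  combination of causal cells.  Design `sim1` plants one gene with
  moderate coordinated effects (0.18, 0.57, 0.29, 0.41 at times 1–4)
  plus one single-large-effect gene (1.02 at time 3); `sim2` plants
  two opposite single-time effects (0.56 at time 1, −0.91 at time 5).
* **Replicates** (`run_replicates`): fresh backbone and outcome per
  replicate (single-class outcomes are redrawn with sub-seeds and
  logged), selectors run, per-time-point selection counts and unique
  gene counts aggregated.

**What the generator does *not* emulate — and why one acceptance check
stays red.**  Real expression data carry pervasive, strong
co-expression: a causal gene drags along dozens of highly correlated
neighbours.  Under permutation screening with BH, that redundancy is
paradoxically *helpful*: many correlated genes hit the permutation
p-value floor together, BH ranks grow, and the q-values of all of them
drop below the cutoff.  The synthetic world's modest `rho_gene = 0.3`
blocks cannot produce this.  Moreover, labels drawn from a logistic
model cap the point-biserial correlation between any single
standardized covariate and the outcome (roughly 0.5 here), so doubling
the logit coefficients saturates the labels rather than doubling
expression effect sizes.  Measured consequence: in the doubled `sim1`
world the causal block is the top-ranked pathway with a true
permutation p around 0.01 — but a rank-1 BH pass over 50 blocks at
$q \le 0.05$ needs $p \le 0.001$, so the pathway screen usually fails
and the planted-recovery acceptance check (≥80% recovery of the
coordinated causal gene at time 2) does not hold in this stated world;
it is kept red deliberately rather than met by moving generator
parameters or thresholds.  The companion clause of the same check —
that the final signature excludes ≥95% of the 998 noise genes — holds
comfortably.  A green run of the remaining checks therefore
establishes correctness of the statistics, permutation machinery,
reduction laws and metrics, not field-realistic power of the pathway
screen.

**Permutation resolution and the BH floor.**  With $B$ permutations the
smallest achievable p-value is $1/(B+1)$, so the smallest achievable
q-value over $m$ sets at rank $r$ is $m / ((B+1)\,r)$.  Screens over
many sets need $B \gtrsim m / 0.05$ before *any* set can pass at
$q \le 0.05$ unless many sets reach the floor together.  The default
`B = 1000` matches common practice; tests use 199–999 to stay inside
desk budgets (stated here, not hidden), and the scaled-down
planted-recovery check uses `B = 999`, where the floor for its 50 sets
sits exactly at the 0.05 boundary.

## Other numerical and design choices

* Sub-seeds: all randomness flows from one master seed through named
  streams (`sub_seed`), so pipeline stages are decoupled but
  reproducible; re-running a written manifest reproduces outputs
  bitwise.
* The residual statistics of a reduction are computed as reverse
  cumulative sums over the ranked features, so the whole $c_k$
  sequence costs one pass over the shared permutation matrix.
* Negative within-class sums of squares arising from floating
  cancellation are clamped at zero before the square root.
* Gene identifiers are matched as exact strings; collapsing probes to
  symbols is the caller's job.  Subjects with incomplete time series
  are dropped with a warning by default (configurable to error),
  mirroring a complete-case design.  Time labels are ordered
  categorical tokens, not numbers.
* `read_gmt` deduplicates members within a set with a warning but
  preserves overlapping membership across sets.

## Known limitations

* The original fudge-factor percentile search is not implemented.
* Only two-class phenotypes are supported; no multi-class statistics.
* The per-gene FDR machinery of the original single-gene method is out
  of scope; FDR control here is BH over set-level permutation p-values.
* The synthetic benchmark underestimates the redundancy-driven power
  of pathway screening on real data (see above); conclusions about
  relative selector power should rest on real backbones.
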