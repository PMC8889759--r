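---
title: "Swarm-selected platelet RNA classifiers: models, parameters and design choices"
author: "plateletPSO authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-selected platelet RNA classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateletPSO)
```

## Scope

Blood platelets take up RNA from tumor cells ("tumor-educated platelets"),
so their transcriptome carries a diagnostic signal that can be read from an
ordinary blood draw. This package implements the complete analysis that
turns a platelet RNA-seq count matrix into a cancer-versus-control
classifier: negative-binomial-aware preprocessing, wrapper feature selection
by binary particle swarm optimization (BPSO) with a cross-validated
SVM-AUROC fitness, and an evaluation suite. A synthetic cohort generator
provides ground-truthed data so that every stage is testable without access
to patient samples.

This vignette is the package's methods account: the models, the tunable
parameters with their defaults and units, the numerical choices, and the
places where the design was genuinely open and a decision had to be made.

## The synthetic cohort generator

`simulateCohort()` draws counts from the negative-binomial model

$$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha), \qquad
  \mu_{gj} = s_j \,\mu_g\, 2^{\beta_g I[\mathrm{CRC}_j]}\,
  2^{\gamma_g (a_j - 50)}\, 2^{\delta_{g,b_j}},$$

with the mean-dispersion parameterization
$\mathrm{Var} = \mu + \alpha\mu^2$. The components:

* $\mu_g$, baseline means, log-uniform on `baseMeanRange` (default 2-5000
  reads), so the matrix spans the low-coverage to highly-expressed regime;
* $s_j$, per-sample library-size multipliers, log-uniform on
  `libsizeRange` (default 0.5-2);
* $\beta_g = \pm$`effectLog2FC` for the `nInformative` planted genes
  (default 863 genes at |log2FC| 1.0, 20% up / 80% down, matching the
  direction imbalance typical of platelet transcriptomes in cancer, where
  most differential genes are downregulated);
* $\gamma_g$ = `ageSlope` (default 0.02 log2-units/year) for `nAgeGenes`
  age-correlated genes (default 300), disjoint from the informative set;
* $\delta_{g,b}$, latent batch offsets, $N(0, \texttt{batchSD}^2)$ per gene
  for batches beyond the first (default 2 batches, SD 0.25). Batch
  assignment is dealt round-robin *within* each diagnosis group, so batch is
  crossed with, not confounded with, the biology and surrogate-variable
  removal is identifiable.

The default cohort composition is the 322-sample design the package
emulates: 21 healthy donors, 40 Crohn's disease, 22 ulcerative colitis, 48
polyps, 59 adenomas, and 132 colorectal cancers (stages I/II/III/IV =
25/48/58/1). Ages are truncated normal per group at the published per-group
mean, SD and range — this matters because the cancer group is older than
the inflammatory-disease groups, so age is a *real* confounder of the class
label and the age-filter stage is exercised under realistic conditions.
Serum CEA and CA199 are log2-normal with a higher location in CRC (log2
medians 2.08 vs 0.77 and 3.16 vs 2.68, SD 1.5 — chosen so the marker-based
AUROC lands in the moderate range reported for these markers clinically).

The study never reports effect sizes for its differential genes, so
`effectLog2FC = 1.0` and the dispersion default 0.2 are calibration
choices, not published values; they were fixed once, before any test was
run, and are stated here so downstream numbers can be read in context.

What the generator does *not* emulate: read-level artifacts (it starts at
the count matrix), gene-gene correlation beyond what the batch and age
terms induce, heavy-tailed per-gene dispersions, and platelet biology
itself. Passing recovery tests on this generator therefore demonstrate that
the pipeline's stages do what they claim on data matching their own model
assumptions — not that the published clinical AUROCs are reproduced (those
require the deposited patient cohort).

## Preprocessing

The chain is fixed and audited: low-count filter → size factors →
dispersion trend → variance-stabilizing transform → age filter → surrogate
variables. `preprocessCohort()` logs genes and samples in and out of every
stage.

**Low-count filter.** Transcripts with fewer than 5 reads in *all* samples
are excluded, read as "no sample reaches 5": a gene survives iff its
maximum count is ≥ 5. The alternative reading (total across samples < 5)
removes almost nothing at 322 samples and contradicts the phrase "in all
samples", so it was rejected. The filter is idempotent.

**Size factors.** Median-of-ratios: $s_j$ is the median over
all-positive genes of $K_{gj}/(\prod_j K_{gj})^{1/n}$, rescaled to
geometric mean exactly 1 so normalized counts stay on the raw scale. When
no gene is positive everywhere, a pseudo-reference fallback (positive
counts only, genes positive in at least half the samples) is available
explicitly rather than silently.

**Dispersion.** Per-gene method-of-moments estimates
$\hat\alpha_g = \max(0, (s^2_g - m_g)/m_g^2)$ on normalized counts, then a
robust (Huber) regression of $\hat\alpha_g$ on $1/m_g$ gives the trend
$\alpha(\mu) = a_0 + a_1/\mu$. The classifier downstream needs variance
stabilization, not differential-expression inference, so shrinkage
machinery is deliberately out of scope; the contract that matters — the
transformed variance is flat in the mean — is what the tests check. If
every gene looks Poisson the fit degenerates to $a_0 = a_1 = 0$ and is
flagged.

**VST.** The closed-form variance-stabilizing map for that trend,

$$u(q) = \log_2\!\frac{1 + a_1 + 2a_0 q +
  2\sqrt{a_0 q\,(1 + a_1 + a_0 q)}}{4 a_0},$$

applied to normalized counts $q$. It is monotone in the count, approaches
$\log_2 q$ for large counts, and is invariant to rescaling counts and size
factors together. When $a_0 = 0$ the transform falls back to
$\log_2(q+1)$ and the provenance records it.

**Age filter.** The published analysis excludes genes correlated with
donor age but states neither the test nor the threshold. Defaults here:
Pearson correlation, Benjamini-Hochberg adjustment, $\alpha = 0.05$; both
configurable, and the removal list is always returned so the choice is
auditable. Constant genes get $p = 1$ by convention. Note that because the
cancer group is older, genuinely informative genes can also correlate with
age and be removed — that is the price of the design, visible in the
audit list.

**Surrogate variables.** Re-implemented as residual SVD with
permutation parallel analysis: residualize expression on the diagnosis
factor (the protected covariate), SVD the residuals, and keep the leading
components whose singular values exceed the 95th percentile of B = 20
within-gene permutations of the residuals (rank by rank, stopping at the
first failure). Each gene is then regressed on diagnosis and the kept
components jointly and only the surrogate contribution is subtracted, so
group contrasts are protected. The ordering question — age filter before or
after surrogate-variable analysis — is not answered by the published
methods; this package fixes age-filter-first, because the age effect is a
known, measured covariate and removing it first keeps the latent-factor
estimation from spending components on it.

**Split.** Stratified by group × stage. Either a fraction per stratum or
exact per-stratum counts; `referenceTrainCounts()` reproduces the published
202/120 design. (The published training-set sentence contains an internal
inconsistency in the UC count — 24 would make 132 controls, not the stated
122, and would overrun the UC group total; 14 reconciles every marginal, so
14 is used.) Strata with fewer than 2 samples go wholly to training with a
warning.

## BPSO feature selection

Each particle is a bit vector over genes. Per iteration and dimension:

$$v_d \leftarrow v_d + \varphi_1 (p_d - x_d) + \varphi_2 (g_d - x_d),
\qquad x_d \leftarrow I[\mathrm{rand}() < S(v_d)],$$

with $S(v) = 1/(1+e^{-v})$, $p$ the particle's best, $g$ the global best.
Fitness is the pooled AUROC of a stratified 10-fold cross-validated SVM
restricted to the selected genes (for more than two classes, the average
one-vs-rest AUROC on the same folds). The iteration count, the classifier,
the fitness and the fold count follow the published method (100 iterations,
SVM, AUROC, tenfold).

Everything else the publication leaves open, and the defaults are the
package's choices, logged in the resolved configuration:

* **Swarm size** 50 — standard BPSO practice.
* **$\varphi$ distribution**: "random positive number" is all that is
  stated; Uniform(0, 2) per term, per particle, per dimension matches
  canonical PSO acceleration bounds.
* **No inertia weight** — the printed update carries $v$ over with
  coefficient 1, and that is implemented literally.
* **Velocity clamp** $v_{\max} = 4$, keeping $S(v) \in [0.018, 0.982]$.
  The printed equation has no clamp, but unbounded velocities saturate the
  logistic and freeze bits permanently; the clamp preserves mixing.
* **Initialization**: positions Bernoulli(`initProb` = 0.05) — sparse,
  because plausible panels are a few percent of the gene universe — and
  velocities at $\mathrm{logit}(0.05)$, not 0. This is the one place the
  implementation departs from the obvious choice deliberately: with
  $v = 0$ the very first resampling sets every bit with probability
  $S(0) = 1/2$, which destroys the sparse initialization, inflates panels
  toward $D/2$, and makes each fitness evaluation an order of magnitude
  slower. Starting velocities at the logit of the inclusion prior makes
  the initial position distribution stationary under the transfer map:
  absent any attraction, particles keep sampling from the sparse prior.
  `psoConfig(vInit = "zero")` restores the naive behavior.
* **Parsimony tie-break**: at exactly equal fitness, the smaller panel
  wins (both for personal and global bests). Without it the search has no
  pressure toward compact panels once the fitness saturates.
* **Empty masks** score 0 rather than being repaired, and the position
  update forces at least one bit on, so the convention never traps the
  swarm.
* **Caching**: fitness values are memoized by mask, since swarms revisit
  positions; on small feature spaces this makes the default budget cost no
  more than exhaustive enumeration.

The global-best fitness is asserted non-decreasing at every iteration (it
is also a validity invariant of the returned object). For feature spaces
small enough to enumerate ($D \le 10$), the swarm at default budget reaches
the exhaustive-search optimum on identical folds — this oracle equivalence
is part of the test suite at $D = 8$, $n = 60$.

The multiclass panel question (one-vs-rest versus a single multiclass
fitness) is likewise unstated in the publication; this package uses
one-vs-rest AUROC averaging on shared folds.

## The final classifier and evaluation

`buildFinalClassifier()` trains the production SVM on the panel genes,
optionally appending standardized serum CEA/CA199 columns; missing serum
values are imputed with the training median and the affected samples
flagged. Standardization parameters are frozen from training data. For
multiclass tasks, per-class scores are softmaxed one-vs-rest decision
values — deterministic, unlike libsvm's internal Platt scaling, which
consumes an unseeded C RNG.

The evaluation suite:

* **ROC/AUROC** (`rocAuc`): tie-grouped empirical curve whose trapezoidal
  area is bit-identical to the Mann-Whitney normalization (ties count
  one-half); DeLong variance for the 95% interval.
* **DeLong comparison** (`compareAucDelong`): two-sided z-test, paired
  (placement covariance subtracted) or unpaired. The publication reports
  p-values for panel-versus-CEA comparisons without naming a test; paired
  DeLong is the ecosystem default and is what is implemented.
* **Confusion metrics** (`confusionMetrics`): accuracy, sensitivity,
  specificity, PPV, NPV with exact Clopper-Pearson 95% intervals, Cohen's
  kappa with marginal-product expected agreement, F1 as the harmonic mean
  of PPV and sensitivity. Empty margins yield `NA`, not errors.
* **Hand-Till M** (`handTillMulticlassAuc`):
  $M = \frac{2}{c(c-1)}\sum_{i<j}\hat A(i,j)$ with
  $\hat A(i,j) = [A(i|j) + A(j|i)]/2$, each $A(i|j)$ the AUC of the class-i
  probability restricted to the i/j samples.
* **LOOCV** (`loocvEvaluate`): n fits, pooled held-out decision values
  into one ROC; hard labels at the SVM boundary (0) feed the confusion
  matrix. The Youden-optimal threshold was considered and rejected as the
  default because the boundary is what a deployed SVM uses; the scores are
  returned so any threshold can be applied post hoc. When a selector
  function is supplied it is refit inside every fold, so selection cannot
  leak the held-out label.
* **Per-stage sensitivities** (`sensitivityByStratum`): TP/(TP+FN) among
  true positives per TNM stage, reported as "k/n" and percent.

## Numerical choices and degenerate inputs

Ties in scores use the average-rank (one-half) convention everywhere,
bit-exact between the curve and the U-statistic. Degenerate DeLong variance
reports `p = NA` with a diagnostic (or `p = 1` when the curves are
identical). Constant expression rows: correlation p-value 1 (age filter),
standardization SD forced to 1 (SVM features). Seeds: one global seed fans
out to per-stage child seeds by a fixed integer derivation, so any stage
can be rerun in isolation; two runs with equal configuration are
bit-identical down to the serialized report.

## Problem sizes used by the checks

The test suite and the acceptance script run at desk scale, sizes chosen
once: the swarm-vs-exhaustive oracle at $D = 8$, $n = 60$; panel recovery
on a 120-sample, 500-gene cohort with 20 informative genes at log2FC 1.0
and dispersion 0.2 (default swarm budget); age/batch recovery on
322-sample cohorts with 300-400 genes; the end-to-end acceptance pipeline
on the full 322-sample design with a 1500-gene universe, 80 informative
genes, the reference 202/120 split, and a 30-particle, 40-iteration swarm.

## Known limitations

* The published headline AUROCs (0.928 training LOOCV, 0.92 internal,
  0.915 external validation) are properties of the deposited patient
  cohort; synthetic cohorts make no claim to reproduce them, and the
  package's checks are recovery and calibration properties instead.
* Pooled-LOOCV AUROC is a pessimistically biased, high-variance estimator
  under the null: each held-out sample is scored by a model that lost
  exactly that sample's local influence, so null AUROCs scatter well below
  0.5 (deviations of −0.3 at n = 100 are observed, with any kernel, with
  or without per-fold selection, and per-fold score calibration does not
  remove the effect). Training-set LOOCV numbers should therefore be read
  as conservative, and the held-out validation AUROC is the figure to
  trust. This is a property of the estimator, not of the selection loop;
  the leakage direction (optimistic bias from selection outside the folds)
  does not occur when the selector is refit per fold.
* The internal-validation sensitivity/specificity pair published for the
  reference study (0.885/0.868) does not reconcile to any integer
  confusion matrix under that study's own 52/68 split; the package does
  not attempt to reproduce that column.
* Surrogate-variable counts on rich expression data can be large (real
  residual correlation from unremoved confounders is picked up); the
  group factor is protected, but over-removal of k components trades
  variance for bias like any factor-correction method.

## A worked micro-example

```{r example, eval = FALSE}
spec <- cohortSpec(nGenes = 500, nInformative = 20, nAgeGenes = 25,
                   seed = 101)
cohort <- simulateCohort(spec)
prep <- preprocessCohort(cohort, seed = 101)
md <- as.data.frame(sampleInfo(cohort))
split <- splitTrainValidation(md, trainCounts = referenceTrainCounts(),
                              seed = 5)
tr <- md$sample_id %in% split$train
fit <- runBpso(prep$expr[, tr], taskLabels(md)[tr], psoConfig(seed = 9))
fit
evaluatePanel(fit, prep$expr[, tr], taskLabels(md)[tr],
              prep$expr[, !tr], taskLabels(md)[!tr])$roc
```

`runPipeline()` wires the same stages together with one global seed and
returns a report object that `writeReport()` serializes to JSON.
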