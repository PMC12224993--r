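---
title: "Methods: TME subtype discovery and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TME subtype discovery and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tmesubtyper)
```

This vignette documents the statistical model behind `tmesubtyper`, the
assumptions it makes, the parameters that matter, and the design choices
taken where several defensible options existed. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## The mixture model of bulk expression

The package treats a bulk expression profile as a noisy linear mixture of
cell-type profiles:

$$ m_g \;=\; \sum_{c} B_{gc}\, f_c \cdot \varepsilon_g, \qquad
   \varepsilon_g \sim \mathrm{LogNormal}(0, \sigma^2), $$

where $B$ is a genes × cell-types basis (signature) matrix, $f$ the
per-sample fraction vector and $\varepsilon$ multiplicative noise. Every
stage of the pipeline is an operation on this model: deconvolution inverts
it per sample, subtype discovery clusters the inferred $f$, and the
classifier short-circuits deconvolution by predicting the cluster directly
from a panel of subtype-discriminative genes.

### Deconvolution (nu-SVR)

`nusvr_deconvolve()` regresses one mixture on the signature columns with a
linear-kernel nu-support-vector regression, the estimator popularized for
leukocyte deconvolution. Choices:

* **Whole-matrix standardization.** Mixture and signature are z-scored over
  the shared genes before regression (the signature as one block, so that
  relative column magnitudes are preserved). The SVR intercept absorbs the
  affine shift; normalization of the weights removes the scale.
* **nu grid `{0.25, 0.5, 0.75}`**, best fit chosen by reconstruction RMSE,
  ties to the smallest nu. nu controls the fraction of support vectors —
  effectively how many genes drive the fit.
* **Relative mode.** Negative coefficients are clipped and the remainder
  normalized to sum 1. Fractions are used only as clustering features here,
  so no absolute-score mode or permutation p-values are provided.
* **Gene floor.** At least 50 shared genes are required; with fewer, the
  regression is badly underdetermined and the function stops rather than
  guessing.
* The fibroblast feature is not deconvolved: fibroblasts are absent from
  the 22-type leukocyte signature, so their abundance is scored as the mean
  log2 expression of marker transcripts (`marker_mean_score()`), the
  standard marker-mean estimator for non-leukocyte populations.

An exact non-negative least squares solver (`nnls_deconvolve()`, via
`pracma::lsqnonneg`) ships alongside as the independent reference; the test
suite checks the SVR against it on noiseless mixtures (agreement within
0.05 per cell type).

### Feature standardization

The 22 fractions live on a 0–1 scale, the fibroblast score on a log2
scale; clustering them together requires per-feature z-scoring. A feature
that is constant across samples is mapped to an all-zero column (with a
warning) rather than NaN, so degenerate cohorts fail soft.

## Subtype discovery

`consensus_cluster()` re-implements resampling consensus clustering:
`reps` times, 80% of samples are drawn without replacement and partitioned
by k-means (10 restarts); consensus(i, j) is the fraction of co-clusterings
among co-samplings. Final labels come from an average-linkage hierarchical
cut of `1 − consensus` — the behavior of the widely used consensus-cluster
wrapper. Repeat $r$ is seeded `seed + r`, making runs reproducible and
embarrassingly order-independent; samples are processed in sorted-id order
internally so results are exactly invariant to input permutation.

**Model selection** uses the PAC statistic — the fraction of off-diagonal
consensus entries strictly inside (0.1, 0.9). A stable k yields a nearly
binary consensus matrix and PAC near 0. `select_k()` minimizes PAC, ties
toward smaller k (parsimony). The delta-area criterion was considered and
rejected as the selector because PAC has the cleaner operational definition
and equals 0 exactly in the fully stable case.

**Naming** is rule-based from the cluster phenotypes: IA is the cluster
with the maximal mean standardized CD8 T-cell feature; of the remaining
two, IE is the one with the larger stromal (fibroblast + endothelial when
present) mean; IS is the last. Exact ties abort with a request for manual
naming rather than resolving arbitrarily — in practice ties indicate a
degenerate clustering.

## Panel selection

Pairwise Wilcoxon rank-sum tests (normal approximation, BH correction per
comparison) define per-subtype up-lists. A gene must clear `adjusted_p <
0.05` **and** `log2FC >= 1` against *both* other subtypes — the strict
reading of "pairwise"; a one-vs-rest reading admits genes elevated in two
subtypes at once, which the subsequent shared-gene removal would have to
delete anyway. Genes appearing in two or more lists are removed from all
(`remove_common()`, idempotent). Finally a random forest on the candidates
ranks permutation importance (mean decrease in accuracy, unscaled) and
keeps genes above the mean importance — a deliberately simple "redundant
genes removed" rule. Because permutation importance is shared among
correlated markers, heavily redundant candidate sets retain fewer genes per
signal; this is intended behavior, not information loss, since the dropped
genes are precisely the redundant ones.

The Wilcoxon test was chosen over moderated-t/count models because the
pipeline must run unchanged on microarray intensities, RNA-seq and
normalized pseudobulk; rank tests are scale-robust across all three.

## The six-model ensemble

Learners and defaults (all CLI-overridable, all recorded in the bundle):

| learner | implementation | defaults |
|---|---|---|
| SVM | `e1071::svm`, RBF kernel | probability calibration by internal CV |
| random forest | `randomForest` | 500 trees |
| neural network | `nnet` | 1 hidden layer, 16 units, max 500 iterations |
| gradient boosting | `xgboost` | 300 rounds, depth 3, 1 thread |
| decision tree | `rpart` | depth ≤ 6 |
| k-NN | `caret::knn3` | k = 11 |

Features are the panel genes z-scored with training-split statistics.
The cohort is split 3:1 per class (stratified, ±1 sample). Each learner is
seeded from the base seed, so identical data and seed reproduce identical
models bitwise. The ensemble probability is the unweighted mean of the six
class-probability vectors — the simplest soft vote; weighting schemes were
deliberately avoided since no principled weights are available without
nested validation. Argmax ties break by the fixed class order (IA, IE, IS),
documented and deterministic. Training metrics are resubstitution metrics
on the training split, reported alongside the internal-validation metrics,
so over-fitting is visible as their gap.

## Applying the model across platforms

New cohorts are z-scored **within the cohort** by default, not with the
training statistics: a model trained on one platform (e.g. microarray) and
applied to another (RNA-seq, targeted panels) would otherwise inherit the
training platform's location/scale. Strict reuse (`use_train_stats = TRUE`)
remains available and is required for cohorts of fewer than 3 samples,
where cohort statistics are undefined.

Missing panel genes are imputed as 0 — the cohort mean after z-scoring, the
least-informative value. Classification requires at least 40% of panel
genes; below that the call is refused. If any single subtype's panel
coverage falls below 0.6, calls additionally carry a merged `IE/IS` label,
generalizing into a policy the practical need (observed on targeted
gene panels) to pool the two therapy-resistant subtypes when one of them
is no longer identifiable from the genes present.

## Single-cell path

QC order is genes first (detected in ≥ 10 cells), then cells (≥ 500 UMIs,
≥ 100 detected genes, < 25% mitochondrial counts, prefix `MT-` by
default). The two published thresholds for detected genes (an initial 200
and a later 100) conflict; the looser 100 is the default and the stricter
value is a flag away. Pseudobulk aggregation sums raw counts per sample
and normalizes to log2(CPM + 1) — the between-sample normalization is
unavoidable because library depth varies by orders of magnitude across
samples. Per-cell subtype scores are means of gene-wise z-scored
log-normalized expression over each subtype's top up-regulated gene set;
genes constant across cells contribute 0.

## The synthetic-data generator

`simulate_cohort()` generates the reference study conditions used by the
test suite and acceptance script:

* 23 cell types carrying the standard leukocyte labels plus fibroblasts;
  5 marker genes per type among 500 genes; baseline basis entries
  LogNormal(meanlog 1, sdlog 0.5).
* Subtype-specific Dirichlet mixing, total concentration mass 30. Elevated
  types (IE: fibroblasts, M2, resting DCs, eosinophils; IS: neutrophils,
  M0, activated mast cells; IA: CD8, M1, Tfh, activated memory CD4) carry
  6× the baseline mass; CD8 in IS carries 0.2×.
* Markers are elevated 2^5.5 ≈ 45-fold within their own cell type.
* 100 samples per subtype; lognormal expression noise σ = 0.5; matched
  single cells drawn per sample (cell type from the sample's fraction
  vector, counts negative binomial, dispersion 0.5, mean library 5000).

The marker elevation and mixing contrast were fixed by a dilution argument,
not by tuning: a marker of cell type $c$ with within-column elevation $E$
appears in bulk with fold change
$(1 + (E-1) f_{hi}) / (1 + (E-1) f_{lo})$ between subtypes whose mean
$c$-fractions are $f_{hi}$ and $f_{lo}$. With a 3× concentration boost and
$E = 2^3$ this is ≈ 1.4 (log2FC ≈ 0.46) — an elevation that real marker
genes exceed easily but that sits *below* the pipeline's own DEG threshold
of log2FC ≥ 1, so planted markers would be undetectable by design. The
defaults (6× mass, $E = 2^{5.5}$, within the tens-to-hundreds-fold
enrichment canonical lineage markers show) put the mixture-level contrast
at log2FC ≈ 1.5–2, comfortably detectable while still requiring genuine
statistical recovery under σ = 0.5 noise.

Seed handling: substreams `seed+1` (basis), `seed+2` (fractions), `seed+3`
(noise), `seed+4` (cells) are independent, so e.g. changing the noise level
leaves the planted fractions bitwise unchanged.

What the generator does **not** emulate: real platform effects (probe
saturation, GC bias, batch structure), correlated marker programs shared
between cell types, tumor-cell contamination of signatures, doublets or
ambient RNA in the single-cell counts, and any survival/clinical structure.
Passing tests therefore demonstrate correctness of the algorithms under
the linear-mixture model, not performance on any particular real cohort.

## Problem sizes and runtime choices

The reference conditions are 300 bulk samples; consensus clustering uses
200 repeats in the end-to-end checks (the discovery default is 1000) and
the pseudobulk check uses 30 samples × 2000 cells. Unit tests run a
60-sample, 200-gene configuration of the same generator. These sizes keep
the default test run to a few minutes while leaving every statistical
margin (recovery ARI, held-out accuracy) far from its threshold.

## Serialization and integrity

A trained ensemble persists as a directory: `manifest.json` (format
version, class order, panel, hyperparameters, training seed, payload
checksums) plus one serialized payload per learner and one for the
preprocessing state. Checksums (MD5 via `tools::md5sum`) are verified on
load, so truncated or tampered bundles are rejected; a reloaded bundle
reproduces predictions bit-identically.

## Symbol handling and non-human data

All gene symbols are uppercased at ingestion, which resolves human
case-variant symbols and, incidentally, maps most mouse symbols onto their
human orthologs by capitalization. For species where capitalization is not
a faithful ortholog map, `read_expression(alias_map = ...)` accepts an
explicit two-column translation table applied before matching; no built-in
ortholog table is shipped.

## Known limitations

* The shipped signature matrix and 134-gene panel are synthetic stand-ins
  (labelled as such) demonstrating the expected layouts; analyses of real
  cohorts need measured references.
* Deconvolution assumes the signature spans the mixture; strong
  tumor-content variation violates this and biases fractions toward the
  closest available columns.
* The DEG step tests location shifts only; subtype markers defined by
  variance or bimodality are not selected.
* No batch correction, doublet removal or data integration is performed;
  those belong upstream of this package.
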