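---
title: "Grouping complex substances: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouping complex substances: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemgroup)
```

`chemgroup` quantifies whether an analytical chemistry fingerprint — a
samples × features table from GC-MS, GC×GC-FID or IM-MS post-processing —
supports grouping complex substances (UVCBs, certified reference materials)
into a proposed categorization such as manufacturing classes. This vignette
is the package's own account of the statistical machinery: what is modeled,
which knobs matter, which conventions were chosen where several were
defensible, and what the synthetic evaluation does and does not demonstrate.

## Data model and preprocessing

The working object is a tibble whose first column holds unique sample IDs
and whose remaining columns are numeric features (non-negative intensities
on ingest). Three-way profiles (sample × elution axis × analyte) enter in
long form and are either *unfolded* — one column per (axis1, axis2)
combination, named `axis1|axis2` in axis1-major order — or *collapsed* by
summing each analyte trace over the elution axis, keeping a selected analyte
panel (e.g. a PAH m/z panel).

Preprocessing is a sequence of explicit, individually testable steps rather
than a monolithic routine, because the appropriate order differs between
data sets (some instruments' post-processing software already row-scales its
output, in which case the row-scaling step is simply skipped):

* **Missing values** denote undetected composition and are imputed as exact
  zeros (`impute_missing_zero()`), not estimated.
* **Low-variance filtering** removes features whose sample standard
  deviation (denominator $n-1$ throughout the package; one convention,
  tested, not configurable) is zero or below a threshold.
  The default threshold 0 removes only constant features; 0.05 is a
  reasonable choice for small row-scaled tables where near-constant columns
  are noise.
* **Row min-max scaling** maps each sample's profile to $[0,1]$, removing
  overall-intensity differences between runs. **Column min-max scaling**
  (applied on top, before classification) equalizes feature leverage.
  **Row z-scoring** (mean 0, SD 1) precedes the SVD. Constant rows or
  columns map to all zeros under every scaling — a declared convention for
  the 0/0 case; such columns carry no information and are caught by the
  filter.

One caution discovered during evaluation and worth stating as a general
warning: when only a handful of features carry class signal, row min-max
scaling *spreads* that signal into every other feature, because the row
range itself becomes class-dependent. For feature-attribution questions
(importance ranking, ToxPi) the column-scaled, non-row-scaled table is the
cleaner input; for clustering whole profiles the row scaling is what removes
nuisance intensity variation.

## Reduced-rank de-noising

`reduced_rank_scores()` applies a singular value decomposition to the
row-z-scored matrix exactly as given (no additional column centering) and
keeps the smallest rank $r$ such that
$\sum_{i \le r} \sigma_i^2 / \sum_i \sigma_i^2 \ge$ `threshold` (default
0.85). "Variation" is defined as squared singular values — the standard
SVD energy. The reduced representation is the $n \times r$ score matrix
(data projected on the leading right singular vectors), i.e. components
*replace* features downstream, rather than a rank-$r$ reconstruction in the
original feature space. Each right singular vector is oriented so its
largest-magnitude loading is positive; this removes the sign
indeterminacy of the SVD and makes scores reproducible across platforms and
sample orderings.

## The unsupervised workflow and its test

Samples are clustered by average linkage (UPGMA) on the correlation
distance $d = 1 - r_{\text{Pearson}}$ between profiles (similarity
converted to distance by the standard $1-r$, which preserves ordering; exact
merge ties are broken deterministically by the agglomeration
implementation). The reference side of the comparison is an *artificial
dendrogram*: categories are one-hot encoded and Euclidean distances taken,
so within-category pairs sit at distance 0 and between-category pairs at
$\sqrt 2$. This two-level structure makes the reference tree's cut at $k$
(the number of categories) recover the categorization exactly regardless of
linkage, so the same average linkage is used for consistency. Both trees cut
at $k$ are compared by the Fowlkes–Mallows index

$$\mathrm{FM} = \sqrt{\frac{TP}{TP+FP} \cdot \frac{TP}{TP+FN}}$$

with pair counts over all $\binom{n}{2}$ sample pairs, computed from the
contingency table of the two partitions (the test suite checks it against a
literal pair-enumeration oracle). FM is defined as 0 when $TP = 0$ (e.g.
all-singleton partitions), a degenerate-case convention: comparing two
all-singleton partitions yields 0, not 1, because no co-grouping evidence
exists. Since cutting the reference tree reproduces the categorization,
comparing tree-to-tree at one $k$ and tree-to-fixed-partition are the same
computation; both entry points exist and are tested to agree.

Significance: the category labels are shuffled over samples (class sizes
preserved), the FM against the same tree cut recomputed `n_perm` times
(default 1000), and $p = \#\{\mathrm{FM}_{perm} \ge \mathrm{FM}_{obs}\}/n_{perm}$.
Ties count as exceedances — the conservative reading — with a
strict-inequality option (`ties = "gt"`). The default significance level is
$\alpha = 0.05$.

Two statistical properties of this test deserve explicit mention:

* **Discreteness.** FM takes finitely many values; for small $n$ (a dozen
  samples) its null support is coarse and p-values have sizable atoms, so
  the p-value distribution under independence is only approximately uniform.
  The distributional check in the test suite therefore runs at 40 samples in
  4 balanced classes, where the support is fine enough for a
  Kolmogorov–Smirnov comparison against the uniform; at smaller $n$ the test
  remains valid (conservative), just coarser.
* **Pseudo-replication.** Replicate runs of one substance always share a
  category. If replicates cluster by substance — which any competent
  instrument guarantees — the sample-level label shuffle breaks that
  dependence and the test will, correctly, call the agreement significant
  even when classes beyond the substance level are uninformative. A
  significant FM therefore certifies "grouping is better than label
  chance", not "the categorization adds information beyond replicate
  identity". The null-calibration checks in the test suite accordingly
  simulate with substance-level offsets disabled, so labels are genuinely
  independent of the data.

## The supervised workflow

`tune_and_fit_forest()` tunes the number of features tried per split
(`mtry`) by leave-one-out cross-validation — one forest per held-out sample
per grid value, 500 trees each by default — over the grid
$\{1, \lceil\sqrt p\rceil, \lceil p/3\rceil, \lceil p/2\rceil, p\}$,
breaking accuracy ties toward the smallest (most regularized) value, then
refits on all samples. The headline accuracy is the LOO-CV accuracy at the
tuned value; out-of-bag accuracy of the final fit is reported alongside.
Features are internally put in a canonical sorted order so results do not
depend on incidental column order; all bootstrap/subsampling randomness
flows from one explicit seed.

When holding out a sample would empty its class (a category represented by
a single sample), the default is an error naming the class; with
`on_empty_class = "drop"` the forest trains without that class, so the
held-out sample is necessarily misclassified — the honest accounting for
designs with singleton categories.

The label-permutation test re-runs the LOO-CV evaluation under shuffled
labels, by default with `mtry` frozen at the observed tuned value (re-tuning
per permutation is available via `retune = TRUE` but multiplies cost by the
grid size); tree count is configurable downward for the permutation runs.
Note that LOO-CV accuracy under permuted labels with preserved class sizes
is slightly *below* the majority-class proportion in balanced designs:
removing the held-out sample leaves its (permuted) class under-represented,
biasing the vote against it. The permuted mean is therefore "near chance"
rather than exactly at it.

`leave_one_substance_out()` withholds all replicates of each substance in
turn — the question being whether a never-seen substance can be categorized
from the remaining database. Substances whose removal leaves their class
without training samples are skipped and reported (`"class emptied"`), since
no model can be built for them.

Feature importance is the permutation mean decrease in out-of-bag accuracy
(unscaled) from the final forest. Two caveats: a mislabeled or atypical
substance in the training set degrades its whole neighbourhood's
leave-one-substance-out predictions, not just its own (fully grown forests
behave locally, like a randomized nearest-neighbour rule); and importance
scores are diluted when scaling has spread class signal across features
(see above).

## ToxPi integration

The top-ranked features (default 10) become ToxPi slices: each selected
column min-max scaled to $[0,1]$ over the visualized sample set — explicit
re-normalization, so the slices are well defined whatever scaling the
classifier consumed. The overall score is the weighted mean of slice
values, with equal weights by default (weights are an explicit argument;
scores are invariant to uniform weight rescaling). `pca_of_scores()` gives a
column-centered PCA map of the slice matrix with the same sign convention as
the SVD module. The radial "pie" rendering (`plot_toxpi()`) is a thin
plotting layer; the scores table is the contract.

## The synthetic generator

`generate_profiles()` emulates the structure of reference-material
fingerprint studies: substances nested in classes, each measured as
replicate runs. Sample values are
$\text{baseline}_f + \text{class mean}_{c,f} + u_{s,f} + \varepsilon_{i,f}$,
with the class term present only on the informative features, the whole
matrix shifted to non-negative intensities, and missing cells injected at an
exact count. Defaults are the study conditions used throughout the
evaluation: 3 classes × 3 substances × 3 replicates (27 samples), 55
features of which 10 informative, class-effect SD 5 against unit-scale
feature baselines, substance and replicate SDs of 0.5 — replicate noise
smaller than class separation, as good instruments deliver, while still an
order of magnitude above numerical noise.

What the generator does **not** emulate: correlated features (real m/z
channels co-vary strongly within compound families), heteroscedastic and
multiplicative noise, batch drift, non-Gaussian intensity distributions,
and class-dependent missingness. Passing the evaluation therefore shows the
machinery is correct and well calibrated — minimal rank selection, exact
pair counting, honest permutation nulls, recovery of planted structure, and
the replicate-count trend (more replicates per substance, higher CV
accuracy) — but does not predict the FM or accuracy values any particular
real fingerprinting technique will achieve.

## Numerical conventions, at a glance

| Choice | Convention |
|---|---|
| Sample SD | denominator $n-1$, everywhere |
| Constant row/column under scaling | maps to zeros |
| Missing token on ingest | empty cell or `NA`; negative values warn, not error |
| Unfolded column names | `axis1|axis2`, axis1-major; numeric-aware key ordering |
| SVD / PCA sign | largest-magnitude loading positive |
| FM with $TP=0$ | 0 |
| Permutation p ties | counted as exceedances (`"ge"`), `"gt"` optional |
| mtry ties in tuning | smallest value wins |
| UPGMA merge ties | deterministic lowest-index agglomeration |

## Problem sizes in the shipped evaluation

The test suite and the end-to-end script run at desk scale, chosen to keep
each statistical check comfortably powered: 200 random partition pairs for
the pair-counting oracle; 100 random label vectors for reference-tree
recovery; 1000 permutations for the exhaustively enumerable 4-sample null
and 200 for each of 200 datasets in the uniformity check; 20 seeds for the
null-effect, feature-recovery and parameter-recovery simulations; 12 seeds
for the replicate-count trend (100-tree forests, 20 features); and 500-tree
forests on the 27 × 55 default conditions in the end-to-end script, with
200 label permutations at 100 trees for its accuracy null.
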