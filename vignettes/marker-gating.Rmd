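---
title: "Marker-based hierarchical gating: methods and design notes"
author: "MarkerGate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based hierarchical gating: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MarkerGate)
```

# The problem

A recurring task in single-cell analysis is to *purify* one cell
population from a heterogeneous dataset: keep the B cells, keep the
macrophages, discard everything else. Practitioners usually do this by
hand — score a few marker genes, draw a threshold, subset, repeat. By
analogy with flow-cytometry gating, MarkerGate automates the procedure:
the user supplies a *gating model*, a small hierarchy of positive and
negative marker signatures, and each cell comes back labelled `"Pure"`
or `"Impure"` with respect to the target population. No reference
profiles and no training data are involved; the only knowledge used is
which markers define the population.

The same machinery applies to any non-negative cell-by-feature matrix:
RNA counts, CITE-seq antibody tags (`modality = "adt"`), or per-gene
chromatin-accessibility activity scores derived from scATAC data.

# The score statistic

For one cell with expression vector $x$ over $p$ features, features are
ranked by *descending* value; tied values receive the mean of their
rank span. Ranks are clamped at a ceiling $r_{\max}$: any rank beyond
it is replaced by $r_{\max}+1$, which makes the statistic insensitive
to everything in the long undetected tail. For a signature of $n$
positive genes with clamped ranks $r_1,\dots,r_n$,

$$
U \;=\; \sum_{i=1}^{n} r_i \;-\; \frac{n(n+1)}{2},
\qquad
S \;=\; 1 \;-\; \frac{U}{n\, r_{\max}} \;\in\; [0,1].
$$

$U$ is the Mann–Whitney U statistic of the signature genes against the
rest of the cell's features (the test suite checks this identity
against an explicit pairwise-comparison oracle to $10^{-12}$). $S = 1$
when the signature occupies the top $n$ ranks; $S = 0$ when every
signature gene sits beyond the ceiling. Because only within-cell ranks
enter, $S$ is invariant under any strictly monotone per-cell transform
— library-size normalization is unnecessary for scoring.

A gene negated inside a signature (written `"CD3D-"`) contributes
through a second score $S^{-}$ computed identically over the negated
set, combined as

$$
S_{\text{signed}} = \min\!\bigl(1,\ \max\bigl(0,\ S^{+} - w_{\text{neg}}\,
S^{-}\bigr)\bigr), \qquad w_{\text{neg}} = 1 \text{ by default.}
$$

This is the simplest signed combination consistent with "penalize the
score when the negated gene is active"; $w_{\text{neg}}$ is exposed in
`scoringParams()`. Negated genes are distinct from whole signatures
declared `use_as = negative` in a gating table: the latter are scored
as ordinary positive signatures and act as *vetoes* at the threshold
stage (below). Both mechanisms exist because both idioms are common:
"NK cells are NCAM1+ KLRD1+ CD3D−" versus "reject anything that looks
like a T cell".

## The rank ceiling

$r_{\max}$ encodes how many features a cell can meaningfully express:
a feature ranked beyond it is treated as absent. Two properties are
essential:

* an *undetected* gene (count 0) must contribute zero signal — its
  tie-averaged rank must exceed the ceiling;
* a single stray ambient count must not leap to a high score — the tie
  block of count-1 features should also straddle or exceed the ceiling.

Both depend on the size and sparsity of the feature space, so a fixed
constant cannot serve all matrices. By default (`maxRank = NA`) the
package resolves

$$
r_{\max} \;=\; \min\bigl(1500,\ p-1,\ \operatorname{median}_c
\#\{\text{features detected in cell } c\}\bigr).
$$

On whole-transcriptome data (20–30k genes, a few thousand detected per
cell) this reproduces 1500, the conventional ceiling for such data. On
a small antibody panel it becomes the panel size minus one. On the
2000-feature synthetic fixtures below it resolves to a few hundred,
which is what keeps undetected and singleton-count genes at score
zero. An explicitly supplied `maxRank` is always used verbatim. The
ceiling is resolved **once per run** on the full matrix, so scores stay
comparable across gating levels.

# kNN smoothing

Dropout makes raw per-cell scores noisy: a genuine B cell may simply
fail to capture its MS4A1 transcript. Each cell's score is therefore
replaced by the unweighted mean over its $k$ nearest neighbours (self
included) in a PCA embedding:

1. per-cell scaling to a fixed total (`targetSum = 10^4`), `log1p`;
2. the `nHVG = 800` most variable features (skipped for ADT panels,
   which are small and fully informative);
3. per-feature standardization; exact truncated SVD to
   `nPCs = 30` dimensions (component signs fixed deterministically, so
   runs are bit-reproducible);
4. exact Euclidean kNN, distance ties broken by lower cell index.

Smoothed values are convex combinations of raw values, hence bounded
by the raw per-signature range; `k = 1` is the identity and constant
fields are fixed points (all asserted in the tests).

**Choice of `k = 30`.** Averaging over $k$ exchangeable neighbours
shrinks score noise by roughly $\sqrt{k}$. With a fixed gate threshold
of 0.2 the binding constraint is the upper tail of the *background*
score distribution: cells outside the target population accumulate
nonzero scores from ambient marker counts, and the threshold sits only
about one standard deviation above the background mean before
smoothing. A neighbourhood of 10 (shrinkage ≈ 3.3×) leaves too much
of that tail above threshold for high-precision single-marker gates;
30 (shrinkage ≈ 5.5×) suppresses it while staying an order of
magnitude below the population sizes the tool targets, so
neighbourhoods remain population-pure. Datasets with populations of
only a few dozen cells should lower `k` accordingly (the rare-ionocyte
preset is the stress case).

# The gating hierarchy

Each level of a gating model is a filter over the cells that survived
the previous level. A cell passes a level iff

* the maximum over the level's positive signatures is **at or above**
  `posThreshold` (a cell exactly at threshold counts as detected), and
* every `use_as = negative` signature stays **strictly below**
  `negThreshold` (a veto exactly at threshold fires).

Both thresholds default to 0.2 on smoothed scores and can be
overridden per signature (`signatureThresholds`). Vetoes are
level-local: a negative signature at level $k$ is not re-applied at
deeper levels. Negative signatures are thresholded on smoothed scores,
like positive ones — smoothing exists to de-noise the evidence, and
vetoes deserve de-noised evidence too.

By default the embedding, graph and smoothing are **recomputed on the
surviving subset** before each deeper level
(`recomputeGraphPerLevel = TRUE`): when purifying macrophages from
immune cells, neighbourhoods should be neighbourhoods *among immune
cells*. The off-switch trades this for speed. If fewer than two cells
reach a level, no neighbourhood exists; the survivors are passed
through with a warning rather than silently discarded.

Failure is absorbing (a cell failing level $k$ fails all deeper
levels), so the pure set shrinks monotonically down the hierarchy and
the final `"Pure"` label equals the intersection over levels — an
invariant the engine asserts on every run.

# Evaluation

`confusionCounts()` joins calls to truth by cell id and
`classificationMetrics()` reports precision $tp/(tp+fp)$, recall
$tp/(tp+fn)$ and the Matthews correlation coefficient

$$
\mathrm{MCC} = \frac{tp\cdot tn - fp\cdot fn}
{\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}.
$$

Whenever a denominator vanishes the metric is reported as 0 with an
explicit `*Defined = FALSE` flag — never `NaN` — so means over many
runs stay computable. `evaluateModels()` runs a model collection over
annotated datasets and reports unweighted means of precision and MCC
across rows (cell-count weighting would let one large dataset dominate
a model-quality summary).

# The synthetic data generator

Real annotated single-cell datasets are large external downloads, so
the package carries a seeded generator used by its tests and examples.
Counts follow a zero-inflated negative binomial: gene $g$ in
population $q$ has NB mean `baselineMean` (default 0.3), multiplied by
`markerFold` (default 8) if $g$ is one of $q$'s markers, with NB size
`dispersion` (default 1.5); every count is additionally zeroed with
probability `dropoutExtra` (default 0.3). Presets use 500 cells per
population and 2000 features. These values produce matrices with
roughly 15–20% detected features per cell and frequent marker dropout —
sparse enough that raw scores genuinely need smoothing, which is the
regime the method is built for.

Each preset population elevates its canonical markers (real symbols,
so literal models like `gatingModel("NK", c("NCAM1","KLRD1","CD3D-"))`
run unchanged) **plus a private 40-gene program** at the same fold.
The program is deliberate: real cell types differ in coordinated
transcriptional programs, and the PCA/kNN stage relies on that
correlated structure to form population-pure neighbourhoods. With
isolated single markers in an otherwise i.i.d. matrix, no embedding
method could recover neighbourhoods and smoothing would average across
populations. The `nk-vs-t` preset additionally gives its T population
KLRD1 at full fold — mirroring KLRD1/CD94 expression on effector and
NKT-like T cells — so that the `CD3D-` veto has real work to do.

What the generator does **not** emulate: within-population gene–gene
correlation beyond shared membership, continuous differentiation
gradients, batch effects, doublets, or ambient-RNA contamination.
Passing tests on these fixtures therefore demonstrate the algorithm's
internal correctness and its behaviour under sparsity and discrete
mixture structure — not performance on tissue atlases, where marker
quality and annotation granularity dominate.

# Numerical conventions

* Tie ranks are averaged (deterministic, permutation-invariant); the
  clamp is applied after averaging.
* kNN distance ties break toward the lower cell index; the cell itself
  is always its own first neighbour.
* SVD component signs are fixed by making each loading's
  largest-magnitude entry positive, so embeddings are reproducible
  across runs on the same platform.
* Smoothed scores are clipped to $[0,1]$ to absorb float drift at the
  boundaries.
* All file writers are atomic (temp file + rename): a failing run
  leaves no partial output.
* `set.seed` state is saved and restored around every seeded
  operation, so library calls never perturb a caller's RNG stream.

# Problem sizes

The test suite exercises the full pipeline at the preset scale (2000
cells × 2000 features for the blood-like mixture, 1500 × 2000 for the
tumor-like hierarchy, 1000 × 2000 for the veto scenario) and uses
smaller mixtures (≈160 cells, 300–500 features, `k = 10`,
`nHVG = 200`) for unit-level engine checks; oracle comparisons run on
50×30 matrices where exhaustive pairwise computation is cheap. These
sizes were chosen so the whole suite completes in well under a minute
while still covering the sparse regime the method targets.

# Known limitations

* One model purifies one target population; there is no multi-model
  annotation with conflict resolution.
* Thresholds are fixed scalars, not data-adaptive; a poorly separated
  marker will not be rescued by the default 0.2.
* Exact kNN is $O(n^2)$ in cells — fine up to a few tens of thousands
  of cells, not for atlas-scale matrices.
* The veto semantics are level-local by design; a veto meant to apply
  globally must be repeated at each level.
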