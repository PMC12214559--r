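---
title: "Identifying senescent neurons with panel eigengenes: models, choices, limitations"
author: "neurescence package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying senescent neurons with panel eigengenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurescence)
```

## The problem

Cellular senescence in post-mitotic neurons (neurescence) has no single
reliable transcript marker. The approach implemented here scores each
nucleus against several senescence gene panels at once — a secretory
(SASP-focused) panel, a canonical cell-cycle-arrest panel, and a
senescence-initiating panel — and only calls a cell senescent when all
panels agree. The labeled cells then anchor differential expression and
the search for minimal marker-gene pairs usable in histology.

## Panel eigengenes

For a panel $G$ of $p$ genes over $n$ cells, expression is
$x_{gc} = \log_2(10^6\,k_{gc}/K_c + 1)$ (counts $k$, cell totals $K$;
a `raw` scale is available via `expressionScale`). The eigengene is the
first principal component: per-cell scores
$s_c = \sum_{g\in G} w_g \tilde x_{gc}$ with unit-norm loadings $w$ and
standardized expression $\tilde x$.

Neuronal datasets are dominated by excitatory cells (roughly 4:1 against
inhibitory), so an unweighted PCA would fit the excitatory covariance.
Each cell therefore receives weight $N/n_{t(c)}$ — total cells over the
frequency of its type — and:

* gene means and s.d.s are weighted by these cell weights;
* each standardized cell profile is scaled by $\sqrt{w_c}$ and the
  leading right singular vector of that matrix gives the loadings. This
  is algebraically the leading eigenvector of the weighted covariance
  matrix, and the test suite verifies both that identity and the
  reduction to plain PCA when all cells share one type.

**Scores are unweighted projections.** The weights shape the component;
the reported per-cell scores are projections of the *unweighted*
standardized data, so a cell's score does not depend on how abundant its
type is. This was a genuinely open choice; the alternative (weighting
the projections too) would make identical cells of different types score
differently, which has no biological reading.

**Orientation.** A principal component is sign-ambiguous. The sign is
chosen so that scores correlate non-negatively with member-gene
expression on average: "high score" always means "panel up".

**Projection onto validation data** uses the discovery loadings, centers
and scales, then rescales the projected vector to the *same Euclidean
norm* as the discovery scores. This norm-matching rule is applied
literally; note its dataset-size sensitivity — duplicating every cell
halves each score by $\sqrt{2}$ (a documented test). Per-cell RMS
matching would remove that sensitivity but would no longer be the same
rule, so the literal behaviour is kept and the caveat documented.
Genes missing from a validation dataset are dropped from the projection
with a warning; zero-variance discovery genes are dropped at fit time.

## Consensus labeling

With score mean $\mu$ and s.d. $\sigma$ over the discovery cells, a cell
is panel-positive above $\mu + 3\sigma$ and panel-negative below $\mu$,
both strict; ties land in the borderline band. A cell is *senescent* iff
positive on all three panels, *non-senescent* iff negative on all three,
otherwise *borderline* and excluded from DE and tree training. The
multiplier 3 and the negative cut are arguments with these defaults. For
validation data, statuses are computed from projected scores against the
*discovery* $\mu$ and $\sigma$ — thresholds are never refit.

Under a Gaussian null each panel's positive rate is
$\Phi(-3) \approx 0.00135$; three roughly independent panels push the
consensus false-positive rate to the $10^{-9}$ scale, which is why the
false-discovery fraction among consensus calls stays low even at 1%
prevalence.

## Differential expression: two independent tests

Genes are pre-filtered to those with a count of at least 1 in at least
200 cells (defaults at discovery scale; scale `minCells` proportionally
for smaller data). Because the senescent class is small, minority cells
are replicated $r = \mathrm{round}(n_{maj}/n_{min})$ times before
testing ($r=36$ at the discovery cohort's 475 vs 16,871 split).

**Hurdle test.** Per gene, a discrete part compares detection
proportions between groups with a 1-df binomial likelihood-ratio
(G) statistic, and a continuous part compares positive-expression means
with the Gaussian LRT $n\ln(\mathrm{RSS}_0/\mathrm{RSS}_1)$ (1 df,
computed only when each group has ≥2 positive cells). The parts are
summed and referred to $\chi^2$ with the summed df. log2 fold change is
the difference in group means over all cells, positive = higher in the
senescent group. Significance: BH-adjusted p < 0.01 and |log2 FC| > 6.
Condition is the sole covariate; a detection-rate covariate is a known
refinement and a deliberate omission here. Null calibration is enforced
by test: empirical type-I error at $\alpha=0.05$ within [0.035, 0.065]
on simulated null data.

**EMD permutation test.** Per gene, both group distributions are
histogrammed on 100 equal-width bins over the pooled range; the EMD is
the L1 distance between the histogram CDFs in bin units (the 1-D
equal-mass optimal-transport cost — verified against an independent
transport oracle). Replicating cells does not change a group's empirical
distribution, so the statistic is computed on original cells, and the
permutation null permutes labels at the original-cell level — replicated
copies of one cell can never straddle both groups, which would corrupt
the null. With few cells the test enumerates all label assignments and
reports the exact fraction; otherwise $p = (b+1)/(n_{perm}+1)$.
Significance: adjusted p < 0.01 and EMD > 30 (both configurable; the
scale on which the conventional EMD cutoff of 30 is defined depends on
the binning, so the default is kept but exposed).

The final DE set is the intersection of the two methods' calls, with an
upper-tail hypergeometric overlap p computed in log space (tail
probabilities far below double precision are reported as log10 p).

## Marker trees

Trees are grown greedily by information gain ratio (the C4.5/C5.0
criterion), splits are `<= t` on observed integer thresholds (threshold
0 in binary mode), a split is admissible only if both branches hold at
least `minCases` cases, depth is capped at 2, and if a fitted tree uses
more than two distinct genes `minCases` is doubled until it does not.
Splits whose two children would be identical leaves are collapsed: they
never change a prediction and should not count against the two-gene
budget. Ties between equally good splits go to the earlier pool gene,
then the smaller threshold, so refits are bit-reproducible.

Training uses the natural class prevalence by default. This was an open
choice (upsampling is a device of the DE stage; nothing requires it for
tree training), and it matters: with balanced classes a tree over two
low-specificity binary markers prefers the OR rule (false-positive rate
$\approx 2p_{off}$), while at 1–3% prevalence a single positive marker is
insufficient evidence and the tree learns the AND rule, which is what
gives the perfect-specificity validation behaviour. `upsample = TRUE`
restores balanced training for users who want sensitivity-leaning trees.

Evaluation against eigengene-derived labels excludes borderline cells
from every denominator; sensitivity is undefined (NA, with a warning)
when there are no truth positives. Accuracy is (TP+TN)/total; the
literal TP/total variant is available behind a flag. The elimination
analysis refits after removing previously selected genes, producing a
ledger of alternative pairs with per-dataset metrics.

## Set statistics

Hypergeometric upper tails accumulate log-gamma mass terms in log space,
so overlap probabilities on the $10^{-200}$ scale are resolved directly rather
than reported as 0. Pathway enrichment intersects each pathway with the
universe (default: the post-filter gene set) and adjusts across pathways
by BH at 0.05. The multi-set intersection test convolves conditional
hypergeometric distributions of the running intersection under
independent uniform placement of each set; it reduces exactly to the
hypergeometric for two sets and is verified against exhaustive
enumeration at small universe size. The right background population for
such overlap tests is frequently ambiguous in practice (all cells? all
neurons? non-borderline neurons?), so the universe size is always an
explicit argument rather than a guessed default.

## The synthetic generator

`simulateDataset()` emulates a post-QC neuronal snRNA-seq experiment:

* **Counts**: negative binomial per gene/cell, mean = baseline × cell
  size factor, dispersion 0.2; dropout arises from low means, not an
  extra zero-inflation channel.
* **Baselines**: log-normal across genes (meanlog 0, sdlog 0.4) — a
  moderately expressed, post-detection-filter universe of 6,000 genes.
  The real analyses operate on exactly such a filtered universe; genes
  far below the detection floor would not enter them.
* **Cell mix**: excitatory:inhibitory 0.79:0.21, matching the
  discovery cohort's neuron ratio; library size factors log-normal
  (sdlog 0.2, i.e. tight post-QC libraries).
* **Planted structure**: a 1% senescent subpopulation with all three
  panels (22/44/116 genes) shifted +2 log2 in those cells; a block of
  324 DE genes shifted +7 log2 whose baselines are scaled down by the
  same factor — a gene with a 128-fold change is near-silent at baseline
  in real sparse data, and anchoring the block there keeps it from
  inflating senescent cells' library sizes and, through CPM
  normalization, depressing every other gene; and two marker genes
  that are positive (1 + Poisson(1) counts) with probability 0.95 in
  senescent and 0.01 in other cells.
* **Determinism**: each stage draws from a sub-seed derived from the one
  global seed, so identical (config, seed) pairs are bit-identical.

`simulateNullDataset()` zeroes every effect while keeping the truth
labels, for type-I-error studies.

**What passing tests do and do not show.** The generator has no batch
effects, doublets, ambient RNA, gene–gene correlation beyond the planted
group structure, or the heavy library-size and sparsity variation of raw
datasets (real cohorts differ markedly in sparsity, and marker
sensitivity drops accordingly). Recovery and accuracy figures on
synthetic data therefore demonstrate correctness of the machinery under
the stated model, not expected performance on arbitrary real cohorts.

## Problem sizes and numerical choices

The test suite exercises labeling recovery at the generator's default
20,000 cells × 6,000 genes over ten seeds, tree recovery at 8,000
training and 500 validation cells over ten seeds, and hurdle calibration
on 2,100 null genes at 150 cells per group; the acceptance script uses
three labeling seeds and a 2,000 × 800 DE demonstration. These sizes
were chosen as the smallest at which the thresholded statistics
stabilize.

Numerical details worth knowing: $0\log 0 \equiv 0$ throughout the
likelihood code; within-group RSS is floored at $10^{-12}$; histogram
binning uses `findInterval(..., rightmost.closed = TRUE, all.inside =
TRUE)`; gain comparisons use a $10^{-12}$ margin so floating-point noise
cannot flip a tie-break; zero-variance genes are dropped at eigengene
fit time with a warning; and all tail probabilities are accumulated in
log space.

## Known limitations

* The expression transform fed to the eigengene PCA is a convention,
  not a constraint; log2(CPM+1) is the default and `raw` is available.
* The literal norm-matching rule makes projected score magnitudes
  depend on validation dataset size (see above).
* The hurdle test omits a cellular-detection-rate covariate.
* The EMD stage implements the distance + permutation core only, not
  any imputation/regularization pre-step.
* Reproducing cohort-specific gene lists and neuron counts requires
  access-controlled human data; everything here is validated on
  synthetic ground truth and on reference summary counts (cohort cell
  counts, DE set sizes, overlap bounds).
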