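---
title: "Methods: tumor-microenvironment subtyping with cccrc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-microenvironment subtyping with cccrc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cccrc)
```

# Overview

`cccrc` implements a tumor-microenvironment (TME) subtyping workflow for
colorectal cancer built around four stages: (1) converting a genes x
samples expression matrix into signature x sample enrichment scores for a
panel of TME signatures (tumor, immune, stroma, metabolic reprogramming);
(2) discovering subtypes by consensus k-medoids clustering of those
scores; (3) transporting the subtypes to new cohorts with a
nearest-shrunken-centroid classifier; and (4) characterising the subtypes
downstream — multi-omic differential analysis, a monotone
"nongenetic evolution" pattern with a per-sample score, a
cancer-cell-intrinsic pre-clinical classifier, and whole-slide-image
patch composition. Every stage can be exercised on seeded synthetic
cohorts with planted ground truth.

# Single-sample enrichment scoring

## GSVA

For gene $i$ with expression $x_{i1},\dots,x_{in}$, a cross-sample kernel
CDF estimate

$$\hat F_i(x) = \frac1n \sum_k \Phi\!\left(\frac{x - x_{ik}}{h_i}\right),
\qquad h_i = s_i/4$$

is evaluated at each observed value. Within each sample, genes are ranked
by $\hat F$ (descending, ties broken by gene order) and mapped to the
symmetric rank statistic $r_{ij} = |p/2 - \mathrm{rank}_{ij}|$. A weighted
Kolmogorov–Smirnov walk over the ranked list,

$$v(\ell) = \frac{\sum_{g(\ell') \in G,\, \ell' \le \ell} r^\tau}
{\sum_{g \in G} r^\tau} -
\frac{\#\{g(\ell') \notin G,\ \ell' \le \ell\}}{p - |G|},$$

yields, with the max-difference convention, the enrichment score
$ES = \max_\ell^+ v + \min_\ell^- v \in [-1, 1]$. A Poisson kernel
(`kcdf = "poisson"`, $\hat F_i(x) = \tfrac1n\sum_k P(X \le x),\,
X \sim \mathrm{Pois}(x_{ik}+0.5)$) is available for count-like inputs.

Numerical choices worth stating:

* **Zero-variance genes.** The bandwidth is floored at $10^{-8}$ so the
  kernel CDF degenerates to a step function instead of dividing by zero.
* **Ties.** All rankings use a stable sort with first-occurrence
  tie-breaking, so results are bit-reproducible.
* **Invariance.** The kernel CDF is exactly invariant to positive affine
  per-gene transforms (the bandwidth rescales with the data); general
  monotone per-gene maps preserve the cross-sample ranks but not the
  kernel-smoothed values, so exact invariance is only asserted for affine
  maps. ssGSEA, by contrast, depends on within-sample ranks only and is
  exactly invariant to any strictly increasing per-sample transform.
* **Minimum set size.** Sets intersected with the gene universe must
  retain at least 2 genes (configurable); smaller sets raise an error
  naming the set.

## ssGSEA

Per sample, genes are ranked by expression descending; the gene at rank
position $\ell$ carries weight $(p - \ell + 1)^\alpha$ with
$\alpha = 0.25$. The score is the summed difference between the weighted
in-set ECDF and the uniform out-of-set ECDF. When `normalize = TRUE` the
whole matrix is divided by its score range — the convention of the tools
this scorer mirrors, stated here because it makes scores comparable only
within one matrix. Spot-level "cell-type-rich" regions
(`rich_region_spots()`) take the spots strictly above the 0.75 quantile
of a cell type's score row, with the type-7 (linear interpolation)
quantile definition.

# Consensus subtyping

Samples are clustered `reps` times on Pearson distance
($d = 1 - \mathrm{cor}$) of their score profiles, each time on a
subsample of $\lceil 0.8\,n \rceil$ samples (the subsample fraction is
the invoked tradition's default; the source protocol states the
iteration count and distance but not the fraction). k-medoids uses the
classical BUILD + SWAP algorithm through `cluster::pam`. The consensus
entry $M_{ij}$ is the co-clustering frequency given co-sampling; final
assignments come from average-linkage hierarchical clustering of
$1 - M$.

Per-replicate seeds are derived from the master seed by a splittable
linear map, so replicates are order-independent and reproducible.

## Choosing k

The empirical CDF of the upper-triangle consensus entries gives the area
$A(k) = \sum_i (x_{i+1} - x_i)\,\mathrm{CDF}(x_i)$, and the relative
gains $\Delta(2) = A(2)$, $\Delta(k) = (A(k) - A(k-1))/A(k-1)$. The
chosen $k$ is the largest one reached before the gain falls below a
threshold (default 0.1), always user-overridable — an explicit numeric
stand-in for the visual "cleanest partition" inspection the protocol
describes.

A caveat the package documents and tests: with *no* structure at all,
co-clustering sits near chance $1/k$, so $A(k)$ tracks $1 - 1/k$ and the
gains follow the mechanical curve
$m(k) = \frac{1 - 1/k}{1 - 1/(k-1)} - 1$ (0.33, 0.13, 0.07, 0.04 for
$k = 3..6$). Structure manifests as an *excess* over this curve, not as
any nonzero gain; the null property test asserts closeness to $m(k)$,
and users should corroborate a chosen $k$ with the consensus-matrix
heatmap rather than the gain curve alone.

# Nearest-shrunken-centroid classification

With class centroids $\bar x_{ik}$, overall centroid $\bar x_i$, pooled
within-class standard deviation $s_i$, fudge $s_0 = \mathrm{median}(s_i)$
and $m_k = \sqrt{1/n_k - 1/n}$, the standardised differences
$d_{ik} = (\bar x_{ik} - \bar x_i)/(m_k (s_i + s_0))$ are soft-thresholded,
$d'_{ik} = \mathrm{sign}(d_{ik})(|d_{ik}| - \Delta)_+$, and samples are
assigned by the discriminant
$\delta_k(x) = \sum_i (x_i - \bar x'_{ik})^2/(s_i+s_0)^2 - 2\log\pi_k$
over surviving features, with posteriors $\propto e^{-\delta_k/2}$.
These are the original nearest-shrunken-centroid formulas; the protocol
cites the implementing package rather than restating them, so they are
fixed here and validated against a formula-by-formula oracle in the
tests.

The threshold grid spans $[0, \max|d_{ik}|]$ in 30 uniform steps;
stratified 10-fold cross-validation (default fold seed 11, matching the
source protocol's seed) selects the *smallest* threshold achieving the
minimum error — the tie-break that retains the most features, consistent
with the protocol keeping most signatures at its chosen threshold.
Priors default to empirical class proportions; uniform priors are a
flag. Cross-cohort use assumes per-cohort row z-scoring of the signature
scores (constant rows map to zero with a warning).

# Differential analysis

Two engines are offered per comparison: a two-sided Wilcoxon rank-sum
(exact enumeration when $n_a + n_b \le 12$, handling ties by full
combinatorial enumeration; a tie-corrected normal approximation
otherwise) and Welch's t. The moderated-t machinery some protocols use
is intentionally out of scope: recovery of planted effects, not matching
a specific variance-moderation model, is what the downstream analyses
rely on. Benjamini–Hochberg correction is applied within each
comparison. Effects are mean differences on the (log) input scale, so
they read as log fold changes for expression and beta-value differences
for methylation.

Subtype-specific markers take each class's significant one-vs-rest
features and remove any feature significant in another class's
comparison — the exclusion rule that makes the per-class lists pairwise
disjoint — optionally truncated to the top $n$ by $|$effect$|$. Note
that a marker planted in one class necessarily leaves a weak "shadow"
signal in every other class's comparison (its samples sit in the rest
group), so the rule interacts with the significance cut; strict cuts
(e.g. $10^{-3}$) keep shadows below threshold at moderate sample sizes.

Methylation support: promoter probes aggregate to gene level by the
per-sample median across mapped probes (missing probes dropped);
differentially methylated genes require normal-tissue mean beta
$< 0.2$, tumor mean beta $> 0.5$ and FDR $< 0.05$, all strict, matching
the stated thresholds.

# The evolution pattern and its score

Features passing each layer's cut in at least one pairwise subtype
comparison are intersected across methylation, expression and protein
layers. The protein cut defaults to p $< 0.5$ — implemented exactly as
the source protocol prints it — with the stricter 0.05 available by
parameter, since the printed value is plausibly a misprint; neither
reading is asserted as intended. For each feature, the six pairwise
effect signs are matched against subtype orderings; a feature is
monotone for an ordering when all six signs agree with it (a transitive
tournament, which has a unique topological order — 24 of the 64 sign
patterns). The strict mode additionally requires every pairwise
comparison to pass the layer's significance cut; a sign-only relaxed
mode is a flag. Monotone-increasing genes shared by two cohorts
(`derive_cccrc_genes()`) form the evolution gene list, and the
per-sample evolution score is the single-set GSVA score of that list.

# Pre-clinical classifier

The marker cascade keeps, per subtype, genes whose human-tumor vs PDX
comparison shows *no* signal (FDR $> 0.5$ and $|$log2FC$| < 1$ — the
absolute value is an interpretive choice: a gene strongly depleted in
xenografts is as stroma-confounded as one enriched), then applies a
cell-line expression gate. The gate's published description is
grammatically ambiguous; the reading implemented is: the gene's maximum
expression across lines lies within the 10–90 percentile range of all
gene maxima, ranks in the top 25% by that maximum, and exceeds a
high-expression threshold in at least 3 lines. The threshold is the
75th percentile of all matrix values — a *global* quantile, because a
per-gene quantile would pass essentially every gene once a panel has a
dozen lines. All pieces are parameters, so alternative readings are one
argument away. The filters are pure and commute.

Nearest-template prediction z-scores each gene over samples, compares a
sample's standardized profile over the marker union to each class's 0/1
template by cosine distance, and assigns the nearest template.
Significance resamples marker positions from the gene universe
(`n_perm` draws, same set sizes, null = minimum distance over class
templates) and reports the fraction of null draws at or below the
observed minimum, exactly as defined — no pseudo-count smoothing — with
BH correction across samples. Calibration under the null is a tested
property (Kolmogorov–Smirnov uniformity at 200 samples, 500 draws).

# Whole-slide quantification

The quantifier consumes patch labels from any provider (the CNN
classifiers that produce them in practice are deliberately out of
scope). Patch validity clips the region polygon against each
224 x 224 px tile (Sutherland–Hodgman, shoelace area) and requires 75%
coverage; a pixel-counting oracle cross-checks the counts in the tests.
The muscle gate calls a patch non-muscle only when its non-muscle
probability strictly exceeds 0.99. Compositions are patch-count
fractions over all eight tissue classes (counts equal areas on a uniform
grid); by default all region patches enter the denominator, with a flag
to exclude muscle, since the source protocol does not state which it
used. Ratios with zero denominators return an explicit undefined marker,
never infinity. The invasive margin is the band within 500 µm outside
the core-tumor contour — the source protocol prints "500 mm", which is
treated as a micron-scale typo consistent with the cited convention; the
unit is a parameter.

# Synthetic cohorts: what they emulate, and what they do not

The generators are pure functions of their parameters and seed:

* `gen_cohort()` — additive Gaussian archetypes: background
  $\mathcal N(0,1)$ on the log scale, plus `effect` added to the
  signature blocks of a sample's subtype, plus an optional per-gene
  batch offset. Defaults encode the reference study conditions: 200
  samples at subtype prevalences 35/21/24/20%, effect 2.5, unit noise,
  and an archetype matrix in which each subtype elevates one signature
  category (C1 tumor, C2 metabolism, C3 stroma, C4 immune). A scalar
  batch shift is invisible to rank-based scoring, so cross-cohort tests
  use per-gene $\mathcal N(0,1)$ offsets.
* `gen_multiomics_evolution()` — 2000 features per layer, 50 of them
  increasing by 1.5 per step along the C1, C4, C2, C3 ordering in all
  three layers, 50 samples per subtype; methylation squashed into
  $[0,1]$ by the logistic function.
* `gen_patch_grid()` — a rectangular CT core, an IM band whose patch
  centers lie within 500 µm outside it at 0.5 µm/px, and region-specific
  categorical label draws.

These are rank-structure emulators, not realistic simulators: no
count-distribution or microarray noise model, no probe-level artifacts,
no spatial correlation between patches, no survival times. Passing the
recovery tests therefore demonstrates that the pipeline's logic recovers
planted structure of the stated effect sizes — it does not certify
performance on real cohorts, where effect sizes, batch structure and
class imbalance are less benign.

# Problem sizes and runtime choices

The test-suite and acceptance-script problem sizes are chosen so the
whole battery runs in minutes on one core while keeping each check at
the scale its statistics need: oracle equivalence on $\le 12$-gene
matrices; consensus recovery at $n = 200$ with 100 resampling
iterations (the full 1000-iteration setting is the package default for
real analyses); calibration on 2000 null features and 500 NTP
permutations; evolution recovery over 5 seeds of 2000 x 600 three-layer
data sets.

# Known limitations

* k-medoids BUILD + SWAP is a local search. On small instances it
  usually attains the exhaustive-search optimum, but single-swap local
  optima above the global minimum exist (they are observable at
  $n = 6$, $k = 2$); the guarantees tested are local optimality and the
  exhaustive lower bound.
* The delta-area rule inherits the known mechanical growth of consensus
  CDF areas with $k$; see the caveat above.
* GSVA scores depend on the sample composition of the matrix (the
  kernel CDF is cross-sample); scores are comparable within one matrix,
  not across separately scored matrices — which is why cross-cohort
  classification z-scores per cohort.
* The DEP p-value cut and the cell-line gate implement stated but
  ambiguous published rules; both expose the alternatives as parameters
  rather than asserting one reading as ground truth.
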