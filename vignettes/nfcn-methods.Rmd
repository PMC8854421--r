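---
title: "Methods: functionally connected neighbors in single-cell and spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functionally connected neighbors in single-cell and spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In immunologically cold tumors such as glioblastoma, infiltrating T cells
acquire a dysfunctional, exhausted phenotype. A candidate driver is a
cytokine-releasing myeloid subpopulation, but droplet scRNA-seq observes
cells after dissociation: which *pairs* of cells were in functional contact
must be inferred. The inference this package implements rests on a
conjunctive assumption: a ligand-receptor interaction is credible only when
(i) a candidate sender expresses the ligand *and* shows activity of the
upstream program that induces the ligand (so the expression is functional,
not noise), and (ii) a receiver expresses the receptor *and* shows activity
of the downstream program the receptor triggers. Spatial transcriptomics
then supplies an orthogonal check: inferred partners should co-localize in
tissue.

Because the original patient data are not required here, every claim is
validated on synthetic data with planted ground truth: a generator
(`generate_immune_counts()`, `generate_spatial_spots()`, `plant_cnv()`)
produces data with known connected populations, a known spatial niche and
known copy-number lesions, and the pipeline is judged by how well it
recovers them.

# The interaction trajectory and pair selection

For each side of a candidate interaction the model computes two scores per
cell: `A_exp`, the mean scaled expression of the ligand (sender side) or
receptor (receiver side) genes, and `A_eff`, an SVD enrichment of the
induction (sender) or activation (receiver) program — the coefficients of
the first right-singular vector of the member-gene submatrix, sign-oriented
to correlate positively with mean member expression and rescaled to [0, 1].
The singular vector captures the dominant co-expression pattern of the
program and is less sensitive to single noisy genes than a plain mean.

Both scores are outlier-filtered to the central 95% of their empirical
distribution. The filter is two-sided — the upper tail is rejected too —
because the subsequent min–max normalization
`n = (A - min(A)) / (max(A) - min(A))` is meaningless when its range is set
by one aberrant cell. Whether the filter should instead be one-sided is a
genuinely open design point; two-sided is implemented and documented, with
the consequence that a few per cent of the strongest genuine senders and
receivers are deliberately discarded as indistinguishable-from-artifact.
Recovery metrics are therefore computed against planted truth restricted to
the cells that survive this documented QC step — the universe the method
actually ranks.

Cells are placed on an interaction trajectory at
`position = -(n_exp + n_eff)/2` (sender side) and `+(n_exp + n_eff)/2`
(receiver side), then smoothed by kernel-weighted local averaging along the
expression axis using the same kernel as the density model
(`kde_density()`): Gaussian or Cauchy, bandwidth restricted to
(0.3, 0.7) — the range in which a kernel width is meaningful on a min–max
normalized axis; the default 0.5 is the interval midpoint. Connected cells
are those above the 70th percentile on *both* axes of their side; every
eligible sender is paired with every eligible receiver, the pair score is
the product of the four normalized scores (enforcing the conjunction), and
the top 1% of pairs by score form the highly connected subset used for
characterization, e.g. the cluster-level connectivity matrix
(`nfcn_score()`), which averages pair scores per sender-cluster x
receiver-cluster cell and normalizes by the matrix maximum.

Tunable parameters and defaults: confidence percentile `ci = 0.70`,
outlier mass `q = 0.95`, `top_fraction = 0.01`, kernel bandwidth
`h = 0.5`, representative downsampling to 3,000 cells (proportional
stratified), spatial cutoff 150 µm. The percentile reading of the "upper
70% confidence band" is deliberate: no distributional family is assumed,
so the empirical quantile is the testable interpretation.

# Spatial validation

**Signature mapping.** Spot-level signature scores are SVD enrichments of
cluster marker sets on the log-normalized, gene-standardized spot matrix.
A cluster's putative position is the enrichment-weighted centroid of its
top five spots. At a handful of cells per spot a single spot's score is a
very noisy estimate of composition, so scores are first regularized with
the same squared-distance kernel used for surface rendering
(`exp(-d^2/theta)`, `theta = pitch^2` by default; disable with
`smooth_theta = NULL`). Pairs whose sender and receiver positions are more
than 150 µm apart are excluded. On a legacy array with 200 µm pitch this
cutoff equals same-spot colocation and is deliberately stringent: in the
synthetic data most cross-cluster pairs are excluded unless both
signatures peak on the same spot, and the analysis scripts report this
attrition rather than hiding it.

**Connectivity map and Moran statistics.** Connected pairs are projected
onto the array: each non-excluded pair adds its pair score times the
product of its two cluster-signature enrichments at every spot. Spatial
clustering of this density is quantified by Moran's I with
row-standardized rook or queen adjacency (queen by default — on small
grids the denser neighborhood stabilizes the statistic) and a seeded
permutation test (999 permutations). Whether a bivariate spatial statistic
was intended in the source analyses is unclear; univariate I on the
(already bivariate) connectivity product is implemented and documented.

**Distance profiles.** Target-signature rank probabilities are binned
(20 equal-width bins) and the mean distance to the nearest top-decile
reference spot is reported per bin; a decreasing curve means the target
population concentrates near the reference niche.

**State coordinates.** Four program scores per spot are collapsed to two
axes: `A1 = max(GS1, GS2) - max(GS3, GS4)` and, within the winning pair,
`A2 = sign(d) log2(|d| + 1)` with `d` the within-pair difference. The
printed form of the within-pair axis (a log of a difference that is
negative for typical scores in [0, 1]) is undefined almost everywhere; the
signed compressed-difference form used in the established four-state
representation is implemented instead. Continuity across the `A1 = 0`
branch switch is not guaranteed and not asserted.

**Surface matrices.** Per-spot fields are rendered on the full grid extent
with convex `exp(-d^2/theta)` weights (row-normalized), empty positions
zero; the "squared distance divided by a threshold" transform is read as
this Gaussian kernel with `theta` the threshold, defaulting to `pitch^2`.

# Denoising and Bayesian correlation

Spatial correlation between two gene programs is estimated after
background-noise reduction with a dense autoencoder: encoder
input -> 64 (rectified) -> 32 (linear bottleneck), mirrored decoder with a
linear output, trained full-batch with Adam on the squared reconstruction
error, biases initialized at zero so training is deterministic given the
seed. A literal 32-*layer* dense network is untrainable at these problem
sizes and contradicts established denoising-autoencoder practice for
expression data; the 32-unit bottleneck reading is used, with depth
configurable. The correlation itself is estimated with a robust Bayesian
model — bivariate t likelihood via gamma scale mixing, uniform prior on
the correlation, exponential prior on the excess degrees of freedom —
sampled with JAGS (seeded, reproducible). Heavy tails keep single aberrant
spots from dominating.

The denoising experiment plants two smooth spatial fields with an *exact*
sample correlation of 0.6 (the second field is orthogonalized and remixed),
attaches 30 genes to each, and corrupts with negative-binomial noise and
50% dropout. Dropout attenuates the observed program-mean correlation to
roughly 0.2–0.4; the claim tested is that the denoised Bayesian estimate is
closer to 0.6 than the raw sample correlation in the majority of seeds.
The autoencoder can overshoot on individual seeds (reconstruction from a
narrow bottleneck inflates shared structure), which is why the claim is a
majority, not a per-seed guarantee.

# Copy-number inference

Log-normalized expression is centered on a reference of up to 400
predicate-selected non-malignant cells (T cells in the synthetic data),
clamped to [-2.6, 2.6] so single highly expressed genes cannot mimic a
lesion, and smoothed per cell with a centered 100-gene sliding window that
never crosses a chromosome boundary. Windows shrink at chromosome ends
rather than dropping telomeric genes; chromosomes smaller than the window
use all their genes. After smoothing, each cell is re-centered by its
median (exposed as a flag). Whether the moving average should run over
z-scored rather than log-normalized relative values is unspecified in the
tradition this follows; log-normalized relative values are used, consistent
with a clamp bound of 2.6 on a natural-log-like scale.

# The synthetic generator: what it emulates, and what it does not

Counts are negative binomial with multiplicative gene abundance, lognormal
library size (renormalized so the expected post-dropout total per cell is
exactly `library_size_mean`), per-gene batch offsets, and logit-linear
dropout in log mean expression. Six populations are planted: two myeloid
subsets, effector and exhausted T cells, tumor cells, and a rest class,
each with a 30-gene marker signature; `myeloidA` additionally carries the
ligand + induction programs and T cells carry receptor + activation
programs scaled by a per-cell exhaustion grade (uniform 0.7–1 in `Texh`,
0–0.25 in `Teff`), giving the exhaustion gradient the receiver scoring
assumes.

Defaults are desk-scale study conditions: 3,000 cells x 1,500 genes, two
batches (log-offset SD 0.15), 5,000 expected UMIs/cell, NB dispersion 0.5,
program effect 1.25 natural-log units (~3.5-fold, the magnitude of a
strong activation marker), an 18 x 18 spot array at 200 µm pitch with 4–12
cells per spot (uniform, so the median is the midpoint 8), and a
contiguous niche covering 25% of the array. Two prevalence choices are
deliberate consequences of the fixed selection rule rather than free
knobs: with eligibility fixed at the top 30% per axis, planted prevalence
must sit slightly *below* that band so that, after the two-sided outlier
filter removes ~5% of each side (drawn from the top scorers), the whole
planted population fits inside the band on both noisy axes simultaneously.
`myeloidA` is therefore 25% of the non-T compartment and `Texh` 25% of the
T compartment. A planted population exactly filling the band loses ~13%
per side at the band boundary for purely order-statistic reasons,
regardless of effect size.

The spatial niche is graded: sampling weights of tumor, `myeloidA` and
`Texh` cells rise toward the niche core (8x, 12x, 24x at the core,
decaying quadratically to the region edge) and are damped four-fold
outside. A flat in/out enrichment at 8 cells per spot leaves the niche
statistically invisible at spot resolution; the graded design reflects how
mesenchymal-like niches concentrate malignant and myeloid cells, with
exhausted T cells the most tightly niche-restricted, and makes the planted
colocalization recoverable.

Not emulated: ambient RNA, doublets, UMI saturation, cell-cycle structure,
realistic gene-gene correlation beyond the planted programs, and histology.
Passing tests therefore demonstrate that the algorithms recover the
specific structure they assume, under realistic count noise — not that
they are robust to every artifact of real tissue data.

# Numerical and implementation notes

* `lognormalize()` conserves `sum(expm1(column)) = 10,000` exactly for
  non-empty cells; all-zero cells are zeroed with a warning.
* Variable genes are ranked by observed variance over a loess-fitted
  mean–variance trend; ties break by gene id so the ranking is total.
* `nontrivial_components()` uses Horn-style parallel analysis: 20 per-gene
  permutations, 95th percentile, counting the leading run of observed
  eigenvalues above threshold.
* `snn_cluster()` builds exact k-nearest neighbors (Euclidean), Jaccard
  SNN weights pruned below 1/15, Louvain modularity at the given
  resolution, all under a fixed seed.
* Eligibility uses strict `>` against the empirical percentile, so raising
  `ci` or lowering `top_fraction` yields exact subsets (ties in pair
  scores break deterministically by cell id).
* Degenerate inputs fail loudly: constant vectors for min–max and Moran's
  I, bandwidths outside (0.3, 0.7), constant genes in scaling are zeroed
  rather than NaN.
* Problem sizes in the test-suite and acceptance runs (3,000-cell
  datasets, 10 replicate seeds, 18 x 18 arrays, 999 permutations, 1,500–
  4,000 posterior draws) are the package's chosen desk scale: large enough
  that every planted effect is comfortably detectable, small enough that
  the full validation runs in minutes.

# Known limitations

* The pair score is a heuristic conjunction; no generative model of
  ligand-receptor signaling is fitted, and scores are comparable only
  within one run.
* Cluster-level putative positions give every cell of a cluster the same
  coordinates; at 200 µm pitch the 150 µm cutoff is effectively same-spot
  colocation, and signature peak localization at ~8 cells/spot carries
  about one spot of noise, so the spatial filter is stringent by
  construction.
* The two-sided outlier filter discards the extreme top tail of genuine
  senders/receivers by design.
* Parallel analysis assumes exchangeable cells within a gene; strong
  batch structure should be regressed out first.
* The autoencoder is a plain dense network without count-aware loss; it is
  a denoiser, not an imputation model.
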