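# nfcn

Nearest functionally connected neighbor analysis for single-cell and
spatial transcriptomics.

## The problem

Tumor-infiltrating T cells in immunologically cold tumors such as
glioblastoma drift into an exhausted, dysfunctional state, and a
cytokine-releasing myeloid subpopulation is a prime suspect for driving
that transition. Dissociative scRNA-seq destroys the spatial and physical
context, so *which sender cells are functionally connected to which
receivers* must be inferred. This package implements that inference — the
nearest functionally connected neighbor (NFCN) algorithm — together with
the preprocessing it needs, the spatially resolved validation that checks
inferred partners for tissue colocalization, and expression-based
copy-number estimation for separating malignant from immune cells. A
synthetic-data module generates datasets with planted ground truth
(connected populations, a spatial niche, chromosomal lesions) so every
stage of the pipeline can be validated end to end.

## The model

A cell–cell connection is accepted only on conjunctive evidence. For a
candidate sender, the ligand must be expressed (score
`A_exp` = mean scaled expression of the ligand genes) *and* the upstream
program that induces the ligand must be active (`A_eff` = SVD gene-set
enrichment: the first right-singular vector of the member-gene submatrix,
oriented to rise with mean member expression). Receivers are scored
likewise on receptor expression and downstream activation. After rejecting
cells outside the central 95% of either score, scores are min–max
normalized,

    n_i = (A_i - min A) / (max A - min A),

and cells are placed on an interaction trajectory at
`-(n_exp + n_eff)/2` (senders) and `+(n_exp + n_eff)/2` (receivers),
smoothed with a kernel density model

    f_h(x) = (1/n) sum_i K_h(x - x_i),   K in {Gaussian, Cauchy},  0.3 < h < 0.7.

Connected cells lie above the 70th percentile on *both* axes of their
side; all sender × receiver combinations of connected cells form the
connected pairs, scored by the product of the four normalized scores, with
the top 1% flagged as the highly connected subset. Pairs whose putative
positions on a spot array (enrichment-weighted centroid of the top five
spots for each cluster signature) are more than 150 µm apart are excluded.
Cluster-level connectivity is the mean pair score per sender-cluster ×
receiver-cluster cell, normalized to [0, 1].

Spatial validation uses Moran's I with row-standardized grid adjacency and
permutation p-values, distance profiles from signature-rank probability to
the nearest top-decile reference spot, surface matrices with
`exp(-d²/θ)` smoothing, a four-program two-dimensional state
representation, and a denoising autoencoder (32-unit bottleneck) followed
by a robust Bayesian correlation (bivariate t likelihood, uniform prior on
ρ, sampled with JAGS). Copy-number profiles are 100-gene moving averages
of reference-centered, ±2.6-clamped log expression along each chromosome.

## Worked example

The `analysis/` scripts run the full workflow on the synthetic study
dataset (3,000 cells × 1,500 genes, 18 × 18 spot array at 200 µm pitch,
planted `myeloidA → Texh` interaction, MES-like niche, chr7 gain / chr10
loss):

```sh
Rscript analysis/01_simulate.R     # writes results/data (MTX, TSV, GMT, BED, JSON)
Rscript analysis/02_preprocess.R
Rscript analysis/03_nfcn.R
Rscript analysis/04_spatial.R
Rscript analysis/05_cnv.R
```

Output from a complete run (seed 1):

```
simulated 3000 cells x 1500 genes in 2 batches
cell types: myeloidA=525, myeloidB=675, other=300, Teff=675, Texh=225, tumor=600
spot array: 324 spots (81 in the MES-like niche), median 8 cells/spot
nontrivial components: 6
SNN clusters: 6; adjusted Rand index vs planted types: 1
connected pairs (upper 70% CI on both axes, both sides): 78411; highly connected (top 1%): 785
strongest cluster-level connection: myeloidA -> Texh
recovery vs planted truth: precision 0.883, recall 0.871
spatial filter at 150 um (same-spot colocation at 200 um pitch): 0 retained, 78411 excluded;
  putative myeloidA-Texh distance 495 um
connectivity map Moran's I = 0.375 (permutation p = 0.001)
Texh -> MES distance profile Spearman rho = -0.526
denoised correlation closer to the planted 0.6 in 4/5 replicates (raw attenuated to ~0.3)
chr7 (planted gain): tumor-vs-rest t = 48
chr10 (planted loss): tumor-vs-rest t = -48.9
```

Reading the numbers: the pipeline recovers the planted sender/receiver
populations (precision/recall ≈ 0.88/0.87 against the planted cross,
restricted to outlier-filter survivors), names the planted cluster pair as
the strongest connection, finds the connectivity map significantly
clustered in space, and sees exhausted T cells sit closer to the
mesenchymal-like niche the higher their signature probability. The 150 µm
distance filter at a 200 µm array pitch demands same-spot colocation;
signature peaks localize with about one spot of noise at eight cells per
spot, so in most runs it excludes all cross-cluster pairs — reported here
rather than hidden, and discussed in the methods vignette
(`vignettes/nfcn-methods.Rmd`).

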