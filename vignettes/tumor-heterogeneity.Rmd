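---
title: "Dissecting mammary tumor heterogeneity with tumorhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting mammary tumor heterogeneity with tumorhet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorhet)
```

## What the package does

`tumorhet` implements a droplet single-cell RNA-seq heterogeneity
analysis for mouse mammary tumors, from gene-tagged reads to annotated
cell populations, together with a gene-alteration co-occurrence
analysis for tumor cohorts. The stages are:

1. **UMI quantification** — demultiplex reads by *exact* barcode match
   (no error correction), then count transcripts per (barcode, gene) as
   connected components of the distinct-UMI graph with edges at Hamming
   distance ≤ 1, using sense-orientation reads only.
2. **Cell calling** — retain barcodes whose total transcript count
   strictly exceeds 0.1 × the total of the barcode at descending rank
   30 (the 99th-percentile anchor for a 3000-cell run).
3. **Normalization** — divide each cell by its scale factor
   (cell total / median total across retained cells) and transform with
   log2(x + 1).
4. **Embedding** — the 1000 most variable genes (variance of normalized
   log expression), then PCA keeping the top 20 components.
5. **Clustering** — Gaussian mixtures with constrained covariance
   structures (EII, VII, EEE, VEV, VVV), fitted by EM for k = 1..20 and
   selected by minimal BIC = −2·logL + p·ln(n).
6. **Annotation** — one-vs-rest Wilcoxon rank-sum marker tests per
   cluster; clusters are merged into lineage superclusters (epithelial,
   stromal, T, myeloid) by marker-panel AUC scores, with clusters that
   exceed the threshold for two panels flagged as multiplets and
   excluded downstream.
7. **Signatures** — per-cell EMT positivity (detection of any of Snai1,
   Twist1, Zeb1, Zeb2 in raw UMIs) and S100a4 positivity, reported as
   per-tumor percentages over non-multiplet cells.
8. **Co-occurrence** — marginal, joint and conditional alteration
   frequencies for gene pairs in a samples × genes boolean table, plus
   the sample odds ratio and Fisher's exact test.

Every stage is driven in tests by a synthetic-data generator with known
ground truth, so recovery can be measured exactly.

## The mixture model

Cells in PCA space are modeled as a k-component multivariate Gaussian
mixture. The covariance of component j is constrained by a named
parameterization of the spectral decomposition
Σ_j = λ_j D_j A_j D_jᵀ (volume λ, shape A with det(A) = 1, orientation
D):

| model | volume | shape | orientation | covariance parameters |
|-------|--------|-------|-------------|----------------------|
| EII | equal | spherical | — | 1 |
| VII | variable | spherical | — | k |
| EEE | equal | equal | equal | d(d+1)/2 |
| VEV | variable | equal | variable | k + (d−1) + k·d(d−1)/2 |
| VVV | variable | variable | variable | k·d(d+1)/2 |

Fitting is by EM. The E-step computes responsibilities from the current
parameters; the M-step updates weights, means and the constrained
covariances — for VEV, component scatter matrices are eigendecomposed
and a flip-flop iteration alternates between the component volumes
λ_j and the shared shape A (at most 50 inner iterations, tolerance
1e-8). Initialization is k-means++ with 5 restarts; each restart runs a
short EM burn-in (15 iterations) and the best log-likelihood is
continued to convergence (gain < 1e-6, at most 500 iterations). The
log-likelihood is asserted to be non-decreasing at every iteration.
Covariance eigenvalues are floored at 1e-8 of the total data variance;
a component whose responsibility mass drops below 2 cells triggers a
re-initialization (up to 3), then a failure that model selection skips
with a warning. Model and k are chosen by *minimal*
BIC = −2·logL + p·ln(n) (some software maximizes the negated quantity;
the convention here is fixed and tested against the parameter-count
formulas above), with ties broken toward smaller k and then fewer
parameters.

The EM core exists twice: a compiled RcppArmadillo engine (default) and
a plain-R reference implementation of the identical algorithm
(`engine = "R"`), which the test suite cross-checks against each other
and against an independent mixture-modeling package on shared fixtures.

## Tunable parameters

| parameter | default | units | rationale |
|-----------|---------|-------|-----------|
| `rank_anchor`, `factor` | 30, 0.1 | barcodes, fraction | cutoff = 0.1 × total of the rank-30 barcode; an adaptive anchor max(30, ⌈0.01·expected cells⌉) is available behind a flag |
| `n_hvg` | 1000 | genes | variance ranking on normalized log values (a flag for raw-count variance is deliberately absent: normalized-log is the scale the rest of the pipeline uses) |
| `n_pcs` | 20 | components | top principal components carried into clustering |
| `k_max`, `models` | 20, all five | — | BIC scanned over every (model, k) pair |
| `auc_threshold` | 0.7 | AUC | minimum mean panel AUC for a supercluster assignment; two panels above it flag a multiplet |
| `min_umi` | 1 | UMIs | detection threshold for EMT/S100a4 positivity |

Positivity calling on raw UMI detection (≥ 1) is the only
parameter-free reading of a binary "positive cells" report; a
continuous EMT score (sum of normalized expression over the four
genes) is also emitted for inspection but does not drive the calls.

## The synthetic-data generator

`simulate_tumor_counts()` emulates one tumor's droplet data:

* **Lineages** — four expression programs (epithelial, stromal, T,
  myeloid), each with exclusive marker genes (led by Epcam/Krt18/Krt5,
  Col3a1/Vim/Bgn, Cd3e/Cd3d, Itgam/Mrc1/Lyz2) over a shared
  housekeeping background. Default lineage proportions are
  2313/369/638/1423 over 4743 singlets — the pooled supercluster
  composition these tumors show — and the default cell number is
  4743. Lineage labels are drawn multinomially.
* **Counts** — negative binomial per gene
  (variance = μ + `nb_dispersion`·μ², Poisson at 0), scaled by a
  log-normal per-cell library factor with sd
  `library_size_dispersion` (default 0.35). The NB is the accepted
  count model for droplet data; the generative model never states a
  distribution choice downstream, so dispersion 0.05 was fixed once as
  a typical UMI-level value.
* **Empty droplets** — ambient-only counts drawn Poisson from the
  library-size-weighted mixture of the lineage programs (including the
  planted programs' expected contribution), rescaled to
  `ambient_total_mean` (default 40 UMIs, roughly 1/25 of a cell).
* **Doublets** — cross-lineage pairs (probability ∝ p_i·p_j, i ≠ j),
  each the sum of two independently drawn cells; the default doublet
  share of non-empty droplets is 252/4995, matching the multiplet
  fraction of the pooled composition above. Same-lineage doublets are not simulated.
* **Planted programs** — an EMT program adds `emt_program_rate`
  (default 2.5) mean UMIs to each of Snai1/Twist1/Zeb1/Zeb2 in an
  *exact* fraction of epithelial+stromal singlets
  (round(fraction × n eligible) cells, sampled without replacement);
  S100a4 is expressed at rate 8 in exact per-lineage fractions.
  Deterministic planting makes a planted fraction a sharp ground truth
  instead of a binomial draw; both program rates give per-cell
  detection probability above 0.99, which the recovery analyses
  presuppose. `tumor_presets()` encodes the two-sample contrast used
  throughout: a malignant-like tumor (EMT 0.37, S100a4 0.51) versus a
  fibroadenoma-like tumor (0.11 and 0.26).
* **Reads** — `simulate_tagged_reads()` expands molecules into
  gene-tagged reads with distinct UMIs per (barcode, gene) molecule;
  duplicate reads optionally carry a distance-1 UMI error. There is no
  FASTQ emission, no cDNA sequencing error and no positional
  alignment: gene tags are taken as given, which is exactly the
  contract of the quantification stage.

`simulate_alteration_table()` builds sample × gene boolean tables with
deterministic counts (round(n·joint) double-positives and so on), so
printed cohort contingencies can be reproduced exactly.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: ambient RNA *inside* cell-containing
droplets, batch effects between tumors, continuous differentiation
gradients within lineages, barcode sequencing errors (the
demultiplexer is exact-match by design), saturation of the UMI space,
and gene–gene correlation beyond the lineage programs. Recovery rates
measured on this generator are upper bounds for real tissue.

## Numerical choices and edge cases

* "Exceed the cutoff" is read strictly: a barcode exactly at the
  cutoff is removed. Rank 30 is 1-based on descending totals; ties are
  resolved by a stable sort on barcode name (the anchor value is
  unaffected).
* The median total is computed over retained cells (normalization
  happens after filtering), with the usual mean-of-middle-two median
  for even n. A retained cell with zero total is an error, not a
  silent NaN.
* UMI collapsing is transitive: a chain A–B–C of single-base steps
  counts one molecule. The alternative count-weighted directional
  merge is out of scope. Collapsing is per (barcode, gene) — pooling
  across genes within a cell is never done, which is universal
  practice although the rule's one-sentence description is silent on
  it.
* Wilcoxon tests use midranks; the exact null is used for comparisons
  with n₁+n₂ ≤ 12 and no ties, otherwise the normal approximation with
  tie correction and continuity correction. The two-sided exact p is
  the doubled smaller tail, capped at 1. BH adjustment is applied
  within each cluster's gene list (the adjustment is this package's
  addition — a correction is standard practice for per-gene scans even
  where a report omits naming one).
* PCA signs are fixed by forcing each component's largest-magnitude
  loading positive, so results are bit-reproducible.
* Fisher's exact p comes from the standard two-sided hypergeometric
  rule (sum of tables no more probable than observed); the odds ratio
  is the sample ad/bc with the Haldane 0.5 correction when a cell is
  zero. Printed percentages round half away from zero to integers
  (61.6 → 62, 48.8 → 49).
* All randomness flows from one run seed through per-stage substreams
  derived by hashing the stage name, so stages are individually
  reproducible and reordering stages cannot silently couple them.

## Design choices where the design was open

* **Supercluster merging** formalizes what is in practice a manual
  inspection of enriched genes: a cluster joins the lineage whose
  marker-panel mean AUC exceeds 0.7, is a multiplet when two panels
  exceed it, and is unassigned otherwise. Panels and threshold are
  configurable; the defaults use canonical markers for the four
  lineages.
* **Per-tumor cell numbers** are uniform across simulated samples; the
  pooled composition is specified but per-sample depths are not, so
  equal sizes are the neutral choice.
* **HVG variance scale** is normalized-log expression; computing
  variance on raw counts would rank by mean instead of by
  heterogeneity.
* **The rank-30 anchor** is computed over whitelist-matched barcodes —
  the only barcodes that exist after demultiplexing.

## Known limitations

* On realistic (negative binomial) synthetic data the BIC-selected k
  exceeds the number of lineages — residual non-Gaussian structure
  within lineages is soaked up by extra components. This mirrors the
  behavior of model-based clustering on real droplet data, where many
  mixture components per biological lineage are expected and are
  merged afterwards by marker inspection; it is why the supercluster
  stage exists. Exact k recovery holds on well-separated Gaussian
  clusters (the test suite uses 8σ separation), not on the full
  scRNA-seq path.
* Cluster-level multiplet flagging cannot detect doublet clusters that
  involve the dominant lineage at the default threshold: scale-factor
  normalization halves a doublet's marker levels relative to its
  parent singlets, capping the dominant panel's one-vs-rest AUC near
  1 − p(dominant) ≈ 0.5 here. Minority-lineage pairs (e.g.
  stromal + T) are flagged correctly. Per-cell doublet scoring is a
  non-goal.
* The EM can only find local optima; the k-means++ restarts make the
  selection reproducible, not provably global.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the generator at 220–800
cells for pipeline-level checks, the full default 4743 cells for
cell-calling accuracy, 1500 cells per sample for signature recovery,
n = 2000 in 20 dimensions (and n = 3000 in 5) for mixture-model
selection over all five models and k ≤ 20, 10,000 (2,000 in the
script) random instances for the UMI-collapsing oracle, and every rank
configuration with n₁+n₂ ≤ 10 for the exact Wilcoxon check.
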