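---
title: "Methods: ECM-immune integration, signature discovery and recovery testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECM-immune integration, signature discovery and recovery testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmimmune)
```

`ecmimmune` links the composition of the tumor extracellular matrix
(matrisome transcripts and proteins) to the immune compartment of
metastatic high-grade serous ovarian cancer, and stratifies samples on the
resulting molecular signatures. This vignette explains the models behind
each stage, the tunable parameters, the synthetic-data generator that the
test suite validates against, and the design decisions that were genuinely
open.

## Immune deconvolution

Two backends estimate immune cell-type abundances from bulk expression,
deliberately different in kind so their agreement is informative:

**Fractions (NNLS).** For each sample `b` (linear-scale TPM) and signature
matrix `S` (signature genes × cell types), `fit_fractions()` solves
`min ||S f − b||²` subject to `f ≥ 0` over the genes shared between `b` and
`S`, then normalizes `f` to sum to one. Non-negative least squares is
deterministic, exact on noiseless mixtures of signature columns (a
machine-precision test in the suite), and scale-invariant per sample. A
support-vector regression core would mimic the popular fractions tool more
closely, but its hyperparameters make the estimator harder to verify; NNLS
is the default because the artifact must be auditable against ground
truth. Inputs whose maximum is ≤ 50 are rejected as likely
log-transformed; at least half of the signature genes must be present.

**Enrichment (rank-based).** `enrichment_scores()` computes an
ssGSEA-style statistic per sample and marker set: genes are ordered by
decreasing expression (ties broken lexicographically by gene id, so the
score is fully deterministic), in-set positions advance a running sum by
`((G − i + 1)/G)^τ` (normalized rank to the power `τ = 0.25`), out-of-set
positions advance a uniform penalty, and the score is the integrated
difference of the two running distributions, finally normalized by the
(max − min) over the cohort. Because only within-sample ranks enter, the
score is invariant to any strictly monotone per-sample transform — an
invariance the suite asserts directly. Spillover compensation and
platform-specific set triplets of the enrichment tool this mirrors are
deliberately out of scope; one marker set per cell type.

## Correlation and the consensus signature

`correlate_layer()` computes Spearman's rank correlation with a two-sided
p-value for every (matrisome molecule, cell type) pair, in each molecular
layer (transcript, protein) and for each deconvolution method. For n ≤ 9
untied observations the p-value is exact — equal to the exhaustive
permutation tail, which the test suite re-derives by enumerating all 8!
permutations — and the t-approximation
`t = ρ √((n−2)/(1−ρ²))` is used otherwise. Ties take average ranks;
protein missingness is handled pairwise-complete; molecules with fewer
than 4 complete pairs or zero variance are skipped with a warning.

`consensus_signature()` applies the consistency rule: a molecule belongs to
the consensus for a target cell type when it is *positively* correlated
(`ρ > 0`) at `p < α` (default `α = 0.05`, uncorrected) in **all four**
(method × layer) cells. No multiple-testing correction is applied by
default — this mirrors the analysis the package reimplements and is
documented as a fidelity-versus-rigor tradeoff; `adjust = "BH"` enables
per-cell Benjamini–Hochberg correction for users who prefer control of the
FDR. The four-cell conjunction is itself a stringent filter: the suite
shows empirically that single-layer filtering admits strictly more false
positives than the cross-layer intersection, which is the methodological
point of the design. A broader "both-layers" set (any cell type passing
everywhere) is returned alongside, since requiring a specific cell type is
the stricter of the two readings of "consistently associated"; both views
are emitted rather than guessing which the source analysis intended.

## Signature scoring, stratification and survival

`score_samples()` averages per-molecule z-scores (centering each molecule
across samples), so the cohort mean score is zero by construction;
zero-variance molecules are excluded with a warning. `stratify_median()`
assigns samples above the cohort median to `high` and below to `low`;
samples tied exactly at the median are allocated lexicographically, low
first, to keep the groups as balanced as possible. With an even number of
all-distinct scores the split is exactly equal — 16/16 for a 32-sample
cohort. The median rule is inferred from that equal split; mean-based
scoring of the signature is an assumption, flagged rather than asserted.

Immunity-cycle scoring assigns each of the seven step-wise events of
anti-tumor immunity a per-sample activity score: the mean z-score of the
step's signature genes, with optional negative-direction members
subtracted. The published step-scoring tool's internal weighting is not
reproduced — its exact normalization is not public — so sets are
user-supplied and the scorer is a documented simplification. Group
comparisons use a group × step two-way ANOVA plus per-step Welch
contrasts.

`survival_analysis()` is a local replacement for web-based KM analysis:
Kaplan–Meier medians per group, the unweighted (Mantel–Haenszel) log-rank
test, and a Cox proportional-hazards model (high vs low, Efron tie
handling) with a 95% Wald interval. Consistency is tested on generator
output at n ∈ {100, 1000}: bias of the hazard-ratio estimate shrinks with
n, and planted ratios in {1.2, 1.5, 2.0} are recovered within 10% at
n = 1000.

## ECM composition groups and category composition

`normalize_proteomics()` imputes missing protein intensities as zero
abundance (the label-free convention; every imputation is logged), scales
each sample to a fixed total of 10^4 — making the result invariant to
per-sample scale, which the suite asserts — and log2-transforms. The row
z-score variant feeds `cluster_ecgs()`: Ward clustering (`ward.D2`,
squared-Euclidean updates) of samples on Euclidean distance over z-scored
proteins detected in at least 25% of samples (the prevalence filter is a
choice, surfaced as a parameter, since the source analysis does not state
one). `k` defaults to 5 ECM composition groups; a mean-silhouette profile
over k = 2..8 is reported so users can justify other choices. Group labels
are ordered by increasing group-mean disease score where metadata is
available, so low-disease groups receive small indices; otherwise by
decreasing size with a lexicographic tie-break, keeping the assignment
deterministic and order-invariant.

`category_composition()` reports the share of summed linear abundance in
each of the six matrisome categories, per sample and cohort-wide; shares
sum to one and unannotated proteins are excluded from the denominator with
a warning. Differential proteins per ECG use one-vs-rest Welch t-tests on
log abundances with BH adjustment (the underlying analysis names no test;
Welch is the robust default for unequal group variances).

## Histology metrics

The staining score is the closed form
`100·(S_low·1 + S_med·2 + S_high·3)/A_tissue` on intensity-binned stained
areas (µm²); it lives in [0, 300] and is invariant to joint rescaling of
all areas. The suite checks it against an independently coded oracle on
1000 randomized tables to 1e-12.

The fiber alignment index treats orientations as axial data (period π):
with doubled angles `φ_j = 2θ_j`, the mean orientation is half the argument
of the mean unit vector, and `AI = (1/N) Σ cos(2(θ_j − θ_avg))` — the mean
resultant length of the doubled angles. The defining description names
`N`, `θ` and `θ_avg` and fixes both endpoints (identical angles → AI = 1;
random orientations → AI → 0) but omits the formula body; the mean
resultant length is adopted because it is the standard circular-statistics
order parameter using exactly those symbols and satisfying both endpoints,
and this reconstruction is called out here deliberately. AI is invariant
to global rotation, to adding π to any subset of fibers, and to
permutation; under uniform orientations its expectation decays like
`√π/(2√N)`. `fiber_summary()` flags fields with fewer than 30 fibers
(flagged, not silently dropped) and aggregates tissues by the median over
QC-passing fields; θ_avg is computed per field, matching the per-field
symbols.

## MAM profiling

Differential expression between macrophages educated on high-disease (HD)
versus low-disease (LD) ECM uses per-gene Welch t-tests on log2
expression, BH adjustment, and the three-part significance filter
`adj p < 0.05 AND |log2FC| > 1 AND protein-coding`. The source analysis
does not name its DE engine; a count-model backend would need raw counts,
which this stage does not consume, so the deterministic t-test is the
default and donor-mean centering (4 blood donors) is available in both the
DE and the module stage. Without a biotype table the coding filter is
skipped with a loud warning rather than silently passed.

`detect_modules()` is a compact WGCNA-style detector: unsigned adjacency
`|cor|^β` with β chosen as the smallest power in 1..12 reaching scale-free
fit R² ≥ 0.8 (falling back to the conventional unsigned default of 6),
topological-overlap dissimilarity, average-linkage clustering, a fixed cut
at 0.9 of the maximum merge height, dissolution of clusters below the
minimum size (default 30) into module 0, and a merge step that fuses
modules whose eigengenes correlate above 0.75 — the standard eigengene
merging heuristic. The cut height was originally conceived as 0.25 of the
maximum, but topological-overlap dissimilarities concentrate near 1 for
unrelated genes, so intra-module merges sit well above a quarter of the
dendrogram: a 0.25 cut lies below the first merge and yields no modules at
all. The 0.9 default places the cut between the intra-module merge range
and the background plateau. Eigengenes are unit-norm first principal
components of the z-scored member profiles, oriented to correlate
positively with the mean member profile. Dynamic tree cutting would adapt
better to nested structure; the fixed cut is chosen for implementability
and is exposed as `cut_frac`.

Module–trait association uses Pearson correlation with two-sided p, with
entries masked at p ≥ 0.05 in the display matrix. Enrichment of DE genes in
externally published macrophage stimulation modules (supplied as GMT) uses
the hypergeometric upper tail with BH adjustment across modules; the suite
verifies it against exhaustive tail sums on a 100-gene universe.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates the full multi-modal cohort with planted
ground truth; its defaults are the study conditions the pipeline is
validated under, chosen once:

- **Cohort**: 32 samples, 8 immune cell types, Dirichlet(2) fractions.
  Bulk transcript expression is `S · fᵀ` with multiplicative log-normal
  noise (σ = 0.1); each cell type has 10 marker genes at 300–700 TPM
  against a 1–10 TPM background.
- **Planted signature**: 5 matrisome molecules (named FN1, VCAN, MXRA5,
  COL11A1, SFRP2 after the canonical desmoplastic markers) coupled to the
  target cell type's fraction at Spearman ρ ≈ 0.7 at *both* layers. The
  coupling is a Gaussian copula: on the latent-normal scale,
  `z = ρ_lat·z_fraction + √(1−ρ_lat²)·ε` with `ρ_lat = 2 sin(π ρ_s/6)`, so
  the *Spearman* correlation targets ρ_s directly (rank-based analysis
  calls for rank-scale control); ρ_s = 1 reproduces ranks exactly. The
  chosen ρ = 0.7 is a strong but realistic bulk-tissue association —
  the source analysis reports significance, not effect sizes, so this is a
  generator choice, not a reported value.
- **Protein layer**: log-normal with σ = 0.5 (cohort CV ≈ 50%, typical of
  label-free quantification across tissues); per-molecule abundance scales
  planted so the cohort-wide category composition is collagens 35%,
  glycoproteins 25%, proteoglycans 25%, regulators 8%, affiliated 5%,
  secreted factors 1%. Five ECM composition groups are planted as 10
  marker proteins per group shifted by 3 protein-SDs, drawn proportionally
  from every category so the shifts leave the composition unchanged.
- **Couplings**: IHC counts are Poisson with mean 500 × fraction; the
  disease score is rank-coupled to the target fraction at ρ = 0.6; survival
  is exponential with a 45.63-month baseline median, hazard multiplied by
  1.56 for samples above the median planted-signature score, and uniform
  censoring on [0, 1.5 × median].
- **MAM experiment** (`simulate_mam_experiment()`): 16 HD / 15 LD profiles
  over 4 donors with additive donor offsets (σ = 0.3), 50 DE genes at
  |log2FC| = 2 (alternating directions) over σ = 0.2 noise, and 5 planted
  co-expression modules of 40 genes at intra-module correlation 0.8 via a
  latent-factor model.
- **Fiber fields** (`simulate_fiber_fields()`): axial von Mises
  orientations via the Best–Fisher sampler on doubled angles; κ = 0 is the
  circular uniform.

What the generator does **not** emulate: the real cohort's full covariance
structure (immune types co-vary in tissue; here fractions are Dirichlet),
intensity-dependent proteomics missingness (missing values appear only if
the user introduces them), isoform- or symbol-mapping ambiguity between
layers (identifiers match exactly), and technical batch structure beyond
the MAM donor offsets. Passing recovery tests therefore demonstrates that
the estimators are correct and well-calibrated under clean planted
structure — not that the pipeline is robust to every pathology of real
tissue data.

Problem sizes in the test suite and acceptance script (20–32 samples, 400
transcript features, 80 matrisome molecules, 1000 MAM genes, 20 seeds per
recovery check, n = 1000 for survival consistency) are the package's
chosen validation scale: large enough for stable rank statistics and Cox
estimation, small enough that the full suite runs in minutes on a laptop.

## Numerical choices and degenerate inputs

- Spearman: exact p only for untied n ≤ 9; average ranks for ties;
  |ρ| = 1 reports p = 0.
- Constant vectors (molecules, markers, eigengenes) are skipped or
  reported as NA rather than producing noise-driven p-values — an exactly
  constant ANOVA response, for instance, yields a floating-point F-ratio
  that is numerically meaningless.
- Median ties in stratification are broken lexicographically by sample id
  (deterministic, order-invariant).
- NNLS coefficients are renormalized to the simplex; an all-zero sample is
  an error, not a silent zero row.
- All generators are pure functions of `(config, seed)`: the RNG state is
  saved and restored around every simulation.

## Known limitations

- The enrichment backend omits spillover compensation, so closely related
  cell types (e.g. macrophage subtypes) have correlated scores.
- The consensus rule inherits the uncorrected α = 0.05 of the analysis it
  mirrors; with many cell types the per-layer record table contains the
  expected share of nominal false positives (the cross-layer intersection,
  not the per-test threshold, provides the control).
- Ward clustering on z-scored proteins assumes roughly elliptical groups;
  strongly nested or non-convex composition structure would favor other
  linkages, which `stats::hclust` provides if needed.
- The module detector's fixed-height cut cannot resolve nested modules;
  `cut_frac` and `beta` are exposed for tuning, and eigengene merging
  mitigates over-splitting only.
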