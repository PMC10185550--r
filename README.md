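# ecmimmune

Integration of tumor extracellular-matrix (ECM) composition with
immune-cell phenotype in metastatic high-grade serous ovarian cancer
(HGSOC), packaged as a tested, reusable R pipeline.

Solid tumors remodel their ECM, and the remodeled matrix in turn shapes the
infiltrating immune compartment — most prominently tumor-associated
macrophages in the omental metastatic niche. `ecmimmune` is aimed at
computational biologists who work with matched bulk RNA-seq, matrisome
proteomics, immunohistochemistry (IHC) and survival data from such cohorts
and want to ask: *which matrisome molecules are robustly associated with
which immune cell populations, and does that association stratify
outcome?*

## What the package does

- **Immune deconvolution** of bulk expression by two complementary
  backends: non-negative least squares against a signature matrix
  (fractions: per sample, solve `min ||S f - b||², f ≥ 0` over shared
  signature genes and normalize `f` to sum to 1), and rank-based
  single-sample enrichment of per-cell-type marker sets (an ssGSEA-style
  running sum with weight exponent 0.25 on normalized ranks). Estimates can
  be validated against IHC counts per mm².
- **ECM–immune integration**: Spearman correlation (two-sided; exact null
  for n ≤ 9, t-approximation otherwise) of every matrisome molecule with
  every immune abundance, at the transcript and the protein layer, under
  both deconvolution methods; a **consensus signature** is the set of
  molecules significantly *positively* associated with the target cell type
  in *all four* (method × layer) cells — intersecting two methods and two
  independent molecular layers is what controls false positives.
- **Signature analysis**: mean z-score sample scoring, median high/low
  stratification (an even cohort of distinct scores splits exactly in
  half, e.g. 16/16 of 32), seven-step cancer-immunity-cycle scoring with
  group × step ANOVA, and Kaplan–Meier / log-rank / Cox proportional-hazards
  survival stratification (Efron ties).
- **Matrisome proteomics**: total-abundance normalization, Ward (`ward.D2`)
  clustering of samples into ECM composition groups (ECGs), matrisome
  category composition (collagens, ECM glycoproteins, proteoglycans, ECM
  regulators, ECM-affiliated proteins, secreted factors), per-group
  differential proteins (one-vs-rest Welch t + BH), and ECG–immune/disease
  associations.
- **Histology metrics**: the IHC staining score
  `100·(S_low + 2·S_med + 3·S_high)/A_tissue`, the fiber **alignment index**
  `AI = (1/N) Σ cos(2(θ_j − θ_avg))` (mean resultant length of doubled
  angles: 1 for perfectly aligned fibers, → 0 for random orientations), and
  the disease score (tumor% + stroma%).
- **Matrix-educated macrophage (MAM) profiling**: HD-vs-LD differential
  expression with the `adj p < 0.05, |log2FC| > 1, protein-coding` filter,
  M0/M1/M2 subtype scoring, WGCNA-style co-expression modules (soft-power
  adjacency, topological overlap, eigengenes), GSVA-style gene-list scores,
  and hypergeometric enrichment against published macrophage stimulation
  modules.
- A **synthetic-cohort generator** that plants all of the above structure
  (known fractions, a 5-molecule cross-layer signature, ECGs, hazard
  ratios, DE genes, co-expression modules, von Mises fiber fields) so every
  stage has a ground-truth recovery test without any external download.

## Worked example

```r
library(ecmimmune)

coh <- simulate_cohort(generator_config(seed = 1))

# immune abundances by both backends
fr <- fit_fractions(coh$transcript, coh$reference)
es <- enrichment_scores(coh$transcript, coh$reference$sets)

# correlate matrisome molecules with abundances at both layers
mats <- merge_layers(coh$transcript, coh$protein)
recs <- rbind(correlate_layer(fr, mats$transcript, coh$annotation),
              correlate_layer(es, mats$transcript, coh$annotation),
              correlate_layer(fr, mats$protein,    coh$annotation),
              correlate_layer(es, mats$protein,    coh$annotation))
consensus_signature(recs, target_cell_type = "Macrophage.M0")
#> <signature_set> target: Macrophage.M0 | 5 consensus molecules across 4 cells
#>    COL11A1, FN1, MXRA5, SFRP2, VCAN
#>   both-layers (any cell type): 5 molecules

# stratify on the signature and test survival
sc <- score_samples(c("COL11A1", "FN1", "MXRA5", "SFRP2", "VCAN"), coh$protein)
table(stratify_median(sc)$group)
#>  low high
#>   16   16
survival_analysis(simulate_cohort(
  generator_config(seed = 1, n_samples = 1000L))$survival)[c("hr", "logrank_p")]
#> $hr
#> [1] 1.494993
#> $logrank_p
#> [1] 5.455647e-05
```

The consensus set is exactly the five planted molecules; the 32-sample
cohort splits 16/16 at the median score; and on a 1000-sample cohort the
Cox model recovers a hazard ratio near the planted 1.56 (single-seed
estimates fluctuate; the average over 20 seeds lands within a few percent).

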