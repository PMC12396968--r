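# immunatlas

Tested, reusable building blocks for analyzing multi-donor, multi-tissue
CITE-seq immune-cell atlases — the kind of study that profiles 20–30
organ donors across blood, bone marrow, spleen, lymph nodes, lung and
gut, asks which immune phenotypes are tissue-intrinsic versus
compositional, and how they shift with donor age and CMV serostatus.

The package reimplements the bespoke computational procedures such a
study chains together, each as a separately tested function:

- **Composite QC filtering** — per-cell quality score
  `total = p_scrublet + p_hashsolo + f_erythro + Σ 1{flag}` (dual
  receptor, erythrocyte call, low UMI/genes/ADT, high mito), with
  cluster-level removal (median ≥ 1 or mean ≥ 0.3, per-tissue
  overrides) and rescue rules for populations like mast cells.
- **Pseudobulk differential expression** — counts summed per
  (donor × tissue × lineage/subset), representation filters (≥ 50
  cells/sample; genes with ≥ 5 counts in ≥ 40% of samples), log2-CPM
  linear models with empirical-Bayes moderation and a random-intercept
  block (donor for one-vs-rest tissue contrasts; chemistry × site for
  old-vs-young age contrasts with sex and CMV as fixed effects), plus
  per-gene variance decomposition over covariates.
- **Signature disentanglement** — Ward clustering of z-scored tissue
  signatures, pre-ranked GSEA (weighted Kolmogorov–Smirnov running sum
  with a permutation null), and composition-versus-expression summaries
  that say whether a tissue signature reflects cell-type frequency or
  within-subset transcription; per-donor Wilcoxon ADT testing with
  cell-number and depth equalization.
- **Consensus Poisson factorization** — an "HPF-lite" Poisson matrix
  factorization (`X ≈ WH`, multiplicative KL updates, monotone
  deviance) fit across restarts and ranks, factor communities by
  walktrap on the gene-score correlation graph, consensus refit from
  community medoids, nuisance-factor flags (ribosomal/heat-shock/
  metallothionein/hemoglobin/stress gene counts among the top 30),
  tissue-specific factor selection (mean cell score ≥ 1.8× the other
  tissues), cross-lineage module detection (Fisher-z 95% correlation
  threshold `r* = tanh(z₀.₉₇₅/√(M−3))`), mixed-model association of
  cell scores with age, and projection of external cells.
- **Compositional shifts** — binomial GLMs on subset counts with
  covariate-aware log2FC, majority-vote compositional analysis over all
  reference-subset choices, two-landmark ADT registration (negative
  peak → 0, positive peak → 1) and percent-positivity testing.
- **Counterfactual effect modules** — filtering and kNN smoothing
  (`S = 2·A·E`) of a per-cell × gene predicted-log2FC matrix, spectral
  co-clustering, signed marker scores, Youden-J thresholds transferred
  across tissues, and validation by relaxed pseudobulk DE + GSEA.
- **Repertoire clonality** — sequential V/J/CDR3 clonotype grouping
  (100% nucleotide identity for TCR, ≥ 85% amino-acid identity with
  single linkage for BCR) and the subsampled clonality score
  `1 − H_s / log₂C` (one minus Pielou evenness).
- **Synthetic atlas generator** — gamma-Poisson counts driven by
  additive gene programs with planted tissue programs, age effects,
  composition shifts, doublets, erythrocytes, batch-shifted bimodal
  ADTs and clonotype repertoires, with every ground truth recorded so
  recovery can be scored without any external data.

## Worked example

```r
library(immunatlas)

cfg <- atlas_config(n_donors = 8, tissue_groups = c("BLO", "JEJ"),
                    cells_per_donor_tissue = 40, n_genes = 420,
                    planted_tissue_programs = list(
                      gut_residency = list(tissue_group = "JEJ",
                                           activity_ratio = 5)))
sim <- simulate_atlas(cfg, seed = 1)
sim$matrix
#> CellMatrix: 672 cells x 420 genes, 8 ADTs
#>   donors: 8, tissue groups: BLO, JEJ

scores   <- compute_quality_scores(sim$matrix, low_umi = 500,
                                   low_genes = 130, low_adt = 0)
clusters <- cluster_cells_kmeans(sim$truth$embedding, k = 14, seed = 0)
keep     <- filter_low_quality_clusters(
  scores, clusters,
  subset_labels = sim$matrix$cell_meta$subset,
  tissue_labels = sim$matrix$cell_meta$tissue_group)
sum(keep)
#> [1] 640   # all 32 planted contaminants removed, no clean cells lost

pb <- filter_pseudobulk(pseudobulk_aggregate(subset_cells(sim$matrix, keep),
                                             "lineage"), min_cells = 10)
de <- fit_differential_expression(pb, list(type = "tissue", tissue = "JEJ"))
head(de[order(de$adj_p_val), c("gene", "unit", "logfc", "t", "adj_p_val")], 3)
#>   gene unit    logfc        t    adj_p_val
#>  G0261    B 1.713854 10.34874 1.977357e-09
#>  G0264    B 1.705347 10.52684 1.977357e-09
#>  G0267    B 1.708945 10.33499 1.977357e-09
```

The three top hits (and in fact the top 20) are planted gut-residency
program genes: the one-vs-rest contrast recovers the planted ~5× tissue
program as log2FC ≈ 1.7 at small adjusted p. Repertoire clonality per
donor on the same simulation:

```r
clonality_score(sim$truth$clone_ids, groups = sim$matrix$cell_meta$donor_id,
                subsample_n = 30, seed = 1)[1:3, c("group", "n_cells", "C",
                                                   "clonality")]
#>  group n_cells     C clonality
#>    D01      31  9.80 0.2644790
#>    D02      37 10.64 0.1315136
#>    D03      35  8.48 0.2803129
```

Values scatter around the generator's default clonality target of 0.3.
An end-to-end run (simulate → qc → pseudobulk DE → clonality, with a
provenance manifest per stage) is one call:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "immunatlas"))
```

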