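---
title: "Models and methods behind immunatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind immunatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunatlas)
```

immunatlas packages the statistical machinery of a cross-tissue,
cross-age immune-cell atlas analysis: quality filtering, pseudobulk
differential expression, gene-program factorization, compositional
testing, counterfactual effect modules and repertoire clonality. This
vignette explains each model, its assumptions and tunable parameters,
what the synthetic generator does and does not emulate, and the design
choices made where the procedure left genuine freedom.

## The synthetic atlas and what passing tests mean

Every stage is exercised on data from `simulate_atlas()`, whose
defaults mirror a realistic organ-donor study: 24 donors (14 male, 10
female, roughly half older than 40), six coarse tissue groups (blood,
bone marrow, spleen, lymph node, lung, jejunum), four immune lineages
of three subsets each, a binary CMV serostatus, two processing sites
and two library chemistries confounded only by chance.

Gene counts are gamma-Poisson. Each cell carries non-negative
activities over additive gene programs — a broad housekeeping program,
one identity program per subset, optional planted tissue/age programs,
and six nuisance programs carved from recognizable gene families
(heat-shock, ribosomal, metallothionein, hemoglobin, dissociation
stress, mitochondrial). The Poisson rate is the cell's depth (log-normal,
mean 5,000) times the row-normalized product of activities and
loadings, overdispersed by a gamma multiplier with shape `theta = 10`,
the standard negative-binomial mean–variance `mu + mu^2/theta` used by
single-cell simulators. Doublets are sums of two random cells;
erythrocytes put ~90% of their mass on hemoglobin genes; ADT counts
come from a two-component log-normal mixture whose component means
shift additively per processing site. Planted structure — tissue
programs with an activity ratio, per-gene or per-program age log2FCs,
composition shifts — is recorded in an `AtlasTruth` object sufficient
to score recovery without re-reading the configuration.

Deliberately **not** emulated: transcriptome-wide correlation
structure beyond shared programs, ambient RNA, realistic gene-length
or GC effects, continuous age, and receptor sequences (clonotypes are
ids; tiny toy contigs exercise the grouping rules). A passing recovery
test therefore shows that an algorithm finds the structure it is
designed to find under realistic noise, sample sizes and confounding —
not that it would perform identically on any real dataset.

Problem sizes in the tests and the acceptance script (hundreds of
genes, a few hundred to a few thousand cells, 6–24 donors) were chosen
as the smallest at which each method's statistical behaviour —
power, calibration, rank recovery — is stable and interpretable.

## Quality filtering

`compute_quality_scores()` sums heterogeneous evidence on its native
scales: two doublet probabilities, the erythrocyte-gene fraction on the
0–1 scale (a 0–100 scale would dominate the sum), and 0/1 indicators
for dual receptor, erythrocyte call, low UMI (< 2,000), low detected
genes (< 1,200), low ADT counts (< 200) and high mitochondrial fraction
(> 20%). Whether the mitochondrial indicator joins the sum is
ambiguous in practice, so it is included by default and excludable via
`include_mito = FALSE`. The count-based thresholds presume a full
transcriptome and ADT panel; on the synthetic few-hundred-gene panels
the worked examples scale them (e.g. `low_genes = 0.3 * n_genes`),
which is a property of the panel, not of the rule.

`filter_low_quality_clusters()` removes any cluster whose median score
is ≥ 1 or whose mean is ≥ 0.3 (both boundaries inclusive), with
per-tissue mean-cutoff overrides mirroring manually raised thresholds
for difficult tissues, and rescue rules that force retention of named
(subset, tissue) populations whose apparent low quality is biology
(mast cells, platelets, plasma cells). Clustering is an input — any
labeling works; a k-means fallback on an embedding ships for fixtures.
The filter is monotone (raising any component never rescues a removed
cluster) and order-invariant, both asserted by tests.

## Pseudobulk differential expression

Counts are summed per (donor × tissue × unit); a unit is a lineage or
a fine subset. Samples with fewer than 50 cells are dropped, genes are
kept when they reach 5 counts in at least 40% of retained samples
(inclusive boundary, per the printed wording), and a contrast is
skipped when an arm has fewer than 3 (tissue) or 4 (age/CMV) samples.
Relaxed mode (10 cells, 10%) and a counterfactual-validation mode
(5 cells, 1,000 total counts, 3 total counts per gene) exist for
low-input reruns.

The model is a linear model on `log2-CPM` with a 0.5 pseudocount and
empirical-Bayes variance moderation (`limma::eBayes`, trend on). The
within-donor dependence of one-vs-rest tissue contrasts — and the
within-batch dependence of age contrasts, which use sex and CMV as
fixed effects — is modeled as a shared intra-block correlation via
`limma::duplicateCorrelation`, the vectorized equivalent of a
random-intercept mixed model. This choice keeps 50-seed calibration
suites tractable on one CPU; when the block correlation is
unestimable the model falls back to fixed intercepts and flags the
unit. The package claims calibration and sign/rank agreement with
precision-weighted mixed-model implementations, not per-gene p-value
equality. Sign convention: positive log2FC means higher in the named
tissue, or in the older / CMV-positive group. BH adjustment is applied
within each (unit, contrast, tissue) family, matching per-table
adjusted p-values.

`decompose_variance()` fits, per gene, a variance-component model with
every covariate as a random intercept (lme4) and reports fractions of
variance; they are non-negative and sum to one by construction.

## Signatures, clustering and GSEA

Tissue-signature genes pass adjusted p < 0.05, log2FC > 1 and average
expression > 2 in at least one tissue × lineage combination; their
per-combination mean expression (use `mean_expression_by_group()`) is
z-scored per gene and clustered with Ward's method on Euclidean
distances, cut to exactly the requested number of clusters. The
number of clusters is a required parameter here; in a real atlas it is
a data-driven choice.

`gsea_preranked()` implements the weighted Kolmogorov–Smirnov running
sum: sorted by decreasing score, set members add `|score|^w /
sum(|scores in set|^w)` and non-members subtract `1/(n − |set|)`; the
enrichment score is the extremum. `w = 1` (weighted) is the default
and `w = 0` gives the classic statistic — both are offered since
pre-ranked analyses are reported with either. The null permutes gene
labels; NES divides by the mean |null ES| of the matching sign
(sign-stratified), the nominal p counts same-sign null ESs at least as
extreme (add-one correction), and FDR over terms is BH. The
implementation is pinned to a brute-force running-sum oracle on random
instances, and cross-checked against an independent implementation
(fgsea) for sign and significance in the test suite.

Whether a tissue signature is compositional or transcriptional is
summarized per subset × tissue from three quantities: the
within-lineage frequency fold-change versus other tissues, the
within-subset shift in mean cluster expression, and the cluster's GSEA
enrichment in subset-level DE. The flags ("composition-driven" when
log2 frequency-FC ≥ 1 with expression shift < 0.25; "expression-driven"
when enrichment is significant with frequency-FC < 0.5) are explicit
reporting heuristics — the visual evidence of the original analysis
formalized into configurable thresholds — and the raw evidence is
always emitted alongside them.

ADT differential abundance is tested per donor after subsampling to
equal group sizes and depth equalization (binomial thinning to the
smallest group-mean depth), then a two-sided tie-corrected Wilcoxon
rank-sum per marker; donors under 50 cells per group are excluded and
analyses with fewer than 4 eligible donors are skipped. Depth
equalization couples markers: a strong shift in one marker slightly
deflates others in the same cells, a real property of the balancing
procedure that the tests exercise separately from the null case.

## Consensus Poisson factorization

The factorization is a deliberately transparent "HPF-lite": maximize
the Poisson likelihood of `X ≈ WH` by multiplicative KL updates, which
guarantee a non-increasing deviance (asserted on every fit). The full
Bayesian hierarchy of probabilistic single-cell factorization tools is
out of scope; acceptance is planted-structure recovery, not numerical
equality with any particular tool. The scale ambiguity is fixed by
normalizing gene-score columns to sum to one. Genes enter the model
when detected in ≥ 1% of cells; balancing of cells across tissues or
donors and depth equalization are separate, testable preprocessing
steps.

Consensus over restarts: for each rank K in a range (15–30 at atlas
scale; 4–8 at desk scale), several restarts are fit and the best by
final deviance kept — the original convergence-based model selection
is not fully specified, so final deviance is used. Factors pooled
across kept models form a correlation graph (Pearson of gene-score
vectors, edges above a threshold, default 0.6); communities come from
walktrap, with a deterministic fallback — single-linkage clustering cut
at the same threshold, i.e. the connected components of the
super-threshold graph — satisfying the same acceptance tests.
Communities containing factors from at least two distinct models
become consensus factors (asserted in every output), and the final
model is refit seeded at community medoids.

Nuisance factors are flagged by strict count thresholds among the top
30 weighted genes: > 1 heat-shock, > 10 ribosomal, > 1
metallothionein, > 0 hemoglobin, > 7 stress-signature genes. A factor
is tissue-specific when its mean cell score in one tissue group is at
least 80% higher than the average of the remaining groups (inclusive:
ratio ≥ 1.8). Cross-lineage modules use the two-sided Fisher-z null
bound `r* = tanh(z₀.₉₇₅ / √(M − 3))` for correlations over M genes —
the printed "95% confidence threshold" is not defined further, and the
Fisher-z bound is the standard parametric reading; an empirical
permutation threshold can be substituted by passing a different
threshold. Factors need at least two super-threshold partners, which
structurally requires at least three lineage models — with only two
models a shared program has exactly one partner and is dropped; the
tests therefore pool three lineages, as the six-lineage study design
does.

Age association fits, per factor, a linear mixed model of cell scores
on age group plus chemistry, sex, site, CMV and (when supplied) two
tissue-type dummies, with donor as a random intercept
(lmerTest/Satterthwaite p-values, BH across factors; positive
coefficients mean higher in older donors). Covariate-adjusted
("partial regression") cell scores — residuals plus the intercept and
age effect — are returned for plotting. Projection of external cells
holds gene scores fixed and runs the cell-score updates on the gene
overlap (≥ 50% required).

## Compositional shifts and ADT positivity

Subset frequencies are tabulated within lineage per donor × tissue,
with 50-cell and 4-donor floors. The shift test is a binomial GLM with
logit link on (subset count, lineage total) — the GLM family of the
original is unstated; binomial-on-counts is the default and a
quasi-binomial model on percent responses is selectable, which also
serves percent-positivity and isotype-share responses. The effect size
reported is a covariate-aware log2FC: the log2 ratio of predicted
proportions at reference covariates with age set to old versus young.
Wald p-values are two-sided, BH-adjusted across units.

The majority-vote wrapper reruns any credible-effect backend once per
choice of reference subset and reports subsets flagged in strictly
more than half of the runs ("more than half" is a strict boundary,
asserted). The built-in backend is an additive-log-ratio linear model
with BH at FDR 0.05; the Bayesian compositional model it stands in for
is pluggable but not reimplemented.

ADT landmark registration is a simplified two-landmark version of the
full registration procedure: kernel-density peaks per batch and
marker, a strictly monotone piecewise-linear warp sending the negative
peak to 0 and the positive peak to 1 (single-peak batches are
shifted), ranks preserved exactly within batch. Acceptance is peak
alignment (within 0.05 after registration), not equality with any GUI
workflow. Percent positivity above a threshold (default 0.5, the
registered midpoint) feeds the same GLM.

## Counterfactual effect modules

The input contract is an `EffectMatrix`: dense per-cell × gene
predicted log2FCs for one covariate plus a cell embedding. The
counterfactual model that produces it is not reimplemented; a clearly
non-equivalent kNN-contrast estimator (`estimate_effects_knn()`) exists
for fixtures and demos.

Genes are dropped when raw mean expression is below 0.01 or the 95th
percentile of |log2FC| is below 0.1; cells represented in fewer than 3
samples are dropped. Smoothing multiplies the row-normalized 15-NN
affinity by the effects and doubles the result (`S = 2·A·E`): the
factor of two is implemented literally as printed despite its unusual
scaling, and can be disabled (`double = FALSE`) since downstream scores
are threshold-calibrated anyway; ties in neighbor distances break by
index.

Co-clustering uses Dhillon's bipartite spectral method
(`D1^(−1/2)|E|D2^(−1/2)`, leading `⌈log2 k⌉` non-trivial singular
vector pairs, k-means on the degree-scaled vectors). The bipartite
graph is built on |E| because the effect matrix is signed and the
normalized-cut formulation requires non-negative weights; a module is
a block of coherently *affected* cells and genes, and direction is
recovered at scoring time. `minibatch` is accepted for interface
parity; at desk scale plain k-means is used.

Two module-score rules are exposed: `sum_lfc` (default; per-cell sum
of effects over up-markers minus down-markers, the definition used for
plotting) and `weighted_sign_mean` (mean of sign-weighted effects, the
definition used by enrichment tooling). Markers are the top 50 genes
by |mean log2FC| within the module. The Youden threshold maximizes
J = sensitivity + specificity − 1 over midpoints of sorted unique
scores with auto-detected orientation, and the same cutoff transfers
to other tissues; a gene-threshold override (select cells with a named
gene's predicted log2FC below a constant) covers modules anchored to a
single gene. Validation reruns pseudobulk DE in the relaxed
counterfactual mode on module-positive cells and tests the module's
markers against the resulting ranking with GSEA.

## Repertoire clonality

Clonotype grouping applies the sequential criteria: partition by
identical V gene, J gene and CDR3 length on every chain, then 100%
CDR3 nucleotide identity for TCRs, or ≥ 85% CDR3 amino-acid identity
(1 − normalized Hamming distance, inclusive boundary) for BCRs with
single-linkage connected components — the linkage is not specified in
the source procedure, and single linkage is the permissive reading
consistent with "sequence similarity". Both chains must satisfy their
rule.

Clonality is `1 − H_s/log₂C` on a 100-cell subsample, where `H_s` is
the Shannon entropy (bits) of clone frequencies and `C` the number of
unique clonotypes observed. A single subsample is noisy, so the
default averages 25 draws and reports the Monte-Carlo SD;
`n_draws = 1` reproduces the literal single-draw procedure. `C = 1`
leaves evenness undefined; clonality is set to 1 by convention — the
limit of vanishing evenness is total clonal dominance — and flagged.
The repertoire simulator draws clone frequencies from a power law
whose exponent is calibrated by bisection against the subsampled score
itself, so generated repertoires hit a requested clonality within
±0.05 across the practically reachable range.

## Numerical choices and degenerate inputs

- Normalization uses the natural log (`ln(scale·c/T + 1)`), the
  dominant single-cell convention; zero counts stay zero and
  zero-total cells are an error naming the cells.
- Depth downsampling is per-cell binomial thinning toward the minimum
  group-mean depth (exact multinomial subsampling is the alternative
  flag); it never creates counts and is reproducible given a seed.
- Factorization updates add 1e-12 inside logs and denominators;
  convergence is relative deviance change below `tol` (1e-5 for
  consensus runs, 1e-6 for single fits).
- Degenerate inputs fail loudly and early: all-zero genes/cells before
  factorization, constant effect matrices before co-clustering,
  single-class sources before Youden thresholds; constant ADT markers
  get an identity warp and a flag rather than an error.
- All stochastic steps take explicit seeds; the pipeline derives
  per-stage seeds from one global seed so stages rerun independently
  and deterministically.

## Known limitations

The pseudobulk engine shares one intra-block correlation across genes
rather than estimating a per-gene random effect; variance fractions
rely on REML variance components that can hit the zero boundary for
weak covariates; the spectral co-clustering ignores effect signs when
forming blocks; GSEA p-values are bounded below by 1/(n_perm + 1); the
generator's nuisance programs are broad-spectrum rather than
cell-state specific, so nuisance-factor flagging is exercised on
clear-cut cases only; and tissue-group mapping, QC thresholds and
composition-flag heuristics are configuration with sensible defaults,
not biology discovered from data.
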