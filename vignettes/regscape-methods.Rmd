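---
title: "Methods: multimodal regulatory-landscape analysis with regscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal regulatory-landscape analysis with regscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

regscape re-implements, as a tested pipeline, an integrative analysis of the
regulatory landscape of a differentiating tissue (the motivating system is
the embryonic mouse neocortex, with neural stem cells differentiating through
intermediate progenitors into projection neurons). It links distal
accessibility peaks to genes from paired single-cell RNA/ATAC data, classifies
the timing of enhancer activation along pseudotime, analyses cell-type
resolved Hi-C maps (insulation, TADs, compartments, a local kNN contact
score, aggregate enrichment), computes per-motif statistics of 3D looping and
DNA-methylation specificity against permutation nulls, and scores MPRA
reporter activity against scrambled controls. Every stage can be exercised on
synthetic data with planted, recorded ground truth.

This vignette documents the statistical models, their assumptions, the
defaults and the design decisions taken where the underlying methods
literature leaves choices open.

## Enhancer–gene pair (EGP) linkage

Paired RNA and ATAC counts are aggregated into *metacells*: each seed cell is
grouped with its k − 1 nearest Euclidean neighbours in a reduced-dimension
space (`group_metacells()`, default k = 50), and group counts are summed,
depth-normalized to counts-per-10k and log2(1 + x) transformed. Aggregation
stabilizes the sparse single-cell signal; the normalization is our concrete
reading of "log-normalized" aggregate profiles, applied identically to both
modalities so that shared structure is preserved.

Candidate pairs are distal peaks (center more than 5 kb from every TSS)
matched to genes with a TSS within 500 kb on the same chromosome. The Pearson
correlation r of peak accessibility and gene expression across metacells is
compared to a *trans-based null*: for every tested gene, `n_null` (default
100) peaks are sampled from other chromosomes and their correlations with the
gene are pooled genome-wide. Two-sided empirical p-values use add-one
smoothing, p = (1 + #{|r_null| ≥ |r|}) / (1 + N_null), so p is never zero;
q-values are Benjamini–Hochberg. Classes follow fixed thresholds: posCor
(r ≥ 0.35, q ≤ 0.1), negCor (r ≤ −0.35, q ≤ 0.1), control (|r| < 0.35,
q > 0.1, subsampled without replacement to the posCor count under a recorded
seed).

Design decisions: the null is pooled genome-wide rather than per gene —
at desk scale a per-gene null of 100 draws cannot resolve p below 10^-2,
while the pooled null resolves the small p-values that survive BH; the
prior literature this step descends from does not specify the choice.
Distances are measured from the peak center (the peak-edge alternative is
ambiguous for wide peaks). The control-pair subsampling seed is recorded in
the table attributes.

Cluster-specific peaks (`call_cluster_specific_peaks()`) use pseudobulk
feature binarization: per peak, the top cluster is tested against the
next-highest cluster with a two-sided pooled-variance t-test on replicate
log2 CPM; specific calls require BH-adjusted p < 0.01 and log2 fold change
≥ 0.25. Clusters with fewer than 100 cells are split into two seeded
pseudoreplicates. A t-test (rather than Wilcoxon) is the default because
replicate counts are 2–4; with so few observations rank tests have no
resolution.

## Pseudotime dynamics and the dPD statistic

Per-feature values are smoothed along pseudotime with a penalized cubic
regression spline fitted by REML (`mgcv::gam`, basis dimension 10), evaluated
on a 100-point grid and min–max rescaled to [0, 1]. Features observed in
fewer than 20 cells are skipped; constant features short-circuit to a
degenerate flag before fitting. For an enhancer–gene pair, dPD is the
pseudotime of the accessibility maximum minus the pseudotime of the
expression maximum (global maxima; ties resolve to the earliest grid point).
Negative dPD means accessibility precedes expression. Timing classes use a
threshold τ: primed (dPD ≤ −τ), delayed (dPD ≥ τ), immediate otherwise.

The pseudotime scale of trajectory-inference tools is arbitrary, so τ is
expressed in native pseudotime units with default τ = 2; the simulator fixes
the trajectory to [0, 20] so that the default threshold equals 10% of the
trajectory. Both are configurable and recorded.

## Hi-C core

**Filtering.** Read pairs on the same restriction fragment, or closer than
1 kb, are removed (`filter_contacts()`).

**Expected model.** `make_expected()` draws, for each observed contact at
distance d, one contact at the same distance with its position uniform along
the chromosome. The distance multiset is preserved *exactly*, so every
enrichment statistic downstream is conditioned on the observed distance-decay
by construction. Marginal-coverage (matrix-balancing) preservation is
deliberately omitted at this scale.

**kNN score.** The bounded local enrichment score is a re-implementation
contract: for a query point q in the 2-D (pos1, pos2) plane, let r_obs and
r_exp be the Chebyshev distances to the k-th nearest observed and expected
contact (k = 100). The score is 100 (r_exp² − r_obs²) / (r_exp² + r_obs²),
bounded in [−100, 100], exactly zero when the two sets coincide, and exactly
antisymmetric under swapping observed and expected. The search runs in
compiled code over a bucketed grid, so a million contacts and millions of
queries are practical. Bit-compatibility with the external normalization
package used in the source literature is not claimed; the contract preserves
its documented properties (kNN-based, pooled replicates, k = 100, bounded
score).

**Insulation and boundaries.** The insulation value of a 1-kb bin is the mean
contact count in the 250 kb × 250 kb rectangle bridging it (upstream window
× downstream window); the score is minus the log2 ratio to the genome-wide
mean, so high scores mark strong insulation. No pseudocount is used — this
keeps the score exactly invariant to global count scaling; empty windows
yield NA. Boundaries are strict local maxima within ±2 kb (ties report the
leftmost bin) above the genome-wide 90% score quantile. Differential
boundaries compare per-cell-type z-normalized scores; a boundary is
differential when the largest pairwise |Δz| exceeds 1, and the differential
set is clustered with seeded k-means (default k = 3, mirroring the three
cell-type patterns in the motivating data).

**Compartments.** Per chromosome, the 250-kb binned matrix is normalized
observed/expected by diagonal, converted to a Pearson correlation matrix, and
the leading eigenvector extracted. The sign is oriented so the eigenvector
correlates positively with a supplied accessibility-density track; A = positive.
The eigenvector is scaled by the square root of the leading eigenvalue's
share of the bin count: structureless maps give a share near 0.02 (the random
matrix edge) while genuine checkerboards sit well above 0.1, which is the
low-confidence flag threshold.

**Compartment strength.** Over bin pairs ≥ 10 Mb apart,
S = (mean AA + mean BB) / (2 · mean AB) with per-pair *means* rather than raw
sums: means make S invariant to the number of A and B bins, and give the
analytic identity S = f² when within-compartment contacts are planted at
f times and between-compartment at 1/f times baseline. The saddle ranks bins
into 5 E1 quantiles (the bin count in the motivating figures is not stated)
and reports mean observed/expected per quantile pair.

**Aggregate enrichment.** TAD aggregation extends each TAD by its own length
on both sides, splits the 3×-length span into 100 bins and accumulates
observed and expected counts across TADs before taking log2 ratios
(aggregate-then-log; per-TAD log ratios are undefined at list-level
sparsity). APA does the same in windows centered on anchor pairs (default
33 bins over 110 kb, so the central 3 × 3 block spans the canonical 10-kb
loop pixel); the summary is the center block versus the mean of the four
corner blocks, with counts pooled per block before the ratio.

## TF motif specificity

For each motif, the peaks containing it are ranked by maximum pseudobulk
accessibility across clusters and the top 5,000 retained as motif-centered
points; motifs whose TF is not expressed (RPKM-like ≤ 1) or not among the
most variable genes are dropped. The background is 1,000 seeded samples of
5,000 points from the top-50,000 accessibility pool. Point pairs at least
10 kb apart within the same TAD (capped at 20,000 per motif, seeded; a
minimum of 50 stabilizes medians) are scored with the windowed maximum kNN
score (10 × 10 kb, 3 × 3 query lattice), and the per-cell-type statistic is
the median over pairs, corrected by subtracting the mean of the background
set medians. Reported per motif: the maximum corrected score across cell
types, the SD across cell types normalized by the mean background SD
(≈ 1 means background-like variability; the "normalized variance" axis of
the motivating figures is not defined there, so this definition is ours and
declared), and permutation p-values
p = (1 + #{background ≥ observed}) / (1 + 1,000) for both statistics.
A motif is called significant when either p < 0.05; both p-values are
reported unmerged. Methylation specificity mirrors this with count-weighted
mean CpG methylation in 500-bp windows, reporting the minimum across cell
types (one-sided low) and the SD (one-sided high).

## Methylation

CpGs are pooled across replicates per cell type before the 10× coverage
filter (per-replicate filtering for 5× single-replicate use sits behind a
flag). Conversion rate = 1 − methylated fraction on the unmethylated spike-in
contig; detection rate = methylated fraction on the fully methylated
spike-in. Metaprofiles are count-weighted means per 50-bp position bin
relative to feature centers (strand-flipped), with SEM across replicates; the
rightmost bin is folded so the +flank edge does not create a sliver bin.

## MPRA

Designed sequences are 266 bp centered at the floor midpoint of the source
interval, with a 4-bp category tag (TCCG for motif mutants, ATTA otherwise).
Scrambled controls are exact nucleotide permutations (GC conserved by
construction), rejection-resampled until the best log2-odds PWM hit over the
expressed-motif set falls below a threshold, else the minimum-scoring
candidate is kept. Motif mutants permute the hit subsequence 100 times and
keep the candidate with the lowest PWM score over the hit region extended by
the PWM width. Barcodes are assigned to a CRE given ≥ 3 supporting reads and
≥ 80% purity, per tag class, dropping cross-class ambiguity.

Activity is the log2 ratio of pseudocounted RNA and DNA counts-per-million of
barcode-summed UMIs ("ratio of sums"). The robust z (MAD-z) compares each
CRE to the median and 1.4826-scaled MAD of scrambled-control activities, with
a two-sided normal p-value; p ≤ 0.05 is called active. This replaces the
external MPRA package's internal model, which is unspecified in the
motivating methods; the decision rule (p ≤ 0.05 on a MAD-scaled score) is
reproduced as stated. The simulator's default of 200 scrambled controls per
300 candidate CREs keeps the MAD estimate tight enough for the nominal 5%
null rate (with ~100 controls the test becomes visibly conservative).

## The synthetic-data generator

`sim_config()` fixes the study conditions at desk scale (roughly 1/100 of
the motivating experiment): three cell types along a pseudotime trajectory on
[0, 20], 800 cells per type, 1,000 genes, 1,600 peaks, 200/200/600 planted
posCor/negCor/null pairs with effect_r = 0.8, timing offsets
(−4, 0, +4) for primed/immediate/delayed enhancers, 10^6 contacts per cell
type with distance-decay exponent 1, within-TAD factor 5, compartment factor
2, CpG baseline 0.8 with enhancer hypomethylation to 0.2, conversion error
0.5% and detection 96.5%, and MPRA depth 100 with 50 barcodes per CRE and a
planted log2 activity of 2. Negative-binomial dispersion is 0.2 throughout.

A design point worth spelling out: cells carry, besides pseudotime, 16
orthogonal latent state factors (cell-to-cell biological variation not
aligned with the trajectory — think cell cycle, metabolic state), and every
feature mixes a Gaussian pseudotime program (width 3) with a random loading
on those factors. Without them, all smooth features on a one-dimensional
trajectory inhabit a ~5-dimensional function space and unrelated features
correlate strongly, which makes correlation-based linkage ill-posed at any
sequencing depth; the latent factors restore the high-dimensional
decorrelation of real tissue. The untargeted feature population carries
trajectory weights ~ U(0, 0.4) (most genes are not strongly stage-specific),
planted pairs carry 0.35, and null-pair peaks are drawn from the same
population as the genome-wide peak pool, which is what keeps the trans-null
p-values uniform for truly null pairs. Planted pairs share the gene's full
program with only the pseudotime bump shifted by the timing offset, so
priming shifts the accessibility maximum without destroying the pair's
correlation.

What the generator deliberately does not emulate: read-level data (no
FASTQ), doublets, batch effects beyond two replicates, trans-chromosomal
contacts, matrix-balancing biases, or sequence-driven accessibility. Passing
tests therefore demonstrate the statistical machinery on data with the
stated covariance and count structure, not robustness to alignment
artefacts or library-specific biases of real experiments.

Hi-C test geometry: contacts are sampled per 1-kb pixel and jittered within
the pixel; loop anchors snapped to the 10-kb grid take a fast keyed lookup.
The kNN score's sensitivity to a focal loop depends on the local contact
density relative to k, so single-pixel checks use a dense 2-Mb map while
boundary and compartment checks use 10–60 Mb chromosomes; problem sizes in
the tests (depth 10^6, 10 boundaries, 50 loops, 1,000 background sets of
5,000 from a 50,000 pool) follow the planted-recovery conditions stated with
each check.

## Known limitations

* The empirical p floor of the linkage null is 1/(1 + N_null); genes on
  genomes with a single chromosome have no trans null at all (an error).
* The kNN score is computed on ordered coordinates (pos1 ≤ pos2); queries
  near the diagonal do not see mirror-image contacts.
* Compartment signs depend on the supplied orientation track; without one,
  the sign convention is deterministic but arbitrary per chromosome.
* The MAD-z normal tail is an approximation; with fewer than ~150 scrambled
  controls it is conservative.
* `differential_boundaries()` assumes insulation tracks share a bin grid
  across cell types (true for tracks computed from the same chromosome set).
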