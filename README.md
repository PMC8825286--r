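# regscape

Tools for dissecting the regulatory landscape of a differentiating tissue —
the motivating system is the embryonic mouse cortex, where neural stem cells
(NSC) differentiate through intermediate progenitors (IPC) into projection
neurons (PN) — by integrating paired single-cell RNA/ATAC data with
cell-type-resolved Hi-C contacts, CpG methylation and massively parallel
reporter assays (MPRA).

The package is aimed at computational biologists who want the statistical
machinery of this kind of multimodal study as reusable, tested functions:

* **Enhancer–gene pair (EGP) linkage.** Distal peaks (> 5 kb from any TSS)
  are paired with genes within 500 kb and scored by the Pearson correlation
  *r* of log-normalized kNN-metacell accessibility and expression. An
  empirical p-value compares |r| to a pooled *trans* null (each gene against
  peaks from other chromosomes), with BH correction; pairs with r ≥ 0.35 and
  FDR q ≤ 0.1 are positively correlated EGPs (negCor: r ≤ −0.35; control
  pairs subsampled to match).
* **Enhancer timing (dPD).** Features are smoothed along pseudotime with
  penalized cubic splines (REML); dPD = argmax(accessibility) −
  argmax(expression). Enhancers are *primed* (dPD ≤ −2), *immediate*, or
  *delayed* (dPD ≥ 2); negative values mean accessibility precedes
  expression.
* **Hi-C core.** Read-pair filtering, a distance-multiset-preserving
  expected model, a bounded kNN contact score
  100 (r_exp² − r_obs²)/(r_exp² + r_obs²) on Chebyshev k-th-neighbour radii
  (k = 100, compiled search), insulation (±250 kb at 1 kb) with TAD-boundary
  calling (local 2-kb maxima above the 90% quantile), differential
  boundaries across cell types, A/B compartments (leading eigenvector at
  250 kb) with strength S = (AA + BB)/(AB + BA) on per-pair means, aggregate
  TAD and pair (APA) enrichment with center-vs-corner ratios.
* **TF motif specificity.** Per motif, the top-5,000 most accessible
  motif-containing peaks are paired within TADs and scored against 1,000
  background sets of 5,000 peaks from the top-50,000 pool; permutation
  p-values for the maximum background-corrected looping score across cell
  types and for its cross-cell-type variability, plus the analogous
  DNA-methylation statistics (minimum level, variability) in 500-bp windows.
* **Methylation.** 10×-coverage CpG filtering (replicates pooled), bisulfite
  conversion/detection QC from unmethylated/fully methylated spike-in
  contigs, and feature-anchored metaprofiles.
* **MPRA.** 266-bp library design with ATTA/TCCG category tags, GC-exact
  scrambled controls and motif mutants (lowest-scoring of 100 permutations),
  barcode association (≥ 3 reads, ≥ 80% purity), and activity scoring: log2
  RNA/DNA ratio-of-sums per CRE, robust z (MAD-z) against scrambled
  controls, significant at p ≤ 0.05.
* **Synthetic data with planted truth.** `sim_config()` +
  `simulate_cells()` / `simulate_contact_maps()` / `simulate_methylation()`
  / `simulate_mpra_counts()` generate every input with recorded ground
  truth, so the whole pipeline is testable end to end without external
  downloads.

## Worked example

```r
library(regscape)

cfg <- sim_config(seed = 42)
cells <- simulate_cells(cfg)
cells
#> <cell_data> 2400 cells | 1000 genes | 1600 peaks | 3 cell types

groups <- group_metacells(cells$reduced, k = 50,
                          rna = cells$rna, atac = cells$atac,
                          n_groups = 400)
egps <- link_peaks_to_genes(groups, cells$peaks, cells$genes, seed = 42)
table(egps$class)
#>      control       negCor       posCor unclassified
#>          212          222          212         1554

truth <- ground_truth(cells)
m <- merge(egps, truth, by = c("peak_id", "gene_id"))
mean(m[m$class.y == "posCor", ]$class.x == "posCor")
#> 0.965   # 96.5% of planted positively correlated pairs recovered

# timing of one recovered primed enhancer
pair <- m[m$class.x == "posCor" & m$timing_class == "primed", ][1, ]
pt <- cells$cell_meta$pseudotime
enh  <- smooth_along_pseudotime(cells$atac[, pair$peak_id], pt)
gene <- smooth_along_pseudotime(cells$rna[, pair$gene_id], pt)
compute_dpd(enh, gene)
#> $dpd
#> [1] -3.428413
#> $timing_class
#> [1] "primed"
```

The 212 posCor calls contain the planted positively correlated pairs (212
calls at 96.5% recovery of the 200 planted, ~10% empirical FDR); the
enhancer's accessibility peaks 3.4 pseudotime units before its gene's
expression, hence *primed*. `vignettes/regscape-methods.Rmd` documents the
models, defaults and design decisions.

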