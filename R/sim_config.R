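#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by all synthetic
#' data generators ([simulate_cells()], [simulate_contact_maps()],
#' [simulate_methylation()], [simulate_mpra_counts()]). The defaults define a
#' desk-scale emulation of a three-stage neural differentiation trajectory
#' (neural stem cells, intermediate progenitors, projection neurons) with
#' planted enhancer-gene pairs, pseudotime offsets, TADs, compartments, loops,
#' enhancer hypomethylation and MPRA activities.
#'
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output from every generator.
#' @param n_cells_per_type Cells simulated per cell type.
#' @param cell_types Ordered cell-type labels along the trajectory.
#' @param n_genes,n_peaks Number of genes / ATAC peaks.
#' @param genome Data frame with columns `chrom`, `length` (bp).
#' @param n_latent Number of orthogonal latent cell-state factors beyond
#'   pseudotime (cell-to-cell variation not aligned with the trajectory).
#' @param n_egp_pos,n_egp_neg,n_egp_null Planted positively correlated,
#'   negatively correlated and independent (null) peak-gene pairs.
#' @param effect_r Target correlation magnitude in (0, 1] for planted pairs.
#' @param timing_offsets Named numeric vector `c(primed=, immediate=,
#'   delayed=)` of pseudotime offsets (accessibility argmax minus expression
#'   argmax) planted on posCor pairs.
#' @param hic_depth Contacts generated per cell type.
#' @param decay_exponent Power of the contact distance decay (intensity
#'   proportional to distance^-decay_exponent).
#' @param tad_factor Multiplicative intensity boost for within-TAD contacts.
#' @param comp_factor Same-compartment contacts are boosted by this factor and
#'   cross-compartment contacts damped by its inverse.
#' @param meth_baseline,meth_enh_level Genome-wide CpG methylation level and
#'   the level planted at active-enhancer CpGs of the matching cell type.
#' @param conversion_error,detection_rate True methylated fraction of the
#'   unmethylated spike-in contig and detected fraction on the fully
#'   methylated spike-in contig.
#' @param mpra List with `n_cre`, `n_scrambled`, `barcodes_per_cre`, `depth`
#'   (mean DNA count per barcode) and `activity` (named planted log2
#'   activities per category).
#' @param pseudotime_scale Maximum pseudotime (trajectory spans `[0, scale]`).
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion) of the
#'   count sampling.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_type = 800L,
                       cell_types = c("NSC", "IPC", "PN"),
                       n_genes = 1000L,
                       n_peaks = 1600L,
                       genome = data.frame(
                         chrom = paste0("chr", 1:4),
                         length = rep(160e6, 4)),
                       n_latent = 16L,
                       n_egp_pos = 200L,
                       n_egp_neg = 200L,
                       n_egp_null = 600L,
                       effect_r = 0.8,
                       timing_offsets = c(primed = -4, immediate = 0, delayed = 4),
                       hic_depth = 1e6,
                       decay_exponent = 1.0,
                       tad_factor = 5,
                       comp_factor = 2,
                       meth_baseline = 0.8,
                       meth_enh_level = 0.2,
                       conversion_error = 0.005,
                       detection_rate = 0.965,
                       mpra = list(n_cre = 300L, n_scrambled = 200L,
                                   barcodes_per_cre = 50L, depth = 100,
                                   activity = c(posCor = 2, negCor = 0,
                                                noCor = 0, scrambled = 0)),
                       pseudotime_scale = 20,
                       dispersion = 0.2) {
  cfg <- list(seed = as.integer(seed),
              n_cells_per_type = as.integer(n_cells_per_type),
              cell_types = as.character(cell_types),
              n_genes = as.integer(n_genes),
              n_peaks = as.integer(n_peaks),
              n_latent = as.integer(n_latent),
              genome = as.data.frame(genome),
              n_egp_pos = as.integer(n_egp_pos),
              n_egp_neg = as.integer(n_egp_neg),
              n_egp_null = as.integer(n_egp_null),
              effect_r = effect_r,
              timing_offsets = timing_offsets,
              hic_depth = hic_depth,
              decay_exponent = decay_exponent,
              tad_factor = tad_factor,
              comp_factor = comp_factor,
              meth_baseline = meth_baseline,
              meth_enh_level = meth_enh_level,
              conversion_error = conversion_error,
              detection_rate = detection_rate,
              mpra = mpra,
              pseudotime_scale = pseudotime_scale,
              dispersion = dispersion)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_cells_per_type, cfg$n_genes, cfg$n_peaks,
              cfg$mpra$n_cre, cfg$mpra$n_scrambled, cfg$mpra$barcodes_per_cre)
  if (any(counts <= 0)) stop("all counts in sim_config must be > 0")
  if (nrow(cfg$genome) < 1 || any(cfg$genome$length <= 0)) {
    stop("genome must contain at least one chromosome of positive length")
  }
  stop_missing_column(cfg$genome, c("chrom", "length"), "genome")
  probs <- c(cfg$meth_baseline, cfg$meth_enh_level,
             cfg$conversion_error, cfg$detection_rate)
  if (any(probs < 0 | probs > 1)) stop("methylation levels must lie in [0, 1]")
  if (cfg$effect_r <= 0 || cfg$effect_r > 1) stop("effect_r must be in (0, 1]")
  if (!all(c("primed", "immediate", "delayed") %in% names(cfg$timing_offsets))) {
    stop("timing_offsets must name primed, immediate and delayed")
  }
  if (max(abs(cfg$timing_offsets)) >= cfg$pseudotime_scale) {
    stop("timing offsets exceed the pseudotime range")
  }
  if (length(cfg$cell_types) < 2) stop("need at least two cell types")
  if (cfg$hic_depth <= 0) stop("hic_depth must be > 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|",
      length(x$cell_types), "cell types x", x$n_cells_per_type, "cells |",
      x$n_genes, "genes,", x$n_peaks, "peaks |",
      x$n_egp_pos, "pos /", x$n_egp_neg, "neg /", x$n_egp_null, "null EGPs |",
      "Hi-C depth", format(x$hic_depth, big.mark = ","), "\n")
  invisible(x)
}
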