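#' Filter cells on per-modality quality-control metrics
#'
#' RNA cells are retained when they have at least 1,000 detected genes and
#' 2,500 UMIs, at most 7,000 genes (doublet guard), at most 10% mitochondrial
#' counts, and are not among the top 4% of cells by UMI count. ATAC cells are
#' retained with 10,000-120,000 unique fragments and a TSS enrichment between
#' 8 and 25. Cell order is preserved.
#'
#' @param cells A `cell_data` object (see [simulate_cells()]) or a data.frame
#'   of per-cell metadata.
#' @param modality `"rna"` or `"atac"`.
#' @return The filtered object, with a `qc_report` attribute counting cells
#'   failing each rule (evaluated independently) and the total removed.
#' @export
qc_filter_cells <- function(cells, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  meta <- if (inherits(cells, "cell_data")) cells$cell_meta else as.data.table(cells)
  if (modality == "rna") {
    stop_missing_column(meta, c("n_genes", "n_umis", "pct_mito"), "cell metadata")
    umi_cap <- quantile(meta$n_umis, 0.96, names = FALSE)
    fail <- list(
      low_genes = meta$n_genes < 1000,
      low_umis = meta$n_umis < 2500,
      high_genes = meta$n_genes > 7000,
      high_mito = meta$pct_mito > 10,
      top_umi_doublet = meta$n_umis > umi_cap)
  } else {
    stop_missing_column(meta, c("n_fragments", "tss_enrichment"), "cell metadata")
    fail <- list(
      low_fragments = meta$n_fragments < 10000,
      high_fragments = meta$n_fragments > 120000,
      low_tss = meta$tss_enrichment < 8,
      high_tss = meta$tss_enrichment > 25)
  }
  drop <- Reduce(`|`, fail)
  report <- c(vapply(fail, sum, integer(1)), removed = sum(drop),
              kept = sum(!drop))
  keep <- which(!drop)
  out <- if (inherits(cells, "cell_data")) {
    res <- cells
    res$cell_meta <- meta[keep]
    res$rna <- cells$rna[keep, , drop = FALSE]
    res$atac <- cells$atac[keep, , drop = FALSE]
    res
  } else meta[keep]
  attr(out, "qc_report") <- report
  out
}

#' TSS enrichment from Tn5 insertion positions
#'
#' Aggregates insertions within +/-2,000 bp of each TSS (profiles of
#' minus-strand genes are mirrored), normalizes the profile to the mean
#' insertion rate in the 1,900-2,000 bp flanks, smooths with a 51-bp centered
#' moving average and reports the maximum smoothed value. A zero-signal flank
#' yields `NA` with an `undefined` attribute rather than infinity.
#'
#' @param insertions data.frame with `chrom`, `pos` and optionally `cell`; if
#'   `cell` is present a per-cell named vector is returned.
#' @param genes data.frame with `chrom`, `tss`, `strand`.
#' @param flank_bp Profile half-width (bp).
#' @param norm_range Distances (bp) from the TSS defining the normalization
#'   flanks.
#' @param smooth_bp Width of the centered moving average (bp, odd).
#' @return Enrichment value(s); the full smoothed profile of the last
#'   aggregate computed is attached as attribute `profile`.
#' @export
compute_tss_enrichment <- function(insertions, genes, flank_bp = 2000,
                                   norm_range = c(1900, 2000), smooth_bp = 51) {
  insertions <- as.data.table(insertions)
  genes <- as.data.table(genes)
  stop_missing_column(insertions, c("chrom", "pos"), "insertions")
  stop_missing_column(genes, c("chrom", "tss", "strand"), "genes")
  if (!nrow(genes)) stop("need at least one TSS")
  if (!is.null(insertions$cell)) {
    cells <- unique(insertions$cell)
    return(vapply(cells, function(cc) {
      compute_tss_enrichment(insertions[cell == cc, .(chrom, pos)], genes,
                             flank_bp, norm_range, smooth_bp)
    }, numeric(1)))
  }
  prof <- numeric(2 * flank_bp + 1)
  setorder(insertions, chrom, pos)
  for (i in seq_len(nrow(genes))) {
    ins <- insertions[chrom == genes$chrom[i], pos]
    lo <- genes$tss[i] - flank_bp
    hi <- genes$tss[i] + flank_bp
    sel <- ins[ins >= lo & ins <= hi]
    if (!length(sel)) next
    rel <- sel - genes$tss[i]
    if (genes$strand[i] == "-") rel <- -rel
    tab <- tabulate(rel + flank_bp + 1L, nbins = 2 * flank_bp + 1L)
    prof <- prof + tab
  }
  rel_pos <- -flank_bp:flank_bp
  flank_idx <- which(abs(rel_pos) >= norm_range[1] & abs(rel_pos) <= norm_range[2])
  flank_mean <- mean(prof[flank_idx])
  if (flank_mean == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  norm <- prof / flank_mean
  sm <- as.numeric(stats::filter(norm, rep(1 / smooth_bp, smooth_bp), sides = 2))
  out <- max(sm, na.rm = TRUE)
  attr(out, "profile") <- data.table(rel_pos = rel_pos, smoothed = sm)
  out
}
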