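#' Filter CpGs on total coverage
#'
#' Replicates are pooled per cell type before filtering (counts summed per
#' CpG), and only CpGs with at least `min_cov` total coverage are kept.
#' Per-replicate filtering (for 5x single-replicate use) is available behind
#' `pool_replicates = FALSE`.
#'
#' @param table A methylation table (`chrom`, `pos`, `meth_count`,
#'   `total_count`, `cell_type`, optional `replicate`, `spike_in`).
#' @param min_cov Minimum total coverage.
#' @param pool_replicates Pool replicates before filtering.
#' @return Filtered data.table (with `replicate = "pooled"` when pooled).
#' @export
filter_cpgs <- function(table, min_cov = 10, pool_replicates = TRUE) {
  dt <- as.data.table(table)
  stop_missing_column(dt, c("chrom", "pos", "meth_count", "total_count",
                            "cell_type"), "methylation table")
  if (is.null(dt$spike_in)) dt[, spike_in := "none"]
  if (pool_replicates) {
    dt <- dt[, .(meth_count = sum(meth_count), total_count = sum(total_count),
                 replicate = "pooled"),
             by = .(chrom, pos, cell_type, spike_in)]
  }
  dt[total_count >= min_cov]
}

#' Bisulfite conversion and detection rates from spike-in controls
#'
#' The conversion rate is one minus the methylated fraction observed on the
#' unmethylated control contig; the detection rate is the methylated
#' fraction observed on the fully methylated control contig. A missing
#' spike-in class yields `NA` for that rate.
#'
#' @param table A methylation table carrying a `spike_in` column.
#' @return List with `conversion_rate` and `detection_rate` (fractions).
#' @export
conversion_qc <- function(table) {
  dt <- as.data.table(table)
  stop_missing_column(dt, c("meth_count", "total_count", "spike_in"),
                      "methylation table")
  rate <- function(flag) {
    sub <- dt[spike_in == flag]
    if (!nrow(sub) || sum(sub$total_count) == 0) return(NA_real_)
    sum(sub$meth_count) / sum(sub$total_count)
  }
  list(conversion_rate = 1 - rate("unmethylated_control"),
       detection_rate = rate("methylated_control"))
}

#' Methylation metaprofile around genomic features
#'
#' Computes the CpG-count-weighted mean methylation per position bin relative
#' to feature centers (profiles of minus-strand features are mirrored),
#' averaged per cell type with the standard error of the mean across
#' replicates. Also returns the per-feature weighted mean within
#' `+/- window/2` of the center. Features without any covered CpG in the
#' flank are excluded and counted.
#'
#' @param table A methylation table (ideally coverage-filtered).
#' @param features data.frame with `chrom`, `pos` (center), optional
#'   `strand`, optional `feature_id`.
#' @param flank Profile half-width (bp).
#' @param window Width (bp) of the central window for per-feature means.
#' @param binwidth Profile bin width (bp).
#' @return List with `profile` (data.table `cell_type`, `rel_pos`, `mean`,
#'   `sem`), `per_feature` (`feature_id`, `cell_type`, `level`, `n_cpgs`)
#'   and `n_empty_features`.
#' @export
feature_meth_profile <- function(table, features, flank = 2000, window = 500,
                                 binwidth = 50) {
  dt <- as.data.table(table)
  features <- as.data.table(features)
  if (!nrow(features)) stop("no features supplied")
  if (is.null(features$feature_id)) features[, feature_id := sprintf("feat_%05d", .I)]
  if (is.null(features$strand)) features[, strand := "+"]
  if (is.null(dt$replicate)) dt[, replicate := "pooled"]
  setorder(dt, chrom, pos)
  hits <- list()
  for (cc in unique(features$chrom)) {
    sub <- dt[chrom == cc]
    if (!nrow(sub)) next
    f <- features[chrom == cc]
    for (i in seq_len(nrow(f))) {
      lo <- f$pos[i] - flank; hi <- f$pos[i] + flank
      ix <- which(sub$pos >= lo & sub$pos <= hi)
      if (!length(ix)) next
      h <- sub[ix]
      h[, rel := pos - f$pos[i]]
      if (f$strand[i] == "-") h[, rel := -rel]
      h[, feature_id := f$feature_id[i]]
      hits[[paste(cc, i)]] <- h
    }
  }
  covered <- unique(rbindlist(hits)$feature_id)
  n_empty <- nrow(features) - length(unique(covered))
  if (!length(hits)) stop("no features with covered CpGs")
  hh <- rbindlist(hits)
  # cap the right edge so rel == +flank folds into the last full bin
  hh[, rel_bin := pmin(floor(rel / binwidth),
                       ceiling(flank / binwidth) - 1) * binwidth + binwidth / 2]
  prof_rep <- hh[, .(level = sum(meth_count) / sum(total_count)),
                 by = .(cell_type, replicate, rel_bin)]
  profile <- prof_rep[, .(
    mean = mean(level),
    sem = if (.N > 1) sd(level) / sqrt(.N) else NA_real_),
    by = .(cell_type, rel_pos = rel_bin)]
  setorder(profile, cell_type, rel_pos)
  per_feature <- hh[abs(rel) <= window / 2,
                    .(level = sum(meth_count) / sum(total_count),
                      n_cpgs = sum(total_count > 0)),
                    by = .(feature_id, cell_type)]
  list(profile = profile, per_feature = per_feature,
       n_empty_features = n_empty)
}
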