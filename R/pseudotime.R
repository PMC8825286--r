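#' Smooth a feature along pseudotime with penalized cubic splines
#'
#' Fits a generalized additive model (cubic regression splines, REML
#' smoothing via [mgcv::gam()]) of the per-cell values against pseudotime,
#' evaluates it on a regular grid spanning the observed range and min-max
#' rescales the fitted curve to `[0, 1]`. Flat features are returned as
#' all-zeros with a degenerate flag.
#'
#' @param values Per-cell feature values.
#' @param pseudotime Per-cell pseudotime.
#' @param G Grid size.
#' @param k Spline basis dimension.
#' @param min_cells Minimum number of cells with nonzero signal; below this
#'   the feature is skipped (returns `NULL` with a warning).
#' @return A `smoothed_curve`: list with `grid`, `values` (rescaled fit),
#'   `argmax` (pseudotime of the global maximum, earliest on ties) and
#'   `degenerate`.
#' @export
smooth_along_pseudotime <- function(values, pseudotime, G = 100, k = 10,
                                    min_cells = 20) {
  stopifnot(length(values) == length(pseudotime), all(is.finite(pseudotime)))
  if (sum(values != 0, na.rm = TRUE) < min_cells) {
    warning("fewer than ", min_cells, " cells with signal; feature skipped")
    return(NULL)
  }
  grid <- seq(min(pseudotime), max(pseudotime), length.out = G)
  if (sd(values) < 1e-12) {
    out <- list(grid = grid, values = rep(0, G), argmax = NA_real_,
                degenerate = TRUE)
    class(out) <- "smoothed_curve"
    return(out)
  }
  df <- data.frame(y = values, t = pseudotime)
  fit <- mgcv::gam(y ~ s(t, k = k, bs = "cr"), data = df, method = "REML")
  yhat <- as.numeric(predict(fit, newdata = data.frame(t = grid)))
  rng <- range(yhat)
  degenerate <- diff(rng) < 1e-10
  vals <- if (degenerate) rep(0, G) else (yhat - rng[1]) / diff(rng)
  out <- list(grid = grid, values = vals,
              argmax = if (degenerate) NA_real_ else grid[which.max(vals)],
              degenerate = degenerate)
  class(out) <- "smoothed_curve"
  out
}

#' Pseudotime offset (dPD) between enhancer accessibility and gene expression
#'
#' dPD is the pseudotime of the accessibility curve's maximum minus the
#' pseudotime of the expression curve's maximum; negative values mean
#' accessibility precedes expression. Timing classes: `primed`
#' (dPD <= -tau), `delayed` (dPD >= tau), `immediate` otherwise.
#'
#' @param enh_curve,gene_curve [smooth_along_pseudotime()] results.
#' @param tau Classification threshold in pseudotime units.
#' @return List with `dpd` and `timing_class`.
#' @export
compute_dpd <- function(enh_curve, gene_curve, tau = 2) {
  if (is.null(enh_curve) || is.null(gene_curve) ||
      enh_curve$degenerate || gene_curve$degenerate) {
    stop("dPD undefined for degenerate or missing curves")
  }
  dpd <- enh_curve$argmax - gene_curve$argmax
  cls <- if (dpd <= -tau) "primed" else if (dpd >= tau) "delayed" else "immediate"
  list(dpd = dpd, timing_class = cls)
}

#' Correlation of TF expression and motif accessibility dynamics
#'
#' Pearson correlation of two smoothed curves over their (shared) grid;
#' degenerate curves yield `NA`.
#'
#' @param tf_curve,motif_curve [smooth_along_pseudotime()] results on a
#'   common grid.
#' @return Pearson r, or `NA` if either curve is degenerate.
#' @export
correlate_tf_dynamics <- function(tf_curve, motif_curve) {
  if (!isTRUE(all.equal(tf_curve$grid, motif_curve$grid))) {
    stop("curves must share a common grid")
  }
  if (tf_curve$degenerate || motif_curve$degenerate) return(NA_real_)
  cor(tf_curve$values, motif_curve$values)
}

#' Median dPD per cluster with a one-sided signed-rank test
#'
#' For each cluster of enhancer-gene pairs, reports the median dPD (M) and a
#' one-sample one-sided Wilcoxon signed-rank p-value for the alternative
#' that the median is negative (accessibility precedes expression).
#'
#' @param dpd Numeric dPD values.
#' @param clusters Cluster label per value.
#' @return data.table with `cluster`, `n`, `M`, `p`.
#' @export
median_dpd_per_cluster <- function(dpd, clusters) {
  stopifnot(length(dpd) == length(clusters))
  dt <- data.table(dpd = dpd, cluster = as.character(clusters))
  dt[, {
    if (.N == 0) stop("empty cluster")
    p <- if (all(dpd == 0)) 1 else
      suppressWarnings(wilcox.test(dpd, mu = 0, alternative = "less",
                                   exact = FALSE)$p.value)
    .(n = .N, M = median(dpd), p = p)
  }, by = cluster]
}
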