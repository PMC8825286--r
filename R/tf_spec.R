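#' Select motif-centered points from the most accessible peaks
#'
#' For each motif, the peaks containing it are ranked by their maximum
#' pseudobulk accessibility across clusters and the top `top_n` are kept as
#' motif-centered points. Motifs whose transcription factor is not expressed
#' (pseudobulk RPKM-like value at or below `rpkm_min`) or not in the
#' variable-gene set are dropped.
#'
#' @param motif_hits data.frame with `motif_id`, `peak_id`, `chrom`, `pos`
#'   (genomic motif position).
#' @param accessibility Named per-peak accessibility (max across clusters),
#'   or a peaks x clusters matrix with rownames (row maxima are used).
#' @param tf_info data.frame with `motif_id`, `rpkm`, `variable` (logical).
#' @param top_n Maximum points per motif.
#' @param rpkm_min Expression floor.
#' @return Named list of data.tables (`peak_id`, `chrom`, `pos`,
#'   `accessibility`) per retained motif; dropped motifs are recorded in the
#'   `dropped` attribute.
#' @export
select_motif_peaks <- function(motif_hits, accessibility, tf_info,
                               top_n = 5000, rpkm_min = 1) {
  hits <- as.data.table(motif_hits)
  stop_missing_column(hits, c("motif_id", "peak_id", "chrom", "pos"),
                      "motif hits")
  if (is.matrix(accessibility)) {
    accessibility <- setNames(apply(accessibility, 1, max),
                              rownames(accessibility))
  }
  tf_info <- as.data.table(tf_info)
  dropped <- character(0)
  out <- list()
  for (m in unique(hits$motif_id)) {
    info <- tf_info[motif_id == m]
    if (!nrow(info) || info$rpkm[1] <= rpkm_min || !isTRUE(info$variable[1])) {
      dropped <- c(dropped, m); next
    }
    sub <- hits[motif_id == m]
    if (!nrow(sub)) { dropped <- c(dropped, m); next }
    sub[, accessibility := accessibility[peak_id]]
    setorder(sub, -accessibility)
    out[[m]] <- sub[seq_len(min(top_n, nrow(sub))),
                    .(peak_id, chrom, pos, accessibility)]
  }
  attr(out, "dropped") <- dropped
  out
}

#' Build background point sets from the most accessible peaks
#'
#' Selects the `pool_size` most accessible peaks and samples `set_size` of
#' them, without replacement, `n_sets` times (seeded), as peak-center points.
#'
#' @param peak_points data.frame with `peak_id`, `chrom`, `pos` (center),
#'   `accessibility`.
#' @param n_sets Number of background sets.
#' @param set_size Points per set.
#' @param pool_size Accessibility pool size (shrunk with a warning when the
#'   peak universe is smaller).
#' @param seed Seed.
#' @return List with `pool` (data.table) and `sets` (n_sets x set_size
#'   integer matrix of pool row indices).
#' @export
build_background <- function(peak_points, n_sets = 1000, set_size = 5000,
                             pool_size = 50000, seed = 1L) {
  pts <- as.data.table(peak_points)
  stop_missing_column(pts, c("peak_id", "chrom", "pos", "accessibility"),
                      "peak points")
  if (pool_size > nrow(pts)) {
    warning("pool_size exceeds the number of peaks; using all peaks")
    pool_size <- nrow(pts)
  }
  if (set_size > pool_size) stop("set_size exceeds the background pool")
  setorder(pts, -accessibility)
  pool <- pts[seq_len(pool_size)]
  sets <- with_seed(child_seed(seed, "background_sets"), {
    t(vapply(seq_len(n_sets), function(j) sample.int(pool_size, set_size),
             integer(set_size)))
  })
  list(pool = pool, sets = sets)
}

# Sample up to n_pairs unordered point pairs that fall in the same TAD and
# are separated by at least min_sep. Enumerates when the pair universe is
# small, otherwise draws random pairs (seeded).
sample_point_pairs <- function(points, tads, min_sep = 10e3,
                               n_pairs = 20000, seed = 1L) {
  pts <- as.data.table(points)
  tads <- as.data.table(tads)
  tadvec <- rep(NA_real_, nrow(pts))
  for (cc in unique(pts$chrom)) {
    tsub <- tads[chrom == cc][order(start)]
    if (!nrow(tsub)) next
    ix <- which(pts$chrom == cc)
    ti <- findInterval(pts$pos[ix], tsub$start)
    inside <- ti >= 1 & pts$pos[ix] < tsub$end[pmax(ti, 1)]
    tadvec[ix[inside]] <- ti[inside] + 1e6 * match(cc, unique(pts$chrom))
  }
  pts[, tad := tadvec]
  pts <- pts[!is.na(tad)]
  grp <- split(seq_len(nrow(pts)), pts$tad)
  grp <- grp[vapply(grp, length, integer(1)) >= 2]
  if (!length(grp)) return(NULL)
  sizes <- vapply(grp, length, integer(1))
  total <- sum(sizes * (sizes - 1) / 2)
  with_seed(child_seed(seed, "point_pairs"), {
    if (total <= 3 * n_pairs) {
      pr <- rbindlist(lapply(grp, function(v) {
        cmb <- utils::combn(v, 2)
        data.table(i = cmb[1, ], j = cmb[2, ])
      }))
    } else {
      pr <- data.table(i = integer(0), j = integer(0))
      tries <- 0L
      while (nrow(pr) < n_pairs && tries < 20L) {
        m <- 3L * n_pairs
        g <- sample.int(length(grp), m, replace = TRUE,
                        prob = sizes * (sizes - 1))
        a <- floor(runif(m) * sizes[g]) + 1L
        b <- floor(runif(m) * sizes[g]) + 1L
        ok <- a != b
        ii <- mapply(function(gg, aa) grp[[gg]][aa], g[ok], pmin(a, b)[ok])
        jj <- mapply(function(gg, bb) grp[[gg]][bb], g[ok], pmax(a, b)[ok])
        pr <- unique(rbind(pr, data.table(i = ii, j = jj)))
        tries <- tries + 1L
      }
    }
    pr[, sep := abs(pts$pos[j] - pts$pos[i])]
    pr <- pr[sep >= min_sep]
    if (nrow(pr) > n_pairs) pr <- pr[sample.int(nrow(pr), n_pairs)]
    if (!nrow(pr)) return(NULL)
    data.table(chrom = pts$chrom[pr$i],
               x = pmin(pts$pos[pr$i], pts$pos[pr$j]),
               y = pmax(pts$pos[pr$i], pts$pos[pr$j]))
  })
}

# Median over pairs of the windowed maximum kNN score, per cell type, for a
# batch of point sets. `pair_list` is a named list of pair tables.
set_loop_medians <- function(pair_list, obs_sets, exp_sets, window, k, grid_n) {
  pair_list <- Filter(Negate(is.null), pair_list)
  if (!length(pair_list)) return(NULL)
  all_pairs <- rbindlist(pair_list, idcol = "set_id")
  offs <- seq(-window / 2, window / 2, length.out = grid_n)
  qg <- as.data.table(expand.grid(dx = offs, dy = offs))
  nq <- nrow(qg)
  q <- all_pairs[rep(seq_len(nrow(all_pairs)), each = nq)]
  q[, `:=`(qx = x + rep(qg$dx, nrow(all_pairs)),
           qy = y + rep(qg$dy, nrow(all_pairs)),
           pair_row = rep(seq_len(nrow(all_pairs)), each = nq))]
  med <- list()
  for (ct in names(obs_sets)) {
    sc <- knn_score(obs_sets[[ct]], exp_sets[[ct]],
                    data.table(chrom = q$chrom, x = q$qx, y = q$qy), k = k)
    q[, score := sc]
    pmax_dt <- q[, .(set_id = set_id[1],
                     m = if (all(is.na(score))) NA_real_ else
                       max(score, na.rm = TRUE)), by = pair_row]
    med[[ct]] <- pmax_dt[, .(med = median(m, na.rm = TRUE)), by = set_id]
  }
  out <- rbindlist(med, idcol = "cell_type")
  data.table::dcast(out, set_id ~ cell_type, value.var = "med")
}

#' TF-motif 3D looping strength and specificity with a permutation null
#'
#' For each motif point set, pairs of points at least `min_sep` apart within
#' the same TAD are formed (capped at `max_pairs`, seeded) and the maximum
#' kNN Hi-C score in a `window x window` square centered on each pair is
#' extracted per cell type; the per-cell-type statistic is the median over
#' pairs. The mean of the background-set medians is subtracted
#' (background-corrected). Reported per motif: the maximum corrected score
#' across cell types, the SD of the corrected scores across cell types
#' normalized by the mean background SD, and permutation p-values for both
#' statistics, `p = (1 + #{background >= observed}) / (1 + n_sets)`.
#'
#' @param motif_points Named list of motif point tables
#'   (from [select_motif_peaks()]).
#' @param background A [build_background()] result.
#' @param obs_sets,exp_sets Named per-cell-type contact tables (or
#'   `contact_set` objects).
#' @param tads data.frame with `chrom`, `start`, `end`.
#' @param min_sep Minimum pair separation (bp).
#' @param window Score window width (bp).
#' @param k Neighbours for the kNN score.
#' @param max_pairs Pair cap per motif.
#' @param bg_pairs Pair cap per background set.
#' @param min_pairs Minimum qualifying pairs; motifs below are skipped with
#'   a warning.
#' @param grid_n Query lattice points per axis within the window.
#' @param seed Seed.
#' @return data.table with one row per motif: per-cell-type corrected
#'   medians, `max_score`, `sd_norm`, `p_max`, `p_sd`, `n_pairs`.
#' @export
motif_loop_specificity <- function(motif_points, background, obs_sets,
                                   exp_sets, tads, min_sep = 10e3,
                                   window = 10e3, k = 100, max_pairs = 20000,
                                   bg_pairs = 200, min_pairs = 50,
                                   grid_n = 3, seed = 1L) {
  if (inherits(obs_sets, "contact_set")) obs_sets <- obs_sets$contacts
  if (inherits(exp_sets, "contact_set")) exp_sets <- exp_sets$contacts
  cts <- names(obs_sets)
  n_sets <- nrow(background$sets)
  bg_pair_list <- lapply(seq_len(n_sets), function(j) {
    sample_point_pairs(background$pool[background$sets[j, ]], tads, min_sep,
                       bg_pairs, seed = child_seed(seed, paste0("bg", j)))
  })
  names(bg_pair_list) <- paste0("bg", seq_len(n_sets))
  bg_med <- set_loop_medians(bg_pair_list, obs_sets, exp_sets, window, k, grid_n)
  if (is.null(bg_med)) stop("background sets yielded no qualifying pairs")
  bg_mat <- as.matrix(bg_med[, cts, with = FALSE])
  bg_mean <- colMeans(bg_mat, na.rm = TRUE)
  bg_corr <- sweep(bg_mat, 2, bg_mean)
  bg_max <- apply(bg_corr, 1, max, na.rm = TRUE)
  bg_sd <- apply(bg_corr, 1, sd, na.rm = TRUE)

  rows <- list()
  for (m in names(motif_points)) {
    prs <- sample_point_pairs(motif_points[[m]], tads, min_sep, max_pairs,
                              seed = child_seed(seed, paste0("motif_", m)))
    if (is.null(prs) || nrow(prs) < min_pairs) {
      warning("motif ", m, " has fewer than ", min_pairs,
              " qualifying pairs; skipped")
      next
    }
    md <- set_loop_medians(list(obs = prs), obs_sets, exp_sets, window, k, grid_n)
    obs_med <- as.numeric(md[1, cts, with = FALSE])
    corrected <- obs_med - bg_mean
    obs_max <- max(corrected, na.rm = TRUE)
    obs_sd <- sd(corrected, na.rm = TRUE)
    row <- data.table(motif_id = m, n_pairs = nrow(prs),
                      max_score = obs_max,
                      sd_norm = obs_sd / mean(bg_sd, na.rm = TRUE),
                      p_max = (1 + sum(bg_max >= obs_max, na.rm = TRUE)) / (1 + n_sets),
                      p_sd = (1 + sum(bg_sd >= obs_sd, na.rm = TRUE)) / (1 + n_sets))
    for (ct in cts) row[, (paste0("score_", ct)) := corrected[match(ct, cts)]]
    rows[[m]] <- row
  }
  if (!length(rows)) return(NULL)
  rbindlist(rows)
}

# Count-weighted mean methylation in windows centered on points, per cell
# type; returns per-point meth/total sums for cheap set-level aggregation.
point_meth_sums <- function(points, meth, window = 500) {
  pts <- as.data.table(points)
  meth <- as.data.table(meth)
  half <- window / 2
  out <- list()
  for (ct in unique(meth$cell_type)) {
    sub <- meth[cell_type == ct][order(chrom, pos)]
    msum <- numeric(nrow(pts)); tsum <- numeric(nrow(pts))
    for (cc in unique(pts$chrom)) {
      cp <- sub[chrom == cc]
      if (!nrow(cp)) next
      ix <- which(pts$chrom == cc)
      lo <- findInterval(pts$pos[ix] - half - 1, cp$pos) + 1L
      hi <- findInterval(pts$pos[ix] + half, cp$pos)
      cm <- c(0, cumsum(as.numeric(cp$meth_count)))
      ct2 <- c(0, cumsum(as.numeric(cp$total_count)))
      ok <- lo <= hi
      msum[ix[ok]] <- cm[hi[ok] + 1L] - cm[lo[ok]]
      tsum[ix[ok]] <- ct2[hi[ok] + 1L] - ct2[lo[ok]]
    }
    out[[ct]] <- data.table(meth = msum, total = tsum)
  }
  out
}

#' TF-motif DNA methylation level and specificity with a permutation null
#'
#' Extracts the count-weighted mean CpG methylation in `window`-bp windows
#' centered on the motif points, per cell type, and compares the minimum
#' across cell types (hypomethylation) and the SD across cell types
#' (cell-type specificity) to the background sets:
#' `p_min = (1 + #{background min <= observed}) / (1 + n_sets)` and
#' `p_sd = (1 + #{background sd >= observed}) / (1 + n_sets)`.
#'
#' @param motif_points Named list of motif point tables.
#' @param background A [build_background()] result.
#' @param meth A (coverage-filtered, replicate-pooled) methylation table.
#' @param window Window width (bp).
#' @param min_windows Minimum covered windows per motif.
#' @return data.table per motif with per-cell-type means, `min_meth`,
#'   `sd_meth`, `p_min`, `p_sd`, `n_covered`.
#' @export
motif_meth_specificity <- function(motif_points, background, meth,
                                   window = 500, min_windows = 100) {
  meth <- as.data.table(meth)
  cts <- unique(meth$cell_type)
  pool_sums <- point_meth_sums(background$pool, meth, window)
  n_sets <- nrow(background$sets)
  bg_stats <- t(vapply(seq_len(n_sets), function(j) {
    ix <- background$sets[j, ]
    lv <- vapply(cts, function(ct) {
      s <- pool_sums[[ct]][ix]
      sum(s$meth) / max(sum(s$total), 1)
    }, numeric(1))
    c(min = min(lv), sdv = sd(lv))
  }, numeric(2)))

  rows <- list()
  for (m in names(motif_points)) {
    ms <- point_meth_sums(motif_points[[m]], meth, window)
    covered <- Reduce(`+`, lapply(ms, function(s) s$total)) > 0
    if (sum(covered) < min_windows) {
      warning("motif ", m, " has fewer than ", min_windows,
              " covered windows; skipped")
      next
    }
    lv <- vapply(cts, function(ct) {
      sum(ms[[ct]]$meth) / max(sum(ms[[ct]]$total), 1)
    }, numeric(1))
    obs_min <- min(lv); obs_sd <- sd(lv)
    row <- data.table(motif_id = m, n_covered = sum(covered),
                      min_meth = obs_min, sd_meth = obs_sd,
                      p_min = (1 + sum(bg_stats[, "min"] <= obs_min)) / (1 + n_sets),
                      p_sd = (1 + sum(bg_stats[, "sdv"] >= obs_sd)) / (1 + n_sets))
    for (ct in cts) row[, (paste0("meth_", ct)) := lv[[ct]]]
    rows[[m]] <- row
  }
  if (!length(rows)) return(NULL)
  rbindlist(rows)
}
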