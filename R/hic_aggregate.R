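#' Average TAD contact enrichment grid
#'
#' Each TAD is extended upstream and downstream by its own length and the
#' resulting 3x-length span is split into `nbins` equal bins; observed and
#' expected contacts with both ends in the span are accumulated into the
#' bin-pair grid across TADs, and the enrichment is `log2(sum obs / sum
#' exp)` per bin pair (the TAD body occupies the central third). TADs whose
#' extended span leaves the chromosome are skipped and counted.
#'
#' @param contacts,expected Contact tables (`chrom`, `pos1`, `pos2`).
#' @param tads data.frame with `chrom`, `start`, `end`.
#' @param chrom_sizes Named chromosome lengths.
#' @param nbins Grid size.
#' @return `nbins x nbins` matrix of log2 enrichment (symmetric; NA where no
#'   expected contacts fell), with attribute `skipped`.
#' @export
aggregate_tad_enrichment <- function(contacts, expected, tads,
                                     chrom_sizes, nbins = 100) {
  tads <- as.data.table(tads)
  if (!nrow(tads)) stop("need at least one TAD")
  obs <- as.data.table(contacts)
  exp <- as.data.table(expected)
  gobs <- matrix(0, nbins, nbins)
  gexp <- matrix(0, nbins, nbins)
  skipped <- 0L
  accum <- function(dt, lo, width, grid) {
    sub <- dt[pos1 >= lo & pos2 < lo + width]
    if (!nrow(sub)) return(grid)
    b1 <- pmin(floor((sub$pos1 - lo) / width * nbins), nbins - 1) + 1L
    b2 <- pmin(floor((sub$pos2 - lo) / width * nbins), nbins - 1) + 1L
    tab <- data.table(i = b1, j = b2)[, .N, by = .(i, j)]
    grid[cbind(tab$i, tab$j)] <- grid[cbind(tab$i, tab$j)] + tab$N
    grid
  }
  for (t_i in seq_len(nrow(tads))) {
    len <- tads$end[t_i] - tads$start[t_i]
    lo <- tads$start[t_i] - len
    hi <- tads$end[t_i] + len
    cc <- tads$chrom[t_i]
    if (lo < 0 || hi > chrom_sizes[[cc]]) { skipped <- skipped + 1L; next }
    gobs <- accum(obs[chrom == cc], lo, 3 * len, gobs)
    gexp <- accum(exp[chrom == cc], lo, 3 * len, gexp)
  }
  gobs <- gobs + t(gobs) - diag(diag(gobs))
  gexp <- gexp + t(gexp) - diag(diag(gexp))
  grid <- log2(gobs / gexp)
  grid[!is.finite(grid)] <- NA_real_
  attr(grid, "skipped") <- skipped
  grid
}

#' Aggregate pair (APA) enrichment around anchor pairs
#'
#' For each anchor pair, contacts within a `window`-wide square centered on
#' the pair are binned into an `nbins x nbins` grid; observed and expected
#' counts are summed across pairs and the grid reports `log2(sum obs / sum
#' exp)` per bin. The summary ratio compares the mean of the central 3x3
#' block to the mean over the four 3x3 corner blocks, reported both as a
#' log2 difference and a linear ratio. Pairs whose window leaves the
#' chromosome are skipped and counted.
#'
#' @param contacts,expected Contact tables.
#' @param pairs data.frame with `chrom`, `x`, `y` anchor midpoints.
#' @param chrom_sizes Named chromosome lengths.
#' @param window Full window width (bp).
#' @param nbins Grid size (odd recommended).
#' @return List with `grid`, `center_log2` (mean log2 enrichment of the
#'   central 3x3 block), `corner_log2`, `log2_ratio`, `ratio` (linear),
#'   `n_pairs`, `skipped`.
#' @export
aggregate_pair_enrichment <- function(contacts, expected, pairs, chrom_sizes,
                                      window = 110e3, nbins = 33) {
  pairs <- as.data.table(pairs)
  if (!nrow(pairs)) stop("no anchor pairs supplied")
  obs <- as.data.table(contacts)
  exp <- as.data.table(expected)
  half <- window / 2
  gobs <- matrix(0, nbins, nbins)
  gexp <- matrix(0, nbins, nbins)
  used <- 0L; skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    cc <- pairs$chrom[i]
    x <- min(pairs$x[i], pairs$y[i]); y <- max(pairs$x[i], pairs$y[i])
    if (x - half < 0 || y + half > chrom_sizes[[cc]]) {
      skipped <- skipped + 1L; next
    }
    used <- used + 1L
    for (src in c("obs", "exp")) {
      dt <- if (src == "obs") obs else exp
      sub <- dt[chrom == cc & pos1 >= x - half & pos1 < x + half &
                  pos2 >= y - half & pos2 < y + half]
      if (!nrow(sub)) next
      b1 <- pmin(floor((sub$pos1 - (x - half)) / window * nbins), nbins - 1) + 1L
      b2 <- pmin(floor((sub$pos2 - (y - half)) / window * nbins), nbins - 1) + 1L
      tab <- data.table(i = b1, j = b2)[, .N, by = .(i, j)]
      if (src == "obs") {
        gobs[cbind(tab$i, tab$j)] <- gobs[cbind(tab$i, tab$j)] + tab$N
      } else {
        gexp[cbind(tab$i, tab$j)] <- gexp[cbind(tab$i, tab$j)] + tab$N
      }
    }
  }
  if (used == 0L) stop("no usable anchor pairs (all windows out of bounds)")
  grid <- log2(gobs / gexp)
  grid[!is.finite(grid)] <- NA_real_
  # block summaries pool counts before the ratio, which is far more stable
  # than averaging per-bin log ratios at list-level sparsity
  mid <- (nbins + 1) %/% 2
  blk <- function(g, ri, ci) sum(g[ri, ci])
  ctr_rows <- (mid - 1):(mid + 1)
  center <- log2(blk(gobs, ctr_rows, ctr_rows) /
                   max(blk(gexp, ctr_rows, ctr_rows), 1))
  corner_idx <- list(1:3, (nbins - 2):nbins)
  corners <- unlist(lapply(corner_idx, function(ri) {
    vapply(corner_idx, function(ci) {
      log2(max(blk(gobs, ri, ci), 0.5) / max(blk(gexp, ri, ci), 0.5))
    }, numeric(1))
  }))
  corner <- mean(corners)
  list(grid = grid, center_log2 = center, corner_log2 = corner,
       log2_ratio = center - corner, ratio = 2^(center - corner),
       n_pairs = used, skipped = skipped)
}

#' Per-pair kNN Hi-C scores in a window
#'
#' For each anchor pair and cell type, evaluates the kNN contact enrichment
#' score on a small lattice of query points spanning a `window`-wide square
#' centered on the pair and reports the maximum and mean. If `pairs` carries
#' a `group` column, two-sided Wilcoxon rank-sum tests comparing groups of
#' the per-pair maxima are attached per cell type.
#'
#' @param obs_sets,exp_sets Named lists (per cell type) of contact tables,
#'   or `contact_set` objects.
#' @param pairs data.frame with `chrom`, `x`, `y` (and optional `group`).
#' @param window Window width (bp).
#' @param k Neighbours for the score.
#' @param grid_n Lattice points per axis.
#' @return data.table with `pair_id`, `chrom`, `x`, `y`, `cell_type`,
#'   `score_max`, `score_mean` (NA when the score is undefined), and an
#'   attribute `tests` when groups were supplied.
#' @export
pair_scores <- function(obs_sets, exp_sets, pairs, window = 10e3, k = 100,
                        grid_n = 3) {
  if (inherits(obs_sets, "contact_set")) obs_sets <- obs_sets$contacts
  if (inherits(exp_sets, "contact_set")) exp_sets <- exp_sets$contacts
  pairs <- as.data.table(pairs)
  if (is.null(pairs$pair_id)) pairs[, pair_id := sprintf("pair_%04d", .I)]
  offs <- seq(-window / 2, window / 2, length.out = grid_n)
  qgrid <- as.data.table(expand.grid(dx = offs, dy = offs))
  out <- list()
  for (ct in names(obs_sets)) {
    q <- pairs[rep(seq_len(nrow(pairs)), each = nrow(qgrid))]
    q[, `:=`(qx = x + rep(qgrid$dx, nrow(pairs)),
             qy = y + rep(qgrid$dy, nrow(pairs)))]
    sc <- knn_score(obs_sets[[ct]], exp_sets[[ct]],
                    data.table(chrom = q$chrom, x = q$qx, y = q$qy), k = k)
    q[, score := sc]
    agg <- q[, .(score_max = if (all(is.na(score))) NA_real_ else
                   max(score, na.rm = TRUE),
                 score_mean = mean(score, na.rm = TRUE)),
             by = .(pair_id, chrom, x, y)]
    agg[, cell_type := ct]
    out[[ct]] <- agg
  }
  res <- rbindlist(out)
  if (!is.null(pairs$group)) {
    res <- merge(res, pairs[, .(pair_id, group)], by = "pair_id")
    gl <- unique(pairs$group)
    tests <- list()
    if (length(gl) == 2) {
      for (ct in names(obs_sets)) {
        a <- res[cell_type == ct & group == gl[1], score_max]
        b <- res[cell_type == ct & group == gl[2], score_max]
        tests[[ct]] <- suppressWarnings(
          wilcox.test(a, b, exact = FALSE)$p.value)
      }
    }
    setattr(res, "tests", tests)
  }
  res[]
}
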