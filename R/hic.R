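# Accept a contact_set (one cell type) or a plain data.table of contacts.
as_contacts <- function(x, cell_type = NULL) {
  if (inherits(x, "contact_set")) {
    ct <- cell_type %||% names(x$contacts)[1]
    return(x$contacts[[ct]])
  }
  as.data.table(x)
}

#' Filter Hi-C read pairs
#'
#' Removes pairs mapping to the same restriction fragment (when fragment ids
#' are present) or separated by less than `min_dist` bp.
#'
#' @param contacts data.table (`chrom`, `pos1`, `pos2`, optional `frag1`,
#'   `frag2`) or a `contact_set` (filtered per cell type).
#' @param min_dist Minimum separation (bp).
#' @return Filtered object with a `filter_report` attribute
#'   (kept / removed counts).
#' @export
filter_contacts <- function(contacts, min_dist = 1000) {
  filt <- function(dt) {
    drop <- (dt$pos2 - dt$pos1) < min_dist
    if (!is.null(dt$frag1) && !is.null(dt$frag2)) {
      drop <- drop | (dt$frag1 == dt$frag2)
    }
    list(kept = dt[!drop], removed = sum(drop))
  }
  if (inherits(contacts, "contact_set")) {
    rem <- 0L
    for (ct in names(contacts$contacts)) {
      f <- filt(contacts$contacts[[ct]])
      contacts$contacts[[ct]] <- f$kept
      rem <- rem + f$removed
    }
    attr(contacts, "filter_report") <-
      c(kept = sum(vapply(contacts$contacts, nrow, integer(1))), removed = rem)
    return(contacts)
  }
  f <- filt(as.data.table(contacts))
  out <- f$kept
  attr(out, "filter_report") <- c(kept = nrow(out), removed = f$removed)
  out
}

#' Contact probability as a function of genomic distance
#'
#' Distances are binned in log10 bins; counts are normalized to sum to one.
#'
#' @param contacts Contact data.table or `contact_set`.
#' @param bin_decades log10 bin width.
#' @param cell_type Cell type when a `contact_set` is given.
#' @return data.table with `log10_dist` (bin midpoint), `dist`, `prob`.
#' @export
contact_probability <- function(contacts, bin_decades = 0.1, cell_type = NULL) {
  dt <- as_contacts(contacts, cell_type)
  if (!nrow(dt)) stop("no contacts")
  d <- pmax(dt$pos2 - dt$pos1, 1)
  b <- floor(log10(d) / bin_decades)
  tab <- table(b)
  mids <- (as.numeric(names(tab)) + 0.5) * bin_decades
  data.table(log10_dist = mids, dist = 10^mids,
             prob = as.numeric(tab) / sum(tab))
}

#' Distance-decay-preserving expected contacts
#'
#' For each observed contact, emits one expected contact on the same
#' chromosome at exactly the same distance, with the position drawn uniformly
#' so that both ends stay within the chromosome. The distance multiset and
#' total count are preserved exactly, making the expected set a
#' distance-matched null for enrichment scoring.
#'
#' @param contacts Contact data.table or `contact_set`.
#' @param chrom_sizes Named chromosome lengths (taken from a `contact_set`
#'   automatically).
#' @param seed Seed.
#' @param cell_type Cell type when a `contact_set` is given.
#' @return Expected contacts in the same format as the input table.
#' @export
make_expected <- function(contacts, chrom_sizes = NULL, seed = 1L,
                          cell_type = NULL) {
  if (inherits(contacts, "contact_set") && is.null(chrom_sizes)) {
    chrom_sizes <- contacts$chrom_sizes
  }
  dt <- as_contacts(contacts, cell_type)
  if (is.null(chrom_sizes)) stop("chrom_sizes required")
  with_seed(seed, {
    out <- lapply(unique(dt$chrom), function(cc) {
      sub <- dt[chrom == cc]
      L <- chrom_sizes[[cc]]
      d <- sub$pos2 - sub$pos1
      x <- floor(runif(nrow(sub)) * (L - d))
      data.table(chrom = cc, pos1 = as.integer(x), pos2 = as.integer(x + d))
    })
    rbindlist(out)
  })
}

#' kNN Hi-C contact enrichment score
#'
#' For each query point q in the 2-D (pos1, pos2) plane, computes the
#' Chebyshev distance to the k-th nearest observed contact (r_obs) and to the
#' k-th nearest expected contact (r_exp), and scores local enrichment as
#' `100 * (r_exp^2 - r_obs^2) / (r_exp^2 + r_obs^2)`. Scores are bounded in
#' `[-100, 100]`; positive values mean the observed map is locally denser
#' than the distance-matched expectation; swapping observed and expected
#' negates the score exactly.
#'
#' @param contacts,expected Contact tables (`chrom`, `pos1`, `pos2`).
#' @param queries data.frame with `chrom`, `x`, `y` (orientation is
#'   normalized so x <= y).
#' @param k Number of neighbours.
#' @param cell Bucketing cell width (bp) of the grid index; affects speed
#'   only.
#' @return Numeric scores, `NA` where a chromosome holds fewer than `k`
#'   contacts in either set.
#' @export
knn_score <- function(contacts, expected, queries, k = 100, cell = 5000) {
  obs <- as.data.table(contacts)
  exp <- as.data.table(expected)
  q <- as.data.table(queries)
  stop_missing_column(q, c("chrom", "x", "y"), "queries")
  qx <- pmin(q$x, q$y); qy <- pmax(q$x, q$y)
  out <- rep(NA_real_, nrow(q))
  for (cc in unique(q$chrom)) {
    qi <- which(q$chrom == cc)
    o <- obs[chrom == cc]; e <- exp[chrom == cc]
    if (nrow(o) < k || nrow(e) < k) next
    ro <- knn_chebyshev_radius(as.numeric(o$pos1), as.numeric(o$pos2),
                               qx[qi], qy[qi], as.integer(k), cell)
    re <- knn_chebyshev_radius(as.numeric(e$pos1), as.numeric(e$pos2),
                               qx[qi], qy[qi], as.integer(k), cell)
    denom <- re^2 + ro^2
    s <- ifelse(denom == 0, 0, 100 * (re^2 - ro^2) / denom)
    out[qi] <- s
  }
  out
}

#' Insulation score track
#'
#' For each 1-kb bin i, the raw insulation value is the mean contact count
#' over the `w x w` pixel rectangle bridging the bin (upstream window
#' `[i-w, i)` times downstream `(i, i+w]`). The normalized value is
#' `n(i) = log2(raw(i) / genome-wide mean raw)` and the reported score is
#' `s(i) = -n(i)`, so that high scores mark strong insulation. Bins whose
#' window does not fit inside the chromosome are not reported; zero-count
#' windows yield `NA`.
#'
#' @param contacts Contact table or `contact_set`.
#' @param chrom_sizes Named chromosome lengths.
#' @param window Window half-width (bp).
#' @param res Bin resolution (bp).
#' @param cell_type Cell type when a `contact_set` is given.
#' @return `insulation_track`: data.table with `chrom`, `start`, `raw`,
#'   `n`, `score`.
#' @export
insulation <- function(contacts, chrom_sizes = NULL, window = 250e3,
                       res = 1000, cell_type = NULL) {
  if (inherits(contacts, "contact_set") && is.null(chrom_sizes)) {
    chrom_sizes <- contacts$chrom_sizes
  }
  dt <- as_contacts(contacts, cell_type)
  if (is.null(chrom_sizes)) stop("chrom_sizes required")
  w <- as.integer(window / res)
  parts <- lapply(unique(dt$chrom), function(cc) {
    sub <- dt[chrom == cc]
    nb <- floor(chrom_sizes[[cc]] / res)
    if (nb < 2 * w + 1) stop("chromosome shorter than twice the window")
    b1 <- pmin(sub$pos1 %/% res, nb - 1L)
    b2 <- pmin(sub$pos2 %/% res, nb - 1L)
    # contact (b1, b2) bridges bin i when b1 in [i-w, i-1] and b2 in [i+1, i+w]
    lo <- pmax(b1 + 1L, b2 - w)
    hi <- pmin(b1 + w, b2 - 1L)
    ok <- lo <= hi
    diffarr <- numeric(nb + 2L)
    if (any(ok)) {
      addl <- tabulate(lo[ok] + 1L, nbins = nb + 2L)
      addh <- tabulate(hi[ok] + 2L, nbins = nb + 2L)
      diffarr <- addl - addh
    }
    counts <- cumsum(diffarr)[seq_len(nb)]  # counts[i+1] = bridge count of bin i
    valid <- seq.int(w, nb - w - 1L)
    data.table(chrom = cc, start = valid * res, raw = counts[valid + 1L] / w^2)
  })
  track <- rbindlist(parts)
  gw_mean <- mean(track$raw)
  track[, n := ifelse(raw > 0, log2(raw / gw_mean), NA_real_)]
  track[, score := -n]
  setattr(track, "class", c("insulation_track", class(track)))
  setattr(track, "res", res)
  track[]
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries are bins whose insulation score is a local maximum within
#' `+/- local_bp` (strictly greater than bins to the left, at least as great
#' as bins to the right, so ties report the leftmost bin) and above the
#' genome-wide `quantile` of the score distribution.
#'
#' @param track An [insulation()] result.
#' @param quantile Genome-wide score quantile threshold.
#' @param local_bp Local-maximum half-window (bp).
#' @return data.table with `chrom`, `pos` (bin start), `score`.
#' @export
call_boundaries <- function(track, quantile = 0.9, local_bp = 2000) {
  res <- attr(track, "res") %||% 1000
  wb <- as.integer(local_bp / res)
  thr <- stats::quantile(track$score, quantile, na.rm = TRUE, names = FALSE)
  parts <- lapply(unique(track$chrom), function(cc) {
    sub <- track[chrom == cc][order(start)]
    s <- sub$score
    nvals <- length(s)
    is_b <- rep(FALSE, nvals)
    for (i in seq_len(nvals)) {
      if (is.na(s[i]) || s[i] <= thr) next
      lft <- s[max(1, i - wb):max(1, i - 1)]
      rgt <- s[min(nvals, i + 1):min(nvals, i + wb)]
      if (i > 1 && any(lft >= s[i], na.rm = TRUE)) next
      if (i < nvals && any(rgt > s[i], na.rm = TRUE)) next
      is_b[i] <- TRUE
    }
    sub[is_b, .(chrom, pos = start, score)]
  })
  rbindlist(parts)
}

#' Differential TAD boundaries across cell types
#'
#' Insulation scores are z-normalized genome-wide per cell type; a boundary
#' is differential when the largest pairwise difference of its z-scores
#' across cell types exceeds `dz_threshold`. Differential boundaries are
#' clustered on their z-score profiles with seeded k-means.
#'
#' @param tracks Named list of [insulation()] tracks, one per cell type.
#' @param boundaries data.frame with `chrom`, `pos` (e.g. the union of
#'   per-cell-type [call_boundaries()] calls).
#' @param dz_threshold Pairwise z-difference threshold.
#' @param kclusters k for k-means on the differential set.
#' @param seed Seed for k-means.
#' @return data.table with `chrom`, `pos`, one `z_<cell type>` column per
#'   track, `dz` (max pairwise difference), `differential` and `cluster`
#'   (NA for non-differential boundaries).
#' @export
differential_boundaries <- function(tracks, boundaries, dz_threshold = 1,
                                    kclusters = 3, seed = 1L) {
  if (length(tracks) < 2) stop("need at least two cell types")
  b <- as.data.table(boundaries)
  zmat <- vapply(names(tracks), function(ct) {
    tr <- tracks[[ct]]
    z <- (tr$score - mean(tr$score, na.rm = TRUE)) / sd(tr$score, na.rm = TRUE)
    vapply(seq_len(nrow(b)), function(i) {
      ix <- which(tr$chrom == b$chrom[i])
      if (!length(ix)) return(NA_real_)
      z[ix[which.min(abs(tr$start[ix] - b$pos[i]))]]
    }, numeric(1))
  }, numeric(nrow(b)))
  if (nrow(b) == 1L) zmat <- matrix(zmat, nrow = 1, dimnames = list(NULL, names(tracks)))
  dz <- apply(zmat, 1, function(z) diff(range(z, na.rm = TRUE)))
  out <- cbind(b[, .(chrom, pos)], as.data.table(zmat))
  setnames(out, names(tracks), paste0("z_", names(tracks)))
  out[, dz := dz]
  out[, differential := dz > dz_threshold]
  out[, cluster := NA_integer_]
  ndiff <- sum(out$differential)
  if (ndiff > 0) {
    if (kclusters > ndiff) stop("kclusters exceeds the number of differential boundaries")
    km <- with_seed(child_seed(seed, "kmeans_boundaries"),
                    kmeans(zmat[out$differential, , drop = FALSE],
                           centers = kclusters, nstart = 10))
    out[differential == TRUE, cluster := km$cluster]
  }
  out[]
}
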