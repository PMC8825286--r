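# Distance from each peak center to the nearest TSS (same chromosome);
# peaks on chromosomes without genes get Inf.
nearest_tss_distance <- function(peaks, genes) {
  peaks <- as.data.table(peaks)
  genes <- as.data.table(genes)
  center <- (peaks$start + peaks$end) / 2
  out <- rep(Inf, nrow(peaks))
  for (cc in unique(peaks$chrom)) {
    tss <- sort(genes[chrom == cc, tss])
    if (!length(tss)) next
    ix <- which(peaks$chrom == cc)
    i <- findInterval(center[ix], tss)
    lo <- ifelse(i >= 1, abs(center[ix] - tss[pmax(i, 1)]), Inf)
    hi <- ifelse(i < length(tss), abs(tss[pmin(i + 1L, length(tss))] - center[ix]), Inf)
    out[ix] <- pmin(lo, hi)
  }
  out
}

#' Classify peaks as promoter-associated, distal or neither
#'
#' A peak is promoter-associated when its center lies within `promoter_bp`
#' of a TSS, distal when it is more than `distal_bp` away from every
#' annotated TSS, and neither otherwise.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genes data.frame with `chrom`, `tss`.
#' @param promoter_bp,distal_bp Distance thresholds (bp).
#' @return Character vector in `{"promoter", "distal", "neither"}`.
#' @export
classify_peak_location <- function(peaks, genes, promoter_bp = 500,
                                   distal_bp = 5000) {
  if (!nrow(as.data.table(genes))) stop("TSS table is empty")
  d <- nearest_tss_distance(peaks, genes)
  ifelse(d < promoter_bp, "promoter", ifelse(d > distal_bp, "distal", "neither"))
}

#' Link distal peaks to genes by metacell correlation with a trans-based null
#'
#' Candidate pairs are distal peaks (center more than `distal_bp` from every
#' TSS) matched to genes with TSS within `max_dist` on the same chromosome.
#' The Pearson correlation of log-normalized metacell accessibility and
#' expression is compared to a pooled genome-wide null built from
#' correlations of each tested gene against `n_null` peaks sampled from
#' other chromosomes. Two-sided empirical p-values use add-one smoothing and
#' are BH-adjusted. Classes: `posCor` (r >= `r_min`, q <= `fdr`), `negCor`
#' (r <= -`r_min`, q <= `fdr`), `control` (|r| < `r_min`, q > `fdr`;
#' subsampled without replacement to the number of posCor pairs with a fixed
#' seed), `unclassified` otherwise.
#'
#' @param groups A [group_metacells()] result carrying both `rna` and `atac`.
#' @param peaks,genes Feature annotation tables (`peak_id`/`gene_id` columns
#'   matching the matrix colnames).
#' @param r_min Correlation threshold.
#' @param fdr BH FDR threshold.
#' @param max_dist Maximum peak-center-to-TSS distance (bp).
#' @param distal_bp Minimum distance to any TSS for a peak to be tested.
#' @param n_null Trans-null peaks sampled per tested gene.
#' @param seed Seed for the null sampling and control subsampling.
#' @return `egp_table`: data.table with `peak_id`, `gene_id`, `distance`
#'   (signed, peak center minus TSS), `r`, `p_emp`, `q`, `class`; parameters
#'   and seed are attached as attributes.
#' @export
link_peaks_to_genes <- function(groups, peaks, genes, r_min = 0.35,
                                fdr = 0.1, max_dist = 500e3, distal_bp = 5000,
                                n_null = 100, seed = 1L) {
  if (is.null(groups$rna) || is.null(groups$atac)) {
    stop("metacell groups must carry both rna and atac aggregates")
  }
  peaks <- as.data.table(peaks)
  genes <- as.data.table(genes)
  stop_missing_column(peaks, c("peak_id", "chrom", "start", "end"), "peaks")
  stop_missing_column(genes, c("gene_id", "chrom", "tss"), "genes")

  loc <- classify_peak_location(peaks, genes, distal_bp = distal_bp)
  distal <- peaks[loc == "distal"]
  distal[, center := (start + end) / 2]
  cand <- rbindlist(lapply(unique(distal$chrom), function(cc) {
    p <- distal[chrom == cc]
    g <- genes[chrom == cc]
    if (!nrow(p) || !nrow(g)) return(NULL)
    cj <- p[, .(peak_id, center, k = 1)][g[, .(gene_id, tss, k = 1)],
                                         on = "k", allow.cartesian = TRUE]
    cj <- cj[abs(center - tss) <= max_dist]
    cj[, .(peak_id, gene_id, distance = center - tss)]
  }))
  if (is.null(cand) || !nrow(cand)) stop("no candidate peak-gene pairs")

  za <- standardize_cols(groups$atac)
  zr <- standardize_cols(groups$rna)
  n <- nrow(za)
  pi <- match(cand$peak_id, colnames(za))
  gi <- match(cand$gene_id, colnames(zr))
  if (anyNA(pi) || anyNA(gi)) stop("annotation ids not found in group matrices")
  cand[, r := colSums(za[, pi, drop = FALSE] * zr[, gi, drop = FALSE]) / n]

  # pooled trans null: each tested gene against peaks on other chromosomes
  null_r <- with_seed(child_seed(seed, "transnull"), {
    genes_tested <- unique(cand$gene_id)
    peak_chrom <- setNames(peaks$chrom, peaks$peak_id)
    all_peaks <- colnames(za)
    unlist(lapply(genes_tested, function(gid) {
      gc <- genes[gene_id == gid, chrom][1]
      pool <- all_peaks[peak_chrom[all_peaks] != gc]
      if (!length(pool)) return(numeric(0))
      sel <- sample(pool, min(n_null, length(pool)))
      colSums(za[, sel, drop = FALSE] * zr[, gid]) / n
    }))
  })
  if (!length(null_r)) stop("trans null is empty; need more than one chromosome")
  abs_null <- sort(abs(null_r))
  n_ge <- length(abs_null) - findInterval(abs(cand$r) - 1e-12, abs_null)
  cand[, p_emp := (1 + n_ge) / (1 + length(abs_null))]
  cand[, q := p.adjust(p_emp, method = "BH")]
  cand[, class := "unclassified"]
  cand[r >= r_min & q <= fdr, class := "posCor"]
  cand[r <= -r_min & q <= fdr, class := "negCor"]
  ctrl_pool <- cand[, which(abs(r) < r_min & q > fdr)]
  n_pos <- cand[, sum(class == "posCor")]
  ctrl <- with_seed(child_seed(seed, "controls"), {
    if (length(ctrl_pool) <= n_pos) {
      if (length(ctrl_pool) < n_pos) {
        warning("fewer eligible control pairs than posCor pairs; keeping all")
      }
      ctrl_pool
    } else sample(ctrl_pool, n_pos)
  })
  cand[ctrl, class := "control"]
  setattr(cand, "params", list(r_min = r_min, fdr = fdr, max_dist = max_dist,
                               distal_bp = distal_bp, n_null = n_null,
                               seed = seed, n_null_total = length(abs_null)))
  setattr(cand, "class", c("egp_table", class(cand)))
  cand[]
}

#' Pseudobulk counts per cluster and replicate
#'
#' Sums counts over cells per (cluster, replicate) sample. Clusters with
#' fewer than `min_cells` cells are split into two seeded pseudoreplicates by
#' random halving instead of using the recorded replicates.
#'
#' @param counts cells x features count matrix.
#' @param cluster,replicate Per-cell labels.
#' @param min_cells Minimum cluster size for using real replicates.
#' @param seed Seed for pseudoreplicate halving.
#' @return List with `counts` (features x samples) and `samples`
#'   (data.table `sample`, `cluster`, `replicate`).
#' @export
pseudobulk_counts <- function(counts, cluster, replicate, min_cells = 100,
                              seed = 1L) {
  cluster <- as.character(cluster)
  cols <- list(); meta <- list()
  for (cl in unique(cluster)) {
    ix <- which(cluster == cl)
    reps <- if (length(ix) < min_cells) {
      with_seed(child_seed(seed, paste0("pseudorep_", cl)), {
        half <- sample(ix, floor(length(ix) / 2))
        list(`1` = half, `2` = setdiff(ix, half))
      })
    } else split(ix, replicate[ix])
    if (length(reps) < 2) stop(sprintf(
      "cluster %s has a single replicate; enable pseudoreplication", cl))
    for (rp in names(reps)) {
      sm <- paste0(cl, "_rep", rp)
      cols[[sm]] <- colSums(counts[reps[[rp]], , drop = FALSE])
      meta[[sm]] <- data.table(sample = sm, cluster = cl, replicate = rp)
    }
  }
  list(counts = do.call(cbind, cols), samples = rbindlist(meta))
}

#' Call cluster-specific peaks by pseudobulk feature binarization
#'
#' For each peak the cluster with the highest mean log2 CPM is tested against
#' the next-highest cluster with a two-sided pooled-variance t-test on
#' replicate values; a peak is specific to its top cluster when the
#' BH-adjusted p-value is below `p_adj` and the log2 fold change to the next
#' cluster is at least `lfc_min`.
#'
#' @param pseudobulk A [pseudobulk_counts()] result.
#' @param p_adj Adjusted p-value threshold.
#' @param lfc_min Minimum log2 fold change to the next-highest cluster.
#' @return data.table with `peak_id`, `cluster` (top), `lfc`, `t`, `p`, `q`,
#'   `specific`.
#' @export
call_cluster_specific_peaks <- function(pseudobulk, p_adj = 0.01,
                                        lfc_min = 0.25) {
  cnt <- pseudobulk$counts
  meta <- pseudobulk$samples
  cpm <- log2(1 + t(t(cnt) / pmax(colSums(cnt), 1) * 1e6))
  clusters <- unique(meta$cluster)
  if (length(clusters) < 2) stop("need at least two clusters")
  cl_cols <- lapply(clusters, function(cl) which(meta$cluster == cl))
  names(cl_cols) <- clusters
  res <- lapply(seq_len(nrow(cpm)), function(i) {
    mns <- vapply(cl_cols, function(ix) mean(cpm[i, ix]), numeric(1))
    ord <- order(mns, decreasing = TRUE)
    top <- clusters[ord[1]]; nxt <- clusters[ord[2]]
    x <- cpm[i, cl_cols[[top]]]; y <- cpm[i, cl_cols[[nxt]]]
    lfc <- mean(x) - mean(y)
    tt <- tryCatch(t.test(x, y, var.equal = TRUE),
                   error = function(e) list(statistic = NA, p.value = 1))
    data.table(peak_id = rownames(cpm)[i], cluster = top, lfc = lfc,
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- rbindlist(res)
  out[, q := p.adjust(p, method = "BH")]
  out[, specific := q < p_adj & lfc >= lfc_min]
  out[specific == FALSE, cluster := NA_character_]
  out[]
}

#' Assign cluster calls to positively correlated enhancer-gene pairs
#'
#' Each posCor pair inherits the cluster-specific call of its peak; pairs
#' whose peak has no call get cluster `"none"`.
#'
#' @param egps An [link_peaks_to_genes()] table.
#' @param calls A [call_cluster_specific_peaks()] table.
#' @return The EGP table with a `cluster` column added.
#' @export
assign_egp_clusters <- function(egps, calls) {
  calls <- as.data.table(calls)
  map <- setNames(calls$cluster, calls$peak_id)
  egps <- as.data.table(egps)
  egps[, cluster := NA_character_]
  egps[class == "posCor",
       cluster := ifelse(is.na(map[peak_id]), "none", map[peak_id])]
  egps[]
}
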