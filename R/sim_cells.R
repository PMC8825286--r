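# Gaussian expression/accessibility program along pseudotime.
bump <- function(t, center, width) exp(-((t - center)^2) / (2 * width^2))

#' Simulate paired single-cell RNA and ATAC counts along a trajectory
#'
#' Generates a `cell_data` object emulating matched scRNA/scATAC profiling of
#' a one-dimensional differentiation trajectory embedded in a richer latent
#' cell state: each cell carries a pseudotime plus `n_latent` orthogonal
#' state factors (cell-to-cell biological variation not aligned with the
#' trajectory). Every dynamic feature mixes a Gaussian pseudotime program
#' with a random loading on the state factors, so that unrelated features
#' decorrelate the way they do in high-dimensional real data.
#'
#' Planted positively correlated (posCor) pairs share the gene's full
#' program, with the pseudotime component shifted by the planted timing
#' offset (negative = accessibility precedes expression); negCor pairs
#' invert it; null pairs get independent programs drawn from the same
#' population as all other (untargeted) peaks, which keeps the trans-null
#' calibrated. Counts are negative binomial around the program means.
#'
#' @param config A [sim_config()].
#' @param noise If `FALSE`, the latent program means are returned in place
#'   of sampled counts (useful for noise-free checks).
#' @return A list of class `cell_data` with elements `rna` (cells x genes),
#'   `atac` (cells x peaks), `reduced` (cells x (1 + n_latent) latent
#'   coordinates, the input for metacell grouping), `cell_meta`, `genes`,
#'   `peaks`, and a `ground_truth` attribute with one row per planted pair
#'   (`egp_id`, `gene_id`, `peak_id`, `class`, `timing_class`, `offset`,
#'   `gene_peak_time`, `peak_width`).
#' @export
simulate_cells <- function(config, noise = TRUE) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, "cells"), {
    n_types <- length(config$cell_types)
    n_cells <- config$n_cells_per_type * n_types
    scale <- config$pseudotime_scale
    q <- config$n_latent
    pt <- sort(runif(n_cells, 0, scale))
    type_idx <- pmin(floor(pt / (scale / n_types)) + 1L, n_types)
    u <- matrix(rnorm(n_cells * q), n_cells, q)
    cell_meta <- data.table(
      cell_id = sprintf("cell_%04d", seq_len(n_cells)),
      cluster = config$cell_types[type_idx],
      pseudotime = pt,
      replicate = sample(rep(1:2, length.out = n_cells)))

    n_pairs <- config$n_egp_pos + config$n_egp_neg + config$n_egp_null
    if (n_pairs > min(config$n_genes, config$n_peaks)) {
      stop("planted pairs exceed the number of genes or peaks")
    }
    width <- 0.15 * scale
    classes <- rep(c("posCor", "negCor", "null"),
                   c(config$n_egp_pos, config$n_egp_neg, config$n_egp_null))
    timing <- rep(NA_character_, n_pairs)
    timing[classes == "posCor"] <-
      rep(names(config$timing_offsets), length.out = config$n_egp_pos)
    offset <- ifelse(is.na(timing), 0, config$timing_offsets[timing])

    # a feature program mixes a pseudotime bump (weight wt) with a squashed
    # random projection of the state factors (weight 1 - wt)
    state_part <- function(z) pnorm(as.vector(u %*% z) / sqrt(sum(z^2)))
    feature_program <- function(center, wt, z, t_off = 0) {
      wt * bump(pt - t_off, center, width) + (1 - wt) * state_part(z)
    }

    # gene programs: planted pos/neg genes are balanced (wt = 0.5) with
    # posCor centers kept interior so shifted accessibility maxima stay
    # inside the observed range; other genes are drawn from the population
    gene_center <- runif(config$n_genes, 0.10 * scale, 0.90 * scale)
    gene_center[which(classes == "posCor")] <-
      runif(config$n_egp_pos, 0.40 * scale, 0.65 * scale)
    # most features are only weakly trajectory-driven (as in real tissue,
    # where few genes are strongly stage-specific); planted pairs carry a
    # defined trajectory share
    wt_planted <- 0.35
    gene_wt <- runif(config$n_genes, 0, 0.4)
    gene_wt[seq_len(n_pairs)][classes %in% c("posCor", "negCor")] <- wt_planted
    gene_z <- matrix(rnorm(config$n_genes * q), q, config$n_genes)
    gene_prog <- vapply(seq_len(config$n_genes), function(j) {
      feature_program(gene_center[j], gene_wt[j], gene_z[, j])
    }, numeric(n_cells))

    # peak programs: posCor = shared gene program with shifted bump;
    # negCor = inverted; null pairs and extra peaks are independent draws
    # from one peak population
    r <- config$effect_r
    peak_prog <- matrix(0, n_cells, config$n_peaks)
    peak_center <- runif(config$n_peaks, 0.10 * scale, 0.90 * scale)
    peak_wt <- runif(config$n_peaks, 0, 0.4)
    peak_z <- matrix(rnorm(config$n_peaks * q), q, config$n_peaks)
    for (j in seq_len(config$n_peaks)) {
      indep <- feature_program(peak_center[j], peak_wt[j], peak_z[, j])
      if (j <= n_pairs && classes[j] == "posCor") {
        shared <- feature_program(gene_center[j], wt_planted, gene_z[, j],
                                  t_off = offset[j])
        peak_prog[, j] <- r * shared + (1 - r) * indep
      } else if (j <= n_pairs && classes[j] == "negCor") {
        peak_prog[, j] <- r * (1 - gene_prog[, j]) + (1 - r) * indep
      } else {
        peak_prog[, j] <- indep
      }
    }

    lib <- exp(rnorm(n_cells, 0, 0.2))
    amp_rna <- 8; amp_atac <- 8; base <- 0.2
    mu_rna <- lib * (amp_rna * gene_prog + base)
    mu_atac <- lib * (amp_atac * peak_prog + base)
    draw <- function(mu) {
      if (!noise) return(mu)
      matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$dispersion),
             nrow(mu), ncol(mu))
    }
    rna <- draw(mu_rna)
    atac <- draw(mu_atac)
    colnames(rna) <- sprintf("gene_%04d", seq_len(config$n_genes))
    colnames(atac) <- sprintf("peak_%04d", seq_len(config$n_peaks))
    rownames(rna) <- rownames(atac) <- cell_meta$cell_id

    ann <- place_features(config, n_pairs)
    # QC metadata planted inside the retention windows of the QC filters;
    # edge-case behaviour of the filters is tested on constructed tables
    cell_meta[, `:=`(
      n_genes = round(runif(n_cells, 1500, 6000)),
      n_umis = round(runif(n_cells, 3000, 20000)),
      pct_mito = runif(n_cells, 0, 8),
      n_fragments = round(runif(n_cells, 15000, 90000)),
      tss_enrichment = runif(n_cells, 9, 20))]

    gt <- data.table(
      egp_id = sprintf("egp_%04d", seq_len(n_pairs)),
      gene_id = colnames(rna)[seq_len(n_pairs)],
      peak_id = colnames(atac)[seq_len(n_pairs)],
      class = classes,
      timing_class = timing,
      offset = offset,
      gene_peak_time = gene_center[seq_len(n_pairs)],
      peak_width = width)

    reduced <- cbind(t_sc = as.vector(scale(pt)), u)
    colnames(reduced) <- c("t_sc", paste0("u", seq_len(q)))
    out <- list(rna = rna, atac = atac, reduced = reduced,
                cell_meta = cell_meta, genes = ann$genes, peaks = ann$peaks)
    class(out) <- "cell_data"
    attr(out, "ground_truth") <- gt
    out
  })
}

# Lay genes and peaks onto the genome. Pair anchors are spaced so that each
# gene's only candidate peak within the 500-kb linkage window is its own
# (10-100 kb away, hence distal); unpaired peaks fill gap midpoints, where
# they are distal to every TSS but within linkage range of the flanking
# genes (genuine null candidates).
place_features <- function(config, n_pairs) {
  g <- config$genome
  n_chrom <- nrow(g)
  chrom_of <- function(i) ((i - 1L) %% n_chrom) + 1L
  pair_chr <- chrom_of(seq_len(config$n_genes))
  anchor <- numeric(config$n_genes)
  for (cc in seq_len(n_chrom)) {
    idx <- which(pair_chr == cc)
    margin <- 2e6
    anchor[idx] <- round(seq(margin, g$length[cc] - margin,
                             length.out = max(length(idx), 2))[seq_along(idx)])
  }
  genes <- data.table(
    gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
    chrom = g$chrom[pair_chr],
    tss = anchor,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE))

  peak_chr <- integer(config$n_peaks)
  peak_center <- numeric(config$n_peaks)
  m <- min(n_pairs, config$n_peaks)
  d <- sample(c(-1, 1), m, TRUE) * round(runif(m, 10e3, 100e3))
  peak_chr[seq_len(m)] <- pair_chr[seq_len(m)]
  peak_center[seq_len(m)] <- anchor[seq_len(m)] + d
  if (config$n_peaks > m) {
    extra <- seq(m + 1L, config$n_peaks)
    # midpoint between a gene anchor and the next anchor on the same chrom
    host <- sample(seq_len(max(config$n_genes - n_chrom, 1L)), length(extra),
                   replace = TRUE)
    nxt <- pmin(host + n_chrom, config$n_genes)
    peak_chr[extra] <- pair_chr[host]
    peak_center[extra] <- round((anchor[host] + anchor[nxt]) / 2 +
                                  runif(length(extra), -50e3, 50e3))
  }
  peaks <- data.table(
    peak_id = sprintf("peak_%04d", seq_len(config$n_peaks)),
    chrom = g$chrom[peak_chr],
    start = round(peak_center) - 250L,
    end = round(peak_center) + 250L)
  list(genes = genes, peaks = peaks)
}

#' @export
print.cell_data <- function(x, ...) {
  cat("<cell_data>", nrow(x$rna), "cells |", ncol(x$rna), "genes |",
      ncol(x$atac), "peaks |",
      length(unique(x$cell_meta$cluster)), "cell types\n")
  invisible(x)
}

#' Planted ground truth of a simulated object
#'
#' @param x An object produced by one of the `simulate_*` generators.
#' @return The ground-truth table (or list) recorded at generation time.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")
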