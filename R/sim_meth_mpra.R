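#' Simulate per-cell-type CpG methylation tables with spike-in controls
#'
#' CpG sites are scattered over the genome; methylated counts are binomial
#' around `config$meth_baseline`, except at CpGs falling inside a planted
#' active enhancer, which are hypomethylated to `config$meth_enh_level` in the
#' matching cell type only. Two spike-in contigs emulate bisulfite controls:
#' an unmethylated contig whose apparent methylation equals the conversion
#' error, and a fully methylated contig read at the detection rate.
#'
#' @param config A [sim_config()].
#' @param enhancers Optional data.frame (`chrom`, `pos`, `cell_type`) of
#'   planted active enhancer centers.
#' @param n_cpgs Genomic CpG sites to simulate.
#' @param coverage Mean total coverage per CpG and replicate (Poisson).
#' @param enh_halfwidth Half-width (bp) of the hypomethylated window.
#' @param replicates Replicates per cell type.
#' @param n_spike_cpgs CpGs on each spike-in contig.
#' @return A data.table of class `methyl_table` (`chrom`, `pos`, `meth_count`,
#'   `total_count`, `cell_type`, `replicate`, `spike_in`), with the planted
#'   enhancer table as `ground_truth` attribute.
#' @export
simulate_methylation <- function(config, enhancers = NULL, n_cpgs = 20000,
                                 coverage = 50, enh_halfwidth = 250,
                                 replicates = 2, n_spike_cpgs = c(500, 100)) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, "meth"), {
    g <- config$genome
    chr <- sample(seq_len(nrow(g)), n_cpgs, replace = TRUE,
                  prob = g$length / sum(g$length))
    pos <- floor(runif(n_cpgs) * g$length[chr])
    o <- order(chr, pos)
    chr <- chr[o]; pos <- pos[o]
    enh <- if (is.null(enhancers)) NULL else as.data.table(enhancers)

    rows <- list()
    for (ct in config$cell_types) {
      level <- rep(config$meth_baseline, n_cpgs)
      if (!is.null(enh) && nrow(enh)) {
        e_ct <- enh[cell_type == ct]
        for (i in seq_len(nrow(e_ct))) {
          hit <- g$chrom[chr] == e_ct$chrom[i] &
            abs(pos - e_ct$pos[i]) <= enh_halfwidth
          level[hit] <- config$meth_enh_level
        }
      }
      for (rep_i in seq_len(replicates)) {
        tot <- rpois(n_cpgs, coverage)
        rows[[paste(ct, rep_i)]] <- data.table(
          chrom = g$chrom[chr], pos = as.integer(pos),
          meth_count = rbinom(n_cpgs, tot, level), total_count = tot,
          cell_type = ct, replicate = rep_i, spike_in = "none")
      }
    }
    # spike-in contigs, shared across cell types/replicates
    spike <- function(contig, n, level, flag) {
      p <- sort(sample.int(5e4, n))
      parts <- lapply(config$cell_types, function(ct) {
        rbindlist(lapply(seq_len(replicates), function(rep_i) {
          tot <- rpois(n, coverage)
          data.table(chrom = contig, pos = p,
                     meth_count = rbinom(n, tot, level), total_count = tot,
                     cell_type = ct, replicate = rep_i, spike_in = flag)
        }))
      })
      rbindlist(parts)
    }
    out <- rbindlist(c(rows, list(
      spike("spikein_unmeth", n_spike_cpgs[1], config$conversion_error,
            "unmethylated_control"),
      spike("spikein_meth", n_spike_cpgs[2], config$detection_rate,
            "methylated_control"))))
    class(out) <- c("methyl_table", class(out))
    attr(out, "ground_truth") <- list(
      enhancers = enh, baseline = config$meth_baseline,
      enh_level = config$meth_enh_level,
      conversion_error = config$conversion_error,
      detection_rate = config$detection_rate)
    out
  })
}

#' Generate a synthetic MPRA design table
#'
#' Random 266-nt candidate regulatory sequences labelled by category, used
#' where no genome sequence is available to run [design_library()] on.
#'
#' @param config A [sim_config()]; `config$mpra` sets the counts.
#' @return A data.table (`cre_id`, `category`, `sequence`, `tag`).
#' @export
simulate_mpra_design <- function(config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, "mpra_design"), {
    m <- config$mpra
    cats <- c(rep("posCor", m$n_cre), rep("scrambled", m$n_scrambled))
    n <- length(cats)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 266, replace = TRUE), collapse = "")
    }, character(1))
    data.table(cre_id = sprintf("cre_%04d", seq_len(n)), category = cats,
               sequence = seqs,
               tag = ifelse(cats == "mut", "TCCG", "ATTA"))
  })
}

#' Simulate MPRA barcode counts with planted activities
#'
#' Each design entry receives `barcodes_per_cre` barcodes; DNA counts are
#' negative binomial around the configured depth and RNA counts around
#' `depth * 2^activity`, where the planted activity is 0 for scrambled
#' controls and the configured per-category value otherwise.
#'
#' @param config A [sim_config()].
#' @param design A design table with `cre_id` and `category` (e.g. from
#'   [simulate_mpra_design()] or [design_library()]).
#' @param sample_name Label written into the `sample` column.
#' @param activity Optional named per-category log2 activity overriding
#'   `config$mpra$activity` (categories missing from the vector get 0).
#' @return data.table (`sample`, `barcode`, `cre_id`, `dna_umis`,
#'   `rna_umis`) with per-CRE true activities as `ground_truth` attribute.
#' @export
simulate_mpra_counts <- function(config, design, sample_name = "pooled",
                                 activity = NULL) {
  validate_sim_config(config)
  design <- as.data.table(design)
  if (!nrow(design)) stop("design is empty")
  m <- config$mpra
  if (m$barcodes_per_cre < 1) stop("barcodes_per_cre must be at least 1")
  act_map <- activity %||% m$activity
  with_seed(child_seed(config$seed, paste0("mpra_counts_", sample_name)), {
    act <- ifelse(design$category == "scrambled", 0,
                  ifelse(design$category %in% names(act_map),
                         act_map[design$category], 0))
    nb <- m$barcodes_per_cre
    n <- nrow(design) * nb
    cre <- rep(design$cre_id, each = nb)
    out <- data.table(
      sample = sample_name,
      barcode = sprintf("%s_bc%03d", cre, rep(seq_len(nb), nrow(design))),
      cre_id = cre,
      dna_umis = rnbinom(n, mu = m$depth, size = 1 / config$dispersion),
      rna_umis = rnbinom(n, mu = m$depth * 2^rep(act, each = nb),
                         size = 1 / config$dispersion))
    attr(out, "ground_truth") <- data.table(cre_id = design$cre_id,
                                            category = design$category,
                                            activity = act)
    out
  })
}
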