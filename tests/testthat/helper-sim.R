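# Shared small fixtures for unit tests. Kept deliberately tiny; the
# full-scale planted-recovery runs live in test-acceptance.R.

tiny_config <- function(seed = 1L,
                        mpra = list(n_cre = 40L, n_scrambled = 25L,
                                    barcodes_per_cre = 10L, depth = 100,
                                    activity = c(posCor = 2, scrambled = 0)),
                        ...) {
  sim_config(seed = seed,
             n_cells_per_type = 60L,
             n_genes = 60L, n_peaks = 80L,
             n_egp_pos = 12L, n_egp_neg = 12L, n_egp_null = 24L,
             genome = data.frame(chrom = c("chr1", "chr2"),
                                 length = c(40e6, 40e6)),
             hic_depth = 2e4,
             mpra = mpra,
             ...)
}

# decay-only contact list on one chromosome
decay_contacts <- function(seed, depth = 2e5, L = 10e6, ...) {
  cfg <- sim_config(seed = seed, genome = data.frame(chrom = "chrS", length = L),
                    hic_depth = depth, ...)
  simulate_contact_maps(cfg, cell_types = "NSC")$contacts$NSC
}

brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

log_norm_test <- function(m) {
  depth <- rowSums(m)
  log2(1 + 1e4 * m / depth)
}

standardize_test <- function(x) (x - mean(x)) / sqrt(mean(x^2) - mean(x)^2)

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
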