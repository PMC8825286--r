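library(data.table)

test_that("metacell groups have exactly k members and aggregate correctly", {
  set.seed(1)
  coords <- matrix(rnorm(40), 20, 2)
  counts <- matrix(rpois(20 * 5, 10), 20, 5,
                   dimnames = list(NULL, paste0("f", 1:5)))
  g <- group_metacells(coords, k = 4, rna = counts)
  expect_equal(dim(g$members), c(20, 4))
  # k = 1: singleton groups; aggregate equals the cell's normalized vector
  g1 <- group_metacells(coords, k = 1, rna = counts)
  expect_equal(g1$rna[3, ],
               log2(1 + 1e4 * counts[3, ] / sum(counts[3, ])))
  expect_error(group_metacells(coords, k = 21), "exceeds")
})

test_that("well-separated blobs never mix and ties are deterministic", {
  set.seed(2)
  blob <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 50), 50, 2))
  g <- group_metacells(blob, k = 10)
  side <- matrix(g$members <= 50, nrow(g$members), ncol(g$members))
  expect_true(all(rowSums(side) %in% c(0L, 10L)))
  # brute-force neighbour check for one seed cell
  d <- as.matrix(dist(blob))
  expect_setequal(g$members[7, ], order(d[7, ], seq_len(100))[1:10])
  # exact ties broken by lowest cell index
  tied <- matrix(c(0, 0, 1, 1, -1, -1, 2, 2), ncol = 2, byrow = TRUE)
  gt <- group_metacells(tied, k = 2)
  expect_identical(gt$members[1, ], c(1L, 2L))  # cells 2 and 3 tie; lowest wins
})

test_that("linkage recovers exact correlations and applies the distance rules", {
  # controlled geometry: 3 genes, 4 peaks on chr1, trans pool on chr2
  genes <- data.table(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      tss = c(1e6, 3e6, 5e6), strand = "+")
  peaks <- data.table(
    peak_id = c("p1", "p2", "p3", "p_far", "p_prom", paste0("t", 1:10)),
    chrom = c(rep("chr1", 5), rep("chr2", 10)),
    start = c(1e6 + 50e3, 3e6 + 50e3, 5e6 + 50e3, 1e6 + 600e3, 3e6 + 100,
              seq(1e6, 10e6, by = 1e6)) - 250)
  peaks[, end := start + 500]
  set.seed(3)
  n <- 50
  base <- matrix(rpois(n * 3, 20), n, 3, dimnames = list(NULL, genes$gene_id))
  atac <- matrix(rpois(n * nrow(peaks), 20), n, nrow(peaks),
                 dimnames = list(NULL, peaks$peak_id))
  groups <- list(rna = log_norm_test(base), atac = log_norm_test(atac))
  groups$atac[, "p1"] <- groups$rna[, "g1"]  # identical group vectors -> r = 1
  egps <- link_peaks_to_genes(groups, peaks, genes, n_null = 10, seed = 1)
  expect_gt(egps[peak_id == "p1" & gene_id == "g1", r], 0.99)
  # peak 600 kb from the TSS is absent
  expect_false("p_far" %in% egps$peak_id)
  # promoter-proximal peak is not tested (not distal)
  expect_false("p_prom" %in% egps$peak_id)
  # every row's class is consistent with the thresholds
  prm <- attr(egps, "params")
  with(egps, {
    expect_true(all((class != "posCor") | (r >= prm$r_min & q <= prm$fdr)))
    expect_true(all((class != "negCor") | (r <= -prm$r_min & q <= prm$fdr)))
    expect_true(all((class != "control") | (abs(r) < prm$r_min & q > prm$fdr)))
  })
  # BH q-values match a brute-force implementation
  expect_equal(egps$q, brute_bh(egps$p_emp))
})

test_that("hand-computed Pearson example matches", {
  a <- c(0, 1, 2, 3, 4, 5)
  e <- c(1, 3, 2, 5, 4, 6)
  # by hand: cov* = 15.5, both centered sums of squares = 17.5
  expect_equal(round(cor(a, e), 4), round(15.5 / 17.5, 4))
  # the linkage r path uses the same standardized product formula
  za <- standardize_test(a); ze <- standardize_test(e)
  expect_equal(sum(za * ze) / 6, cor(a, e), tolerance = 1e-12)
})

test_that("peak location classes follow the distance thresholds", {
  genes <- data.frame(gene_id = "g", chrom = "c", tss = 10000, strand = "+")
  pk <- function(center) data.frame(peak_id = "p", chrom = "c",
                                    start = center - 250, end = center + 250)
  expect_identical(classify_peak_location(pk(10300), genes), "promoter")
  expect_identical(classify_peak_location(pk(16000), genes), "distal")
  expect_identical(classify_peak_location(pk(12000), genes), "neither")
  expect_error(classify_peak_location(pk(1), genes[0, ]), "empty")
})

test_that("cluster-specific peak calling matches a manual t-test", {
  # a large stable anchor row keeps library sizes comparable, so the planted
  # 4-fold enrichment survives CPM normalization
  counts <- cbind(A_rep1 = c(4000, 100, 96000), A_rep2 = c(4100, 110, 95500),
                  B_rep1 = c(1000, 105, 99000), B_rep2 = c(1020, 100, 98500),
                  C_rep1 = c(990, 95, 99100), C_rep2 = c(1010, 102, 98900))
  rownames(counts) <- c("pk_up", "pk_flat", "pk_anchor")
  pb <- list(counts = counts,
             samples = data.table(sample = colnames(counts),
                                  cluster = rep(c("A", "B", "C"), each = 2),
                                  replicate = rep(1:2, 3)))
  calls <- call_cluster_specific_peaks(pb, p_adj = 0.05, lfc_min = 0.25)
  expect_true(calls[peak_id == "pk_up", specific])
  expect_identical(calls[peak_id == "pk_up", cluster], "A")
  expect_false(calls[peak_id == "pk_flat", specific])
  # manual pooled-variance t statistic for the same top-vs-next comparison
  cpm <- log2(1 + t(t(counts) / colSums(counts) * 1e6))
  mns <- vapply(list(1:2, 3:4, 5:6), function(ix) mean(cpm["pk_up", ix]),
                numeric(1))
  nxt <- list(1:2, 3:4, 5:6)[[order(mns, decreasing = TRUE)[2]]]
  x <- cpm["pk_up", 1:2]; y <- cpm["pk_up", nxt]
  sp2 <- (var(x) + var(y)) / 2
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(calls[peak_id == "pk_up", t], t_manual, tolerance = 1e-8)
})

test_that("pseudobulk halving pseudoreplicates small clusters deterministically", {
  counts <- matrix(rpois(30 * 4, 5), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  pb1 <- pseudobulk_counts(counts, cluster = rep("small", 30),
                           replicate = rep(1, 30), min_cells = 100, seed = 9)
  pb2 <- pseudobulk_counts(counts, cluster = rep("small", 30),
                           replicate = rep(1, 30), min_cells = 100, seed = 9)
  expect_identical(pb1, pb2)
  expect_equal(ncol(pb1$counts), 2)
  # the two pseudoreplicates partition the cells
  expect_equal(rowSums(pb1$counts), colSums(counts), ignore_attr = TRUE)
})

test_that("EGP cluster assignment inherits peak calls and tallies", {
  egps <- data.table(peak_id = c("p1", "p2", "p3", "p4"),
                     gene_id = paste0("g", 1:4),
                     class = c("posCor", "posCor", "posCor", "control"))
  calls <- data.table(peak_id = c("p1", "p2"), cluster = c("NSC", NA))
  out <- assign_egp_clusters(egps, calls)
  expect_identical(out[peak_id == "p1", cluster], "NSC")
  expect_identical(out[peak_id == "p2", cluster], "none")  # uncalled peak
  expect_identical(out[peak_id == "p3", cluster], "none")  # peak without row
  expect_true(is.na(out[peak_id == "p4", cluster]))        # not posCor
  tally <- out[class == "posCor" & cluster != "none", .N]
  expect_equal(tally, 1)
})
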