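library(data.table)

make_universe <- function(seed = 1, n_peaks = 2000, L = 5e6) {
  set.seed(seed)
  data.table(peak_id = sprintf("pk%05d", seq_len(n_peaks)), chrom = "chrF",
             pos = round(runif(n_peaks, 1e5, L - 1e5) / 1e4) * 1e4,
             accessibility = rexp(n_peaks))
}

test_that("motif peak selection ranks by accessibility and applies filters", {
  hits <- data.table(motif_id = "M1", peak_id = sprintf("p%04d", 1:800),
                     chrom = "c", pos = seq_len(800) * 1e4)
  acc <- setNames(seq_len(800) / 100, hits$peak_id)  # increasing
  tf <- data.table(motif_id = c("M1", "M2"), rpkm = c(5, 0.2),
                   variable = c(TRUE, TRUE))
  sel <- select_motif_peaks(hits, acc, tf, top_n = 500)
  expect_equal(nrow(sel$M1), 500)
  expect_setequal(sel$M1$peak_id, sprintf("p%04d", 301:800))  # top accessible
  # below the expression floor -> dropped
  hits2 <- copy(hits)[, motif_id := "M2"]
  sel2 <- select_motif_peaks(hits2, acc, tf, top_n = 500)
  expect_length(sel2, 0)
  expect_identical(attr(sel2, "dropped"), "M2")
  # fewer hits than top_n -> all retained
  sel3 <- select_motif_peaks(hits[1:100], acc, tf, top_n = 500)
  expect_equal(nrow(sel3$M1), 100)
  # not in the variable set -> dropped
  tf3 <- data.table(motif_id = "M1", rpkm = 5, variable = FALSE)
  expect_length(select_motif_peaks(hits, acc, tf3), 0)
})

test_that("background sets are seeded samples from the top pool", {
  pts <- make_universe(2)
  bg <- build_background(pts, n_sets = 20, set_size = 100, pool_size = 500,
                         seed = 3)
  expect_equal(dim(bg$sets), c(20, 100))
  expect_true(all(apply(bg$sets, 1, function(s) length(unique(s)) == 100)))
  expect_true(all(bg$sets >= 1 & bg$sets <= 500))
  # pool = top 500 by accessibility
  expect_gte(min(bg$pool$accessibility),
             sort(pts$accessibility, decreasing = TRUE)[500])
  bg2 <- build_background(pts, n_sets = 20, set_size = 100, pool_size = 500,
                          seed = 3)
  expect_identical(bg$sets, bg2$sets)
  expect_warning(build_background(pts, 5, 100, pool_size = 1e6), "all peaks")
  expect_error(build_background(pts, 5, 600, pool_size = 500), "exceeds")
})

test_that("intra-TAD pair sampling respects separation and the cap", {
  pts <- make_universe(4, n_peaks = 400)
  tads <- data.table(chrom = "chrF", start = c(0, 2.5e6), end = c(2.5e6, 5e6))
  prs <- regscape:::sample_point_pairs(pts, tads, min_sep = 1e4,
                                       n_pairs = 300, seed = 5)
  expect_lte(nrow(prs), 300)
  expect_true(all(prs$y - prs$x >= 1e4))
  # both ends in the same TAD
  same_tad <- (prs$x < 2.5e6) == (prs$y < 2.5e6)
  expect_true(all(same_tad))
  expect_identical(prs, regscape:::sample_point_pairs(pts, tads, 1e4, 300,
                                                      seed = 5))
})

test_that("looping specificity detects a planted motif against the null", {
  pts <- make_universe(6)
  gen <- data.frame(chrom = "chrF", length = 5e6)
  tads <- tads_from_boundaries(data.frame(chrom = "chrF",
                                          pos = seq(1e6, 4e6, by = 1e6)),
                               c(chrF = 5e6))
  cfg <- sim_config(seed = 6, genome = gen, hic_depth = 1e6, tad_factor = 2)
  motif <- pts[sample(.N, 150)]
  prs <- regscape:::sample_point_pairs(motif, tads, 1e4, 2000, seed = 9)
  loops <- data.frame(chrom = "chrF", a1 = prs$x, a2 = prs$y, fold = 5)
  cs <- simulate_contact_maps(cfg, boundaries = data.frame(
    chrom = "chrF", pos = seq(1e6, 4e6, by = 1e6)), loops = loops)
  exps <- lapply(cs$contacts, make_expected, chrom_sizes = cs$chrom_sizes,
                 seed = 10)
  bg <- build_background(pts, n_sets = 100, set_size = 150, pool_size = 2000,
                         seed = 7)
  motifs <- list(planted = motif)
  set.seed(8)
  for (i in 1:3) motifs[[paste0("pseudo", i)]] <- bg$pool[sample(2000, 150)]
  res <- motif_loop_specificity(motifs, bg, cs$contacts, exps, tads,
                                max_pairs = 300, bg_pairs = 60,
                                min_pairs = 30, seed = 11)
  expect_lt(res[motif_id == "planted", p_max], 0.05)
  expect_gt(min(res$p_max), 0)  # add-one smoothing: never exactly 0
  expect_gt(res[motif_id == "planted", max_score],
            max(res[motif_id != "planted", max_score]))
  # permutation p never 0 and bounded by 1
  expect_true(all(res$p_max > 0 & res$p_max <= 1 &
                    res$p_sd > 0 & res$p_sd <= 1))
})

test_that("methylation specificity finds planted cell-type hypomethylation", {
  pts <- make_universe(12, n_peaks = 1000, L = 20e6)
  cfg <- sim_config(seed = 12,
                    genome = data.frame(chrom = "chrF", length = 20e6))
  motif <- pts[sample(.N, 150)]
  enh <- data.frame(chrom = "chrF", pos = motif$pos, cell_type = "IPC")
  mt <- simulate_methylation(cfg, enhancers = enh, n_cpgs = 60000,
                             coverage = 30, enh_halfwidth = 250)
  meth <- filter_cpgs(mt[mt$spike_in == "none", ])
  bg <- build_background(pts, n_sets = 100, set_size = 150,
                         pool_size = 1000, seed = 13)
  res <- motif_meth_specificity(list(planted = motif), bg, meth,
                                window = 500, min_windows = 30)
  expect_lt(res$min_meth, 0.4)
  expect_lt(res$p_min, 0.05)
  expect_lt(res$p_sd, 0.05)
  expect_lt(abs(res$meth_NSC - 0.8), 0.05)
  # uniform methylation: a background-drawn set is not significant
  set.seed(14)
  rnd <- bg$pool[sample(1000, 150)]
  res0 <- motif_meth_specificity(list(r = rnd), bg, meth, window = 500,
                                 min_windows = 30)
  expect_gt(res0$p_sd, 0.05)
})

test_that("motif records are invariant to peak input order", {
  pts <- make_universe(15, n_peaks = 600, L = 20e6)
  cfg <- sim_config(seed = 15,
                    genome = data.frame(chrom = "chrF", length = 20e6))
  mt <- simulate_methylation(cfg, n_cpgs = 30000, coverage = 30)
  meth <- filter_cpgs(mt[mt$spike_in == "none", ])
  bg <- build_background(pts, n_sets = 30, set_size = 100, pool_size = 600,
                         seed = 16)
  motif <- pts[1:120]
  a <- motif_meth_specificity(list(m = motif), bg, meth, min_windows = 20)
  b <- motif_meth_specificity(list(m = motif[sample(.N)]), bg, meth,
                              min_windows = 20)
  expect_equal(a$min_meth, b$min_meth)
  expect_equal(a$p_min, b$p_min)
})
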