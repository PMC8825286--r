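library(data.table)

test_that("library design centers, resizes and tags sequences", {
  set.seed(61)
  genome <- c(chr1 = paste(sample(c("a", "c", "g", "t"), 5000, TRUE),
                           collapse = ""))
  iv <- data.table(cre_id = c("w1", "m1", "edge"),
                   category = c("posCor", "mut", "posCor"),
                   chrom = "chr1",
                   start = c(1000, 2000, 0), end = c(1501, 2600, 6))
  des <- design_library(iv, genome)
  expect_equal(attr(des, "skipped"), 1L)  # interval 3 bp from the start
  expect_true(all(nchar(des$sequence) == 266))
  expect_true(all(grepl("^[ACGT]+$", des$sequence)))  # uppercased
  expect_identical(des$tag, c("ATTA", "TCCG"))
  # center = floor midpoint, deterministic window
  ctr <- floor((1000 + 1501) / 2)
  expect_equal(des[cre_id == "w1", start], ctr - 133)
  expect_identical(des[cre_id == "w1", sequence],
                   toupper(substr(genome[["chr1"]], ctr - 133 + 1, ctr + 133)))
})

test_that("scrambles preserve base composition and reduce motif scores", {
  pwm <- random_pwm(8, seed = 62)
  seqin <- paste0(strrep("ACGT", 40), attr(pwm, "consensus"),
                  strrep("GTTA", 24))
  scr <- scramble_control(seqin, list(pwm), seed = 63)
  expect_identical(sort(strsplit(seqin, "")[[1]]),
                   sort(strsplit(unclass(scr), "")[[1]]))
  expect_lte(attr(scr, "score"), max_pwm_score(seqin, pwm))
  expect_identical(as.character(scr),
                   as.character(scramble_control(seqin, list(pwm), seed = 63)))
  expect_error(scramble_control(seqin, list()), "non-empty")
})

test_that("motif mutagenesis minimizes the hit score and touches only the hit", {
  pwm <- random_pwm(8, seed = 64)
  seqin <- paste0(strrep("ACGT", 30), attr(pwm, "consensus"), strrep("TGCA", 30))
  mu <- mutate_motif(seqin, 121, 128, pwm, n_perm = 100, seed = 65)
  s_in <- strsplit(seqin, "")[[1]]; s_mu <- strsplit(unclass(mu), "")[[1]]
  expect_true(all(s_in[-(121:128)] == s_mu[-(121:128)]))
  # GC of the hit conserved exactly
  expect_identical(sort(s_in[121:128]), sort(s_mu[121:128]))
  # selection = min over the same 100 seeded candidates (re-scan oracle)
  idx <- regscape:::encode_seq(seqin)
  hit <- idx[121:128]
  cand_scores <- with_seed_test(65, vapply(1:100, function(i) {
    cand <- idx
    cand[121:128] <- hit[sample.int(8)]
    max_pwm_score(regscape:::decode_seq(cand[114:135]), pwm)
  }, numeric(1)))
  expect_equal(attr(mu, "score"), min(cand_scores))
  expect_warning(mutate_motif(seqin, 121, 123, pwm, seed = 1), "tiny")
  expect_error(mutate_motif(seqin, 0, 5, pwm), "coordinates")
})

test_that("barcode association applies read and purity floors per tag class", {
  reads <- rbind(
    data.table(barcode = "b1", cre_id = rep("A", 10), tag = "ATTA"),
    data.table(barcode = "b2", cre_id = c(rep("A", 5), rep("B", 5)),
               tag = "ATTA"),                      # purity 0.5 -> dropped
    data.table(barcode = "b3", cre_id = rep("A", 2), tag = "ATTA"),  # < 3 reads
    data.table(barcode = "b4", cre_id = c(rep("C", 9), "D"), tag = "ATTA"),
    data.table(barcode = "b5", cre_id = rep("E", 4), tag = "TCCG"))
  map <- associate_barcodes(reads)
  expect_setequal(map$barcode, c("b1", "b4", "b5"))
  expect_identical(map[barcode == "b4", cre_id], "C")
  expect_equal(map[barcode == "b1", n_reads], 10)
  # hand tally on the 12-row toy table: x pure (4/4 A, kept);
  # y purity 3/4 = 0.75 < 0.8 (dropped); z purity 2/4 = 0.5 (dropped)
  toy <- data.table(barcode = rep(c("x", "y", "z"), each = 4),
                    cre_id = c(rep("A", 4), rep("B", 3), "C", rep("D", 2),
                               "E", "F"))
  m2 <- associate_barcodes(toy)
  expect_identical(m2$barcode, "x")
  expect_identical(m2$cre_id, "A")
})

test_that("activity scoring is a calibrated MAD-z against scrambled controls", {
  cfg <- tiny_config(seed = 66)
  des <- simulate_mpra_design(cfg)
  # RNA == DNA everywhere -> no significance, madz ~ 0
  cnt <- simulate_mpra_counts(cfg, des)
  flat <- copy(cnt)[, rna_umis := dna_umis]
  expect_error(score_activity(flat, des), "MAD is zero")
  # with sampled counts at zero activity: none strongly significant
  cnt0 <- simulate_mpra_counts(cfg, des, activity = c(posCor = 0))
  act0 <- score_activity(cnt0, des)
  expect_true(all(act0$significant == (act0$p <= 0.05)))
  expect_lt(act0[category != "scrambled", mean(significant)], 0.2)
  expect_lt(abs(median(act0$madz)), 0.5)
  # planted activity log2 = 2: strong power
  cnt2 <- simulate_mpra_counts(cfg, des)
  act2 <- score_activity(cnt2, des)
  gt <- ground_truth(cnt2)
  mm <- merge(act2, gt, by = "cre_id")
  expect_gte(mm[activity.y == 2, mean(significant)], 0.9)
  # min_barcodes floor enforced
  few <- cnt2[!(cre_id == des$cre_id[1] &
                  barcode %in% cnt2[cre_id == des$cre_id[1], barcode][1:8])]
  act3 <- score_activity(few, des, min_barcodes = 5)
  expect_false(des$cre_id[1] %in% act3$cre_id)
  # too few scrambled controls -> explicit error
  pos_ids <- des[category != "scrambled", cre_id]
  expect_error(score_activity(cnt2[cre_id %in% pos_ids], des), "scrambled")
})

test_that("paired WT/mut comparison detects motif-dependent activity", {
  cfg <- tiny_config(seed = 67,
                     mpra = list(n_cre = 50L, n_scrambled = 25L,
                                 barcodes_per_cre = 20L, depth = 100,
                                 activity = c(posCor = 2, mut = 0,
                                              scrambled = 0)))
  wt <- simulate_mpra_design(cfg)
  mut <- copy(wt[category == "posCor"])
  mut[, `:=`(cre_id = paste0(cre_id, "_mut"), category = "mut",
             tag = "TCCG")]
  des <- rbind(wt, mut)
  cnt <- simulate_mpra_counts(cfg, des)
  act <- score_activity(cnt, des)
  w <- act[category == "posCor"][order(cre_id), activity]
  m <- act[category == "mut"][order(cre_id), activity]
  expect_equal(length(w), length(m))
  expect_lt(wilcox.test(w, m, paired = TRUE)$p.value, 0.01)
})
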