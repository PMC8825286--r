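#' Design an MPRA library from genomic intervals
#'
#' Each interval is replaced by the `oligo_length`-bp window centered at the
#' floor midpoint of the interval and the genomic sequence is extracted and
#' uppercased. A 4-bp category tag is recorded: `TCCG` for motif mutants,
#' `ATTA` for wild-type and control sequences. Intervals whose centered
#' window leaves the chromosome are skipped and counted.
#'
#' @param intervals data.frame with `cre_id`, `category`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param genome Named character vector (or `Biostrings::DNAStringSet`) of
#'   chromosome sequences.
#' @param oligo_length Designed sequence length (bp).
#' @return data.table (`cre_id`, `category`, `chrom`, `start`, `end`,
#'   `sequence`, `tag`) with attribute `skipped`.
#' @export
design_library <- function(intervals, genome, oligo_length = 266) {
  intervals <- as.data.table(intervals)
  stop_missing_column(intervals, c("cre_id", "category", "chrom", "start", "end"),
                      "intervals")
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  half_lo <- floor(oligo_length / 2)
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(intervals))) {
    cc <- intervals$chrom[i]
    if (!cc %in% names(genome)) stop("chromosome ", cc, " not in genome")
    center <- floor((intervals$start[i] + intervals$end[i]) / 2)
    s0 <- center - half_lo          # 0-based window start
    e0 <- s0 + oligo_length         # 0-based half-open end
    if (s0 < 0 || e0 > nchar(genome[[cc]])) { skipped <- skipped + 1L; next }
    rows[[i]] <- data.table(
      cre_id = intervals$cre_id[i], category = intervals$category[i],
      chrom = cc, start = s0, end = e0,
      sequence = toupper(substr(genome[[cc]], s0 + 1L, e0)),
      tag = if (intervals$category[i] == "mut") "TCCG" else "ATTA")
  }
  out <- rbindlist(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Scrambled control sequence with matched GC and minimal motif content
#'
#' Produces a random nucleotide permutation of the input (base composition,
#' hence GC content, is preserved exactly), rejection-resampled until the
#' best PWM log-odds hit over the supplied motifs falls below
#' `score_threshold`; if no candidate passes within `max_tries`, the
#' minimum-scoring candidate seen is returned.
#'
#' @param sequence Input DNA sequence.
#' @param pwms List of expressed-TF PWMs to prescreen against.
#' @param score_threshold Accept candidates scoring below this.
#' @param max_tries Candidates to draw.
#' @param seed Seed.
#' @return The scrambled sequence, with its motif score as attribute
#'   `score`.
#' @export
scramble_control <- function(sequence, pwms, score_threshold = 7,
                             max_tries = 100, seed = 1L) {
  if (!length(pwms)) stop("PWM set must be non-empty")
  idx <- encode_seq(sequence)
  with_seed(seed, {
    best <- NULL; best_score <- Inf
    for (i in seq_len(max_tries)) {
      cand <- idx[sample.int(length(idx))]
      sc <- max_pwm_score(decode_seq(cand), pwms)
      if (sc < best_score) { best <- cand; best_score <- sc }
      if (sc < score_threshold) break
    }
    out <- decode_seq(best)
    attr(out, "score") <- best_score
    out
  })
}

#' Mutate a motif hit to its lowest-scoring GC-matched permutation
#'
#' Generates `n_perm` random permutations of the subsequence at the motif
#' hit (permutation preserves the GC count exactly), scores each candidate
#' over the mutated region (extended by the PWM width on both sides) and
#' substitutes the lowest-scoring one. The rest of the sequence is
#' untouched.
#'
#' @param sequence Input DNA sequence.
#' @param hit_start,hit_end 1-based inclusive motif hit coordinates.
#' @param pwms PWM (or list) to minimize against.
#' @param n_perm Number of candidate permutations.
#' @param seed Seed.
#' @return The mutated sequence, with the selected candidate's score as
#'   attribute `score`.
#' @export
mutate_motif <- function(sequence, hit_start, hit_end, pwms, n_perm = 100,
                         seed = 1L) {
  n <- nchar(sequence)
  if (hit_start < 1 || hit_end > n || hit_start > hit_end) {
    stop("motif hit coordinates outside the sequence")
  }
  if (hit_end - hit_start + 1 < 4) {
    warning("motif hit shorter than 4 bp; permutation space is tiny")
  }
  if (is.matrix(pwms)) pwms <- list(pwms)
  w <- max(vapply(pwms, ncol, integer(1)))
  idx <- encode_seq(sequence)
  hit <- idx[hit_start:hit_end]
  ctx_lo <- max(1L, hit_start - (w - 1L))
  ctx_hi <- min(n, hit_end + (w - 1L))
  with_seed(seed, {
    best <- NULL; best_score <- Inf
    for (i in seq_len(n_perm)) {
      cand <- idx
      cand[hit_start:hit_end] <- hit[sample.int(length(hit))]
      sc <- max_pwm_score(decode_seq(cand[ctx_lo:ctx_hi]), pwms)
      if (sc < best_score) { best <- cand; best_score <- sc }
    }
    out <- decode_seq(best)
    attr(out, "score") <- best_score
    out
  })
}

#' Associate barcodes to CREs from association reads
#'
#' A barcode is assigned to a CRE when at least `min_reads` reads carry it
#' and at least a `purity` fraction of them agree on the CRE. When a `tag`
#' column is present (wild-type vs mutant 4-bp identifiers) the association
#' is performed separately per tag class, and barcodes assigned in more
#' than one class are dropped as ambiguous.
#'
#' @param reads data.frame with `barcode`, `cre_id` and optional `tag`.
#' @param min_reads Minimum supporting reads.
#' @param purity Minimum agreeing fraction.
#' @return data.table (`barcode`, `cre_id`, `n_reads`, `purity`).
#' @export
associate_barcodes <- function(reads, min_reads = 3, purity = 0.8) {
  reads <- as.data.table(reads)
  stop_missing_column(reads, c("barcode", "cre_id"), "association reads")
  if (is.null(reads$tag)) reads[, tag := "all"]
  assoc <- reads[, .(n = .N), by = .(tag, barcode, cre_id)]
  per_bc <- assoc[, {
    tot <- sum(n); top <- which.max(n)
    .(cre_id = cre_id[top], n_reads = tot, purity = n[top] / tot)
  }, by = .(tag, barcode)]
  min_purity <- purity
  keep <- per_bc[n_reads >= min_reads & purity >= min_purity]
  dup <- keep[, .N, by = barcode][N > 1, barcode]
  keep[!barcode %in% dup, .(barcode, cre_id, n_reads, purity)]
}

#' Score MPRA activity with a robust z against scrambled controls
#'
#' DNA and RNA UMIs are summed per CRE over its assigned barcodes (ratio of
#' sums), scaled to counts-per-million within the sample, and the activity
#' is `log2((rna_cpm + 1) / (dna_cpm + 1))`. Each CRE's activity is
#' converted to a robust z-score (MAD-z) against the median and
#' 1.4826-scaled MAD of the scrambled-control activities, with a two-sided
#' standard-normal p-value; CREs with `p <= 0.05` are flagged significant.
#'
#' @param counts data.frame with `sample`, `barcode`, `dna_umis`,
#'   `rna_umis` (and `cre_id` unless `mapping` is given).
#' @param design Design table with `cre_id`, `category`.
#' @param mapping Optional barcode-to-CRE mapping (from
#'   [associate_barcodes()]).
#' @param min_barcodes Minimum assigned barcodes per scored CRE.
#' @param min_scrambled Minimum scored scrambled controls.
#' @return `activity_table`: data.table with `sample`, `cre_id`,
#'   `category`, `dna_sum`, `rna_sum`, `n_barcodes`, `activity`, `madz`,
#'   `p`, `significant`.
#' @export
score_activity <- function(counts, design, mapping = NULL, min_barcodes = 5,
                           min_scrambled = 20) {
  counts <- as.data.table(counts)
  design <- as.data.table(design)
  if (!is.null(mapping)) {
    counts <- merge(counts[, setdiff(names(counts), "cre_id"), with = FALSE],
                    as.data.table(mapping)[, .(barcode, cre_id)],
                    by = "barcode")
  }
  stop_missing_column(counts, c("sample", "cre_id", "dna_umis", "rna_umis"),
                      "counts")
  agg <- counts[, .(dna_sum = sum(dna_umis), rna_sum = sum(rna_umis),
                    n_barcodes = .N), by = .(sample, cre_id)]
  agg <- merge(agg, design[, .(cre_id, category)], by = "cre_id")
  agg <- agg[n_barcodes >= min_barcodes]
  out <- agg[, {
    dna_cpm <- dna_sum / sum(dna_sum) * 1e6
    rna_cpm <- rna_sum / sum(rna_sum) * 1e6
    activity <- log2((rna_cpm + 1) / (dna_cpm + 1))
    scr <- activity[category == "scrambled"]
    if (length(scr) < min_scrambled) {
      stop("fewer than ", min_scrambled, " scored scrambled controls")
    }
    scr_mad <- mad(scr)  # 1.4826-scaled by default
    if (scr_mad == 0) stop("scrambled-control MAD is zero; scoring aborted")
    madz <- (activity - median(scr)) / scr_mad
    p <- 2 * pnorm(-abs(madz))
    .(cre_id = cre_id, category = category, dna_sum = dna_sum,
      rna_sum = rna_sum, n_barcodes = n_barcodes, activity = activity,
      madz = madz, p = p, significant = p <= 0.05)
  }, by = sample]
  setattr(out, "class", c("activity_table", class(out)))
  out[]
}
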