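# Position weight matrix utilities. PWMs are 4 x w probability matrices
# with rownames A, C, G, T; scores are log2 odds against a uniform
# background, maximized over both strands and all offsets.

BASES <- c("A", "C", "G", "T")

encode_seq <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], BASES)
  if (anyNA(x)) stop("sequence contains non-ACGT characters")
  x
}

decode_seq <- function(idx) paste(BASES[idx], collapse = "")

revcomp_idx <- function(idx) 5L - rev(idx)

pwm_logodds <- function(pwm, floor_p = 1e-3) {
  stopifnot(nrow(pwm) == 4)
  log2(pmax(pwm, floor_p) / 0.25)
}

# All offset scores of one PWM (log-odds matrix) along an encoded sequence.
scan_pwm <- function(idx, lo) {
  w <- ncol(lo)
  n <- length(idx)
  if (n < w) return(numeric(0))
  offs <- seq_len(n - w + 1L)
  sc <- numeric(length(offs))
  for (i in seq_len(w)) sc <- sc + lo[cbind(idx[offs + i - 1L], i)]
  sc
}

#' Maximum PWM log-odds score of a sequence
#'
#' Scores a sequence against one or more position weight matrices
#' (probability matrices, rows A/C/G/T), taking the maximum log2-odds score
#' versus a uniform background over all offsets and both strands.
#'
#' @param seq A character DNA sequence.
#' @param pwms A single PWM matrix or a list of them.
#' @return The maximum score (`-Inf` when the sequence is shorter than every
#'   PWM).
#' @export
max_pwm_score <- function(seq, pwms) {
  if (is.matrix(pwms)) pwms <- list(pwms)
  idx <- encode_seq(seq)
  rc <- revcomp_idx(idx)
  best <- -Inf
  for (p in pwms) {
    lo <- pwm_logodds(p)
    best <- max(best, scan_pwm(idx, lo), scan_pwm(rc, lo))
  }
  best
}

#' Generate a random PWM with an embedded consensus
#'
#' Convenience generator for simulations and tests: a PWM whose columns put
#' probability `strength` on a random consensus base and spread the rest
#' uniformly.
#'
#' @param width Motif width.
#' @param strength Consensus-base probability.
#' @param seed Seed.
#' @return A 4 x width probability matrix (rownames A/C/G/T) with the
#'   consensus string as attribute `consensus`.
#' @export
random_pwm <- function(width = 8, strength = 0.9, seed = 1L) {
  with_seed(seed, {
    cons <- sample.int(4, width, replace = TRUE)
    m <- matrix((1 - strength) / 3, 4, width, dimnames = list(BASES, NULL))
    m[cbind(cons, seq_len(width))] <- strength
    attr(m, "consensus") <- decode_seq(cons)
    m
  })
}
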