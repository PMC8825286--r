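#' @importFrom stats cor dist kmeans ks.test mad median p.adjust
#'   pnorm predict quantile rbinom rmultinom rnbinom rnorm rpois runif sd
#'   setNames t.test var wilcox.test
#' @importFrom utils head tail
#' @importFrom data.table data.table as.data.table := setorder setnames
#'   setattr rbindlist fwrite fread .N .SD .I
#' @useDynLib regscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed for stage `tag` derived from a parent seed.
# Keeps independent stages on independent streams while remaining < 2^31.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_missing_column <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# log2(1 + counts-per-10k) depth normalization of a cells/groups x features
# count matrix (rows are observations).
log_norm_cp10k <- function(m) {
  depth <- Matrix::rowSums(m)
  depth[depth == 0] <- 1
  log2(1 + 1e4 * (m / depth))
}

# Column-standardize a matrix to zero mean / unit variance; zero-variance
# columns become all-zero so they contribute r = 0, not NaN.
standardize_cols <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  s <- sqrt(colMeans(m^2) - mu^2)
  s[s < .Machine$double.eps] <- Inf
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}
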