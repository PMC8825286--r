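#' Group cells into kNN metacells and aggregate both modalities
#'
#' Each seed cell defines a group consisting of itself and its `k - 1`
#' nearest Euclidean neighbours in the supplied reduced-dimension space
#' (ties broken by lowest cell index, so output is deterministic). Group
#' counts are aggregated by summation, depth-normalized to counts-per-10k and
#' log2(1 + x) transformed, which stabilizes the sparse single-cell signal
#' for correlation-based linkage.
#'
#' @param reduced_coords cells x d numeric matrix.
#' @param k Group size (number of member cells).
#' @param rna,atac Optional cells x feature count matrices to aggregate.
#' @param n_groups Number of seed cells; defaults to all cells, or a seeded
#'   downsample when smaller.
#' @param seed Seed for the seed-cell downsample.
#' @return `metacell_groups`: list with `members` (n_groups x k integer
#'   matrix of cell indices), `seed_cells`, `k`, and aggregated `rna` /
#'   `atac` matrices (groups x features) when counts were supplied.
#' @export
group_metacells <- function(reduced_coords, k, rna = NULL, atac = NULL,
                            n_groups = NULL, seed = 1L) {
  reduced_coords <- as.matrix(reduced_coords)
  n <- nrow(reduced_coords)
  if (ncol(reduced_coords) < 1) stop("need at least one reduced dimension")
  if (k > n) stop("k exceeds the number of cells")
  seeds <- seq_len(n)
  if (!is.null(n_groups) && n_groups < n) {
    seeds <- with_seed(seed, sort(sample.int(n, n_groups)))
  }
  d2 <- as.matrix(dist(reduced_coords))^2
  members <- t(vapply(seeds, function(i) {
    ord <- order(d2[i, ], seq_len(n))  # ties -> lowest cell index
    ord[seq_len(k)]
  }, integer(k)))
  if (k == 1L) members <- matrix(members, ncol = 1L)
  agg <- function(m) {
    if (is.null(m)) return(NULL)
    s <- t(apply(members, 1, function(ix) {
      if (length(ix) == 1L) as.numeric(m[ix, ]) else colSums(m[ix, , drop = FALSE])
    }))
    colnames(s) <- colnames(m)
    log_norm_cp10k(s)
  }
  out <- list(members = members, seed_cells = seeds, k = k,
              rna = agg(rna), atac = agg(atac))
  class(out) <- "metacell_groups"
  out
}

#' @export
print.metacell_groups <- function(x, ...) {
  cat("<metacell_groups>", nrow(x$members), "groups of size", x$k,
      if (!is.null(x$rna)) sprintf("| rna: %d features", ncol(x$rna)) else "",
      if (!is.null(x$atac)) sprintf("| atac: %d features", ncol(x$atac)) else "",
      "\n")
  invisible(x)
}
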