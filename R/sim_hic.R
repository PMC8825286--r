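#' Simulate per-cell-type Hi-C contact lists with planted structure
#'
#' Draws intrachromosomal contact lists whose intensity over 1-kb pixels is
#' proportional to `distance^-decay_exponent`, modulated by planted TADs
#' (within-TAD contacts boosted by `config$tad_factor`), A/B compartments
#' (same-label pairs boosted by `config$comp_factor`, cross-label pairs damped
#' by its inverse) and focal loops (a `fold`-times boost inside the 10-kb
#' pixel around each anchor pair). Contacts are sampled per pixel and then
#' jittered uniformly within the pixel; exactly `config$hic_depth` contacts
#' are produced per cell type.
#'
#' @param config A [sim_config()]; `genome`, `hic_depth`, `decay_exponent`,
#'   `tad_factor` and `comp_factor` are used.
#' @param boundaries Optional data.frame of planted TAD boundaries
#'   (`chrom`, `pos`, optional `cell_type`; `NA` cell_type = present in all).
#' @param compartments Optional data.frame of compartment blocks
#'   (`chrom`, `start`, `end`, `label` in `{"A","B"}`).
#' @param loops Optional data.frame of loop anchors (`chrom`, `a1`, `a2`,
#'   `fold`, optional `cell_type`).
#' @param cell_types Cell types to simulate (default from config).
#' @return A `contact_set`: list with `contacts` (named list of data.tables
#'   `chrom`, `pos1`, `pos2` with `pos1 <= pos2`), `chrom_sizes`, and a
#'   `ground_truth` attribute echoing the planted structure.
#' @export
simulate_contact_maps <- function(config, boundaries = NULL,
                                  compartments = NULL, loops = NULL,
                                  cell_types = config$cell_types) {
  validate_sim_config(config)
  if (config$hic_depth < 1) stop("hic_depth must be at least 1")
  g <- config$genome
  check_in_bounds <- function(df, cols) {
    if (is.null(df)) return(invisible(NULL))
    df <- as.data.table(df)
    if (!all(df$chrom %in% g$chrom)) stop("unknown chromosome in planted structure")
    len <- g$length[match(df$chrom, g$chrom)]
    for (cl in cols) {
      if (any(df[[cl]] < 0 | df[[cl]] > len)) {
        stop("planted positions must lie within chromosome bounds")
      }
    }
    df
  }
  boundaries <- check_in_bounds(boundaries, "pos")
  compartments <- check_in_bounds(compartments, c("start", "end"))
  loops <- check_in_bounds(loops, c("a1", "a2"))
  if (!is.null(boundaries) && is.null(boundaries$cell_type)) {
    boundaries[, cell_type := NA_character_]
  }
  if (!is.null(loops) && is.null(loops$cell_type)) {
    loops[, cell_type := NA_character_]
  }

  contacts <- list()
  for (ct in cell_types) {
    contacts[[ct]] <- with_seed(child_seed(config$seed, paste0("hic_", ct)), {
      n_per_chrom <- as.vector(rmultinom(1, config$hic_depth,
                                         prob = g$length / sum(g$length)))
      parts <- lapply(seq_len(nrow(g)), function(ci) {
        b <- if (is.null(boundaries)) numeric(0) else
          boundaries[chrom == g$chrom[ci] &
                     (is.na(cell_type) | cell_type == ct), sort(pos)]
        cmp <- if (is.null(compartments)) NULL else
          compartments[chrom == g$chrom[ci]][order(start)]
        lp <- if (is.null(loops)) NULL else
          loops[chrom == g$chrom[ci] & (is.na(cell_type) | cell_type == ct)]
        sample_chrom_contacts(n_per_chrom[ci], g$length[ci],
                              config$decay_exponent, b, cmp, lp,
                              config$tad_factor, config$comp_factor,
                              g$chrom[ci])
      })
      rbindlist(parts)
    })
  }
  out <- list(contacts = contacts,
              chrom_sizes = setNames(g$length, g$chrom))
  class(out) <- "contact_set"
  attr(out, "ground_truth") <- list(boundaries = boundaries,
                                    compartments = compartments,
                                    loops = loops)
  out
}

# Rejection sampler for one chromosome: propose (distance, position) from the
# pure decay model at 1-kb pixel resolution, thin by the planted structure
# weight, jitter within the pixel. Returns exactly n contacts.
sample_chrom_contacts <- function(n, L, alpha, bpos, comp, loops, tadf, compf,
                                  chrom_label) {
  if (n == 0L) {
    return(data.table(chrom = character(0), pos1 = integer(0), pos2 = integer(0)))
  }
  res <- 1000
  nb <- floor(L / res)
  D <- seq_len(nb - 1L)
  pD <- D^(-alpha) * (nb - D)
  pD <- pD / sum(pD)
  wmax <- (if (length(bpos)) tadf else 1) *
    (if (!is.null(comp) && nrow(comp)) compf else 1) *
    (if (!is.null(loops) && nrow(loops)) max(c(1, loops$fold)) else 1)
  comp_label_at <- function(x) {
    i <- findInterval(x, comp$start)
    ifelse(i >= 1 & x <= comp$end[pmax(i, 1)], comp$label[pmax(i, 1)], NA)
  }
  acc1 <- numeric(0); acc2 <- numeric(0)
  est_acc <- 1 / wmax
  while (length(acc1) < n) {
    m <- min(5e6, ceiling((n - length(acc1)) / est_acc * 1.2) + 1000)
    d <- sample.int(nb - 1L, m, replace = TRUE, prob = pD)
    b1 <- floor(runif(m) * (nb - d))
    b2 <- b1 + d
    x1 <- b1 * res + res / 2
    x2 <- b2 * res + res / 2
    w <- rep(1, m)
    if (length(bpos)) {
      within <- findInterval(x2, bpos) == findInterval(x1, bpos)
      w <- w * ifelse(within, tadf, 1)
    }
    if (!is.null(comp) && nrow(comp)) {
      l1 <- comp_label_at(x1); l2 <- comp_label_at(x2)
      both <- !is.na(l1) & !is.na(l2)
      w[both] <- w[both] * ifelse(l1[both] == l2[both], compf, 1 / compf)
    }
    if (!is.null(loops) && nrow(loops)) {
      if (all(loops$a1 %% 1e4 == 0) && all(loops$a2 %% 1e4 == 0)) {
        # anchors on the 10-kb grid: |x - a| <= 5 kb is round-to-nearest,
        # so the loop lookup is a single keyed match
        key <- paste(round(x1 / 1e4), round(x2 / 1e4))
        hit <- match(key, paste(loops$a1 / 1e4, loops$a2 / 1e4))
        w[!is.na(hit)] <- w[!is.na(hit)] * loops$fold[hit[!is.na(hit)]]
      } else {
        for (i in seq_len(nrow(loops))) {
          hit <- abs(x1 - loops$a1[i]) <= 5000 & abs(x2 - loops$a2[i]) <= 5000
          w[hit] <- w[hit] * loops$fold[i]
        }
      }
    }
    keep <- runif(m) < w / wmax
    acc1 <- c(acc1, b1[keep]); acc2 <- c(acc2, b2[keep])
    est_acc <- max(sum(keep) / m, 1e-4)
  }
  acc1 <- acc1[seq_len(n)]; acc2 <- acc2[seq_len(n)]
  p1 <- as.integer(acc1 * res + floor(runif(n) * res))
  p2 <- as.integer(acc2 * res + floor(runif(n) * res))
  data.table(chrom = chrom_label, pos1 = pmin(p1, p2), pos2 = pmax(p1, p2))
}

#' Derive TAD intervals from a boundary list
#'
#' TADs are the intervals between consecutive boundaries on each chromosome
#' (chromosome ends act as implicit boundaries).
#'
#' @param boundaries data.frame with `chrom`, `pos` (optionally filtered to
#'   one cell type beforehand).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return data.table with `chrom`, `start`, `end`.
#' @export
tads_from_boundaries <- function(boundaries, chrom_sizes) {
  b <- as.data.table(boundaries)
  parts <- lapply(names(chrom_sizes), function(cc) {
    pos <- sort(unique(c(0, b[chrom == cc, pos], chrom_sizes[[cc]])))
    data.table(chrom = cc, start = head(pos, -1), end = tail(pos, -1))
  })
  rbindlist(parts)
}

#' @export
print.contact_set <- function(x, ...) {
  n <- vapply(x$contacts, nrow, integer(1))
  cat("<contact_set>", length(x$contacts), "cell type(s):",
      paste(sprintf("%s=%s", names(n), format(n, big.mark = ",")),
            collapse = ", "), "\n")
  invisible(x)
}
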