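# Bin a contact list into a symmetric dense matrix at `res`.
bin_contact_matrix <- function(dt, L, res) {
  nb <- ceiling(L / res)
  b1 <- pmin(dt$pos1 %/% res, nb - 1L) + 1L
  b2 <- pmin(dt$pos2 %/% res, nb - 1L) + 1L
  m <- matrix(0, nb, nb)
  tab <- data.table(i = pmin(b1, b2), j = pmax(b1, b2))[, .N, by = .(i, j)]
  m[cbind(tab$i, tab$j)] <- tab$N
  m[cbind(tab$j, tab$i)] <- tab$N
  m[cbind(tab$i, tab$j)[tab$i == tab$j, , drop = FALSE]] <- tab$N[tab$i == tab$j]
  m
}

# Observed/expected normalization: each diagonal divided by its mean.
oe_normalize <- function(m) {
  nb <- nrow(m)
  oe <- m
  for (d in 0:(nb - 1)) {
    i <- seq_len(nb - d)
    idx <- cbind(i, i + d)
    mu <- mean(m[idx])
    if (mu > 0) {
      oe[idx] <- m[idx] / mu
      oe[idx[, c(2, 1), drop = FALSE]] <- oe[idx]
    }
  }
  oe
}

#' A/B compartment assignment from the dominant eigenvector
#'
#' Contacts are binned at `res`, normalized to observed/expected by diagonal,
#' converted to a Pearson correlation matrix, and the leading eigenvector is
#' extracted per chromosome. The eigenvector is scaled by the square root of
#' the leading eigenvalue's share of the matrix dimension, so structureless
#' (decay-only) maps yield near-zero magnitudes and are flagged low
#' confidence. The global sign per chromosome is chosen so that the
#' eigenvector correlates positively with `orientation` (e.g. accessibility
#' density per bin); label A is assigned to positive entries.
#'
#' @param contacts Contact table or `contact_set`.
#' @param chrom_sizes Named chromosome lengths.
#' @param res Bin size (bp).
#' @param orientation Optional data.frame (`chrom`, `start`, `value`) used to
#'   orient the sign.
#' @param min_share Minimum leading-eigenvalue share (of the bin count) below
#'   which the chromosome is flagged low confidence; structureless maps sit
#'   around 0.02, genuine compartmentalization well above 0.1.
#' @param cell_type Cell type when a `contact_set` is given.
#' @return `compartment_track`: data.table with `chrom`, `start`, `end`,
#'   `E1`, `label`, `low_confidence`.
#' @export
compartments <- function(contacts, chrom_sizes = NULL, res = 250e3,
                         orientation = NULL, cell_type = NULL,
                         min_share = 0.1) {
  if (inherits(contacts, "contact_set") && is.null(chrom_sizes)) {
    chrom_sizes <- contacts$chrom_sizes
  }
  dt <- as_contacts(contacts, cell_type)
  orientation <- if (!is.null(orientation)) as.data.table(orientation)
  parts <- lapply(unique(dt$chrom), function(cc) {
    sub <- dt[chrom == cc]
    nb <- ceiling(chrom_sizes[[cc]] / res)
    if (nb < 4) stop("need at least 4 bins per chromosome")
    m <- bin_contact_matrix(sub, chrom_sizes[[cc]], res)
    oe <- oe_normalize(m)
    keep <- which(apply(oe, 2, sd) > 0)
    if (length(keep) < 4) {
      warning("chromosome ", cc, " has a degenerate contact matrix; skipped")
      return(NULL)
    }
    cm <- suppressWarnings(cor(oe[keep, keep]))
    cm[!is.finite(cm)] <- 0
    eg <- eigen(cm, symmetric = TRUE)
    share <- max(eg$values[1], 0) / length(keep)
    e1 <- rep(NA_real_, nb)
    e1[keep] <- eg$vectors[, 1] * sqrt(share) * sqrt(length(keep))
    if (!is.null(orientation)) {
      ov <- orientation[chrom == cc]
      ref <- vapply(seq_len(nb) - 1L, function(b) {
        v <- ov[start %/% res == b, value]
        if (length(v)) sum(v) else NA_real_
      }, numeric(1))
      cr <- suppressWarnings(cor(e1, ref, use = "pairwise.complete.obs"))
      if (is.finite(cr) && cr < 0) e1 <- -e1
    } else if (sum(e1 > 0, na.rm = TRUE) < sum(e1 < 0, na.rm = TRUE)) {
      e1 <- -e1  # deterministic default orientation
    }
    data.table(chrom = cc, start = (seq_len(nb) - 1L) * res,
               end = pmin(seq_len(nb) * res, chrom_sizes[[cc]]),
               E1 = e1, label = ifelse(e1 > 0, "A", "B"),
               low_confidence = share < min_share)
  })
  out <- rbindlist(Filter(Negate(is.null), parts))
  setattr(out, "res", res)
  setattr(out, "class", c("compartment_track", class(out)))
  out[]
}

#' Compartment strength and saddle matrix
#'
#' Over intrachromosomal bin pairs separated by at least `min_dist`, computes
#' the strength `S = (mean AA + mean BB) / (2 * mean AB)` where each term is
#' the mean observed contact count per qualifying bin pair of that label
#' combination (per-pair means make S invariant to the number of A and B
#' bins). Also returns a saddle matrix: bins ranked by E1 into
#' `n_quantiles` quantiles, mean log2 observed/expected per quantile pair,
#' where the expected count of a bin pair is the mean count at its distance.
#'
#' @param contacts Contact table or `contact_set`.
#' @param comp A [compartments()] track.
#' @param chrom_sizes Named chromosome lengths.
#' @param min_dist Minimum pair separation (bp).
#' @param n_quantiles Saddle quantiles.
#' @param cell_type Cell type when a `contact_set` is given.
#' @return List with `S`, `saddle` (n_quantiles x n_quantiles matrix) and
#'   the per-class means.
#' @export
compartment_strength <- function(contacts, comp, chrom_sizes = NULL,
                                 min_dist = 10e6, n_quantiles = 5,
                                 cell_type = NULL) {
  if (inherits(contacts, "contact_set") && is.null(chrom_sizes)) {
    chrom_sizes <- contacts$chrom_sizes
  }
  dt <- as_contacts(contacts, cell_type)
  res <- attr(comp, "res") %||% 250e3
  sums <- list(AA = 0, BB = 0, AB = 0)
  npairs <- list(AA = 0, BB = 0, AB = 0)
  saddle_num <- matrix(0, n_quantiles, n_quantiles)
  saddle_den <- matrix(0, n_quantiles, n_quantiles)
  any_valid <- FALSE
  for (cc in unique(dt$chrom)) {
    cmp <- comp[chrom == cc]
    if (!nrow(cmp)) next
    nb <- nrow(cmp)
    L <- chrom_sizes[[cc]]
    if (L <= min_dist) next
    m <- bin_contact_matrix(dt[chrom == cc], L, res)
    lab <- cmp$label
    dmin_bins <- ceiling(min_dist / res)
    ij <- which(upper.tri(m), arr.ind = TRUE)
    ij <- ij[ij[, 2] - ij[, 1] >= dmin_bins, , drop = FALSE]
    if (!nrow(ij)) next
    li <- lab[ij[, 1]]; lj <- lab[ij[, 2]]
    ok <- !is.na(li) & !is.na(lj)
    ij <- ij[ok, , drop = FALSE]; li <- li[ok]; lj <- lj[ok]
    cls <- ifelse(li == lj, ifelse(li == "A", "AA", "BB"), "AB")
    v <- m[ij]
    for (cl in c("AA", "BB", "AB")) {
      sums[[cl]] <- sums[[cl]] + sum(v[cls == cl])
      npairs[[cl]] <- npairs[[cl]] + sum(cls == cl)
    }
    any_valid <- TRUE
    # saddle: expected = mean count at the pair's distance
    dbin <- ij[, 2] - ij[, 1]
    expd <- vapply(sort(unique(dbin)), function(d) {
      i <- seq_len(nb - d); mean(m[cbind(i, i + d)])
    }, numeric(1))
    names(expd) <- sort(unique(dbin))
    e <- expd[as.character(dbin)]
    qrk <- cut(rank(comp[chrom == cc, E1], ties.method = "first",
                    na.last = "keep"),
               breaks = n_quantiles, labels = FALSE)
    qi <- qrk[ij[, 1]]; qj <- qrk[ij[, 2]]
    ok2 <- !is.na(qi) & !is.na(qj) & e > 0
    for (r in which(ok2)) {
      a <- min(qi[r], qj[r]); b <- max(qi[r], qj[r])
      saddle_num[a, b] <- saddle_num[a, b] + v[r] / e[r]
      saddle_den[a, b] <- saddle_den[a, b] + 1
    }
  }
  if (!any_valid || any(unlist(npairs) == 0)) {
    warning("no qualifying bin pairs with both compartment labels; S undefined")
    return(list(S = NA_real_, saddle = NULL, means = NULL))
  }
  means <- vapply(c("AA", "BB", "AB"),
                  function(cl) sums[[cl]] / npairs[[cl]], numeric(1))
  S <- (means[["AA"]] + means[["BB"]]) / (2 * means[["AB"]])
  saddle <- log2(saddle_num / saddle_den)
  saddle[lower.tri(saddle)] <- t(saddle)[lower.tri(saddle)]
  list(S = unname(S), saddle = saddle, means = means)
}
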