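#' Write a cell_data object to MTX + TSV sidecars
#'
#' Counts go to MatrixMarket files (`rna.mtx`, `atac.mtx`, features x cells),
#' annotations and metadata to TSVs, and the planted ground truth (if any)
#' to a JSON sidecar.
#'
#' @param cells A `cell_data` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_data <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(cells$rna), sparse = TRUE),
                  file.path(dir, "rna.mtx"))
  Matrix::writeMM(Matrix::Matrix(t(cells$atac), sparse = TRUE),
                  file.path(dir, "atac.mtx"))
  fwrite(data.table(id = colnames(cells$rna)), file.path(dir, "genes.tsv"),
         sep = "\t", col.names = FALSE)
  fwrite(data.table(id = colnames(cells$atac)), file.path(dir, "peaks.tsv"),
         sep = "\t", col.names = FALSE)
  fwrite(cells$cell_meta, file.path(dir, "cell_meta.tsv"), sep = "\t")
  fwrite(cells$genes, file.path(dir, "gene_annotation.tsv"), sep = "\t")
  fwrite(cells$peaks[, .(chrom, start, end, peak_id)],
         file.path(dir, "peaks.bed"), sep = "\t", col.names = FALSE)
  gt <- ground_truth(cells)
  if (!is.null(gt)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         dataframe = "rows", digits = NA)
  }
  invisible(dir)
}

#' Read / write contact lists as TSV
#'
#' @param contacts Contact table (`chrom`, `pos1`, `pos2`, ...).
#' @param path File path.
#' @return `read_contacts` returns a data.table; `write_contacts` the path.
#' @export
write_contacts <- function(contacts, path) {
  fwrite(as.data.table(contacts), path, sep = "\t")
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  dt <- fread(path)
  stop_missing_column(dt, c("chrom", "pos1", "pos2"), "contact file")
  dt
}

#' Write an EGP table as TSV with parameter header comments
#'
#' @param egps An [link_peaks_to_genes()] table.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_egp_table <- function(egps, path) {
  params <- attr(egps, "params")
  hdr <- c(
    sprintf("# params: %s", jsonlite::toJSON(params[setdiff(names(params), "seed")],
                                             auto_unbox = TRUE)),
    sprintf("# seed: %s", params$seed %||% NA))
  writeLines(hdr, path)
  fwrite(as.data.table(egps), path, sep = "\t", append = TRUE,
         col.names = TRUE)
  invisible(path)
}

#' Write an MPRA design as FASTA plus a TSV manifest
#'
#' The FASTA records contain the 4-bp category tag prepended to each
#' designed sequence.
#'
#' @param design A [design_library()] (or [simulate_mpra_design()]) table.
#' @param fasta_path,manifest_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_mpra_design <- function(design, fasta_path, manifest_path = NULL) {
  design <- as.data.table(design)
  seqs <- Biostrings::DNAStringSet(paste0(design$tag, design$sequence))
  names(seqs) <- design$cre_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(manifest_path)) {
    fwrite(design[, setdiff(names(design), "sequence"), with = FALSE],
           manifest_path, sep = "\t")
  }
  invisible(fasta_path)
}
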