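#' Write a count matrix as Matrix Market plus gene/cell TSVs
#'
#' Emits `matrix.mtx`, `genes.tsv` (one id per line) and `cells.tsv` in
#' `dir`. The round trip through [read_count_matrix()] is integer-exact.
#'
#' @param counts genes x cells integer matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  paths[1])
  writeLines(rownames(counts), paths[2])
  writeLines(colnames(counts), paths[3])
  invisible(paths)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return dense integer matrix with gene/cell dimnames.
#' @export
read_count_matrix <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "cells.tsv"))
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("matrix dimensions do not match genes.tsv/cells.tsv")
  if (anyDuplicated(genes))
    stop("duplicate gene id: ", genes[duplicated(genes)][1])
  if (anyDuplicated(cells))
    stop("duplicate cell id: ", cells[duplicated(cells)][1])
  if (!is_whole(m)) stop("non-integer counts in matrix.mtx")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, cells)
  m
}

#' Read cell metadata from TSV
#'
#' @param path TSV with header; must contain a unique `cell_id` column.
#' @return data.frame.
#' @export
read_cell_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"cell_id" %in% names(md)) stop("metadata lacks a cell_id column")
  if (anyDuplicated(md$cell_id)) {
    d <- md$cell_id[duplicated(md$cell_id)][1]
    line <- which(md$cell_id == d)[2] + 1L
    stop("duplicate cell_id '", d, "' (line ", line, ")")
  }
  md
}

#' Write a data.frame as TSV (lossless string round trip)
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
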