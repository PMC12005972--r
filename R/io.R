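#' Write / read a count matrix as MTX plus TSV metadata
#'
#' Sparse counts in MatrixMarket format with `genes.tsv` (gene metadata) and
#' `cells.tsv` (cell metadata) alongside; round-trips the
#' `SingleCellExperiment` produced by [build_count_matrix()].
#'
#' @param sce Count matrix.
#' @param dir Output directory (created if needed).
#' @return `write_count_matrix()` returns `dir` invisibly;
#'   `read_count_matrix()` returns the `SingleCellExperiment`.
#' @export
write_count_matrix <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(SummarizedExperiment::assay(sce, "counts"),
                  file.path(dir, "counts.mtx"))
  utils::write.table(as.data.frame(SummarizedExperiment::rowData(sce)),
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::colData(sce)),
                     file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes$gene, as.character(cells$cell))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cells, row.names = as.character(cells$cell)),
    rowData = S4Vectors::DataFrame(genes, row.names = genes$gene))
}
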