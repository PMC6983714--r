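#' Assemble a raw count container
#'
#' Wraps a genes x cells integer count matrix, per-gene technical flags and
#' per-cell read-mapping metadata into a [SingleCellExperiment] object, the
#' container every downstream stage of the pipeline consumes. Gene flags mark
#' mitochondrial genes (used for the mitochondrial-fraction QC rule) and
#' exogenous spike-in transcripts (ERCC-style technical controls, used for the
#' spike-in-fraction rule and excluded from size-factor estimation).
#'
#' @param counts genes x cells matrix of non-negative integer counts (dense or
#'   sparse); must carry gene and cell names.
#' @param gene_flags data.frame with columns `gene_id`, `is_mito`,
#'   `is_spikein` and optionally `gene_name`; one row per gene, same order as
#'   `counts`.
#' @param cell_meta data.frame with columns `cell_id`, `total_reads`,
#'   `mapped_reads`; one row per cell, same order as `counts`. `total_reads`
#'   counts all sequenced reads of the cell's library; `mapped_reads` those
#'   aligned to the genome, so `mapped_reads <= total_reads`.
#' @return A `SingleCellExperiment` with assay `"counts"`, `rowData` columns
#'   `gene_name`, `is_mito`, `is_spikein` and `colData` columns `total_reads`,
#'   `mapped_reads`.
#' @export
count_matrix <- function(counts, gene_flags, cell_meta) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids in counts")
  if (any(counts@x < 0)) stop("negative values in counts")
  if (any(counts@x != round(counts@x))) stop("non-integer values in counts")
  stopifnot(is.data.frame(gene_flags), is.data.frame(cell_meta))
  if (nrow(gene_flags) != nrow(counts))
    stop("gene_flags rows (", nrow(gene_flags), ") != genes (", nrow(counts), ")")
  if (nrow(cell_meta) != ncol(counts))
    stop("cell_meta rows (", nrow(cell_meta), ") != cells (", ncol(counts), ")")
  if (!identical(as.character(gene_flags$gene_id), rownames(counts)))
    stop("gene_flags$gene_id does not match rownames(counts)")
  if (!identical(as.character(cell_meta$cell_id), colnames(counts)))
    stop("cell_meta$cell_id does not match colnames(counts)")
  if (any(cell_meta$mapped_reads > cell_meta$total_reads))
    stop("mapped_reads exceeds total_reads for some cells")
  gene_name <- if (is.null(gene_flags$gene_name)) gene_flags$gene_id else
    gene_flags$gene_name
  SingleCellExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(gene_name = as.character(gene_name),
                        is_mito = as.logical(gene_flags$is_mito),
                        is_spikein = as.logical(gene_flags$is_spikein),
                        row.names = rownames(counts)),
    colData = DataFrame(total_reads = as.numeric(cell_meta$total_reads),
                        mapped_reads = as.numeric(cell_meta$mapped_reads),
                        row.names = colnames(counts)))
}

#' @rdname count_matrix
#' @param x a `SingleCellExperiment` built by [count_matrix()].
#' @export
is_spikein <- function(x) rowData(x)$is_spikein

#' @rdname count_matrix
#' @export
is_mito <- function(x) rowData(x)$is_mito
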