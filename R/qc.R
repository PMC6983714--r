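#' QC thresholds for plate-based single-cell libraries
#'
#' Default thresholds reproduce the six cell filters of the analyzed study:
#' more than 4.5 log10 total counts, between 2.7 and 3.9 log10 features
#' detected with more than one read, under 50% of counts in the 50 most
#' expressed genes, under 20% mitochondrial counts, under 25% spike-in
#' counts, and more than 20% of reads mapped to the genome. All comparisons
#' are strict, matching the more-than/less-than wording of the rules, so
#' boundary values fail.
#'
#' @param min_log10_total,min_log10_features,max_log10_features,max_frac_top50,max_frac_mito,max_frac_spikein,min_frac_mapped
#'   per-rule cutoffs.
#' @param min_cells_per_gene gene filter: minimum number of cells in which a
#'   gene must be detected (count > 0).
#' @return list of thresholds with class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_log10_total = 4.5, min_log10_features = 2.7,
                          max_log10_features = 3.9, max_frac_top50 = 0.5,
                          max_frac_mito = 0.2, max_frac_spikein = 0.25,
                          min_frac_mapped = 0.2, min_cells_per_gene = 3L) {
  stopifnot(min_log10_features < max_log10_features,
            max_frac_top50 > 0, max_frac_top50 <= 1,
            max_frac_mito > 0, max_frac_mito <= 1,
            max_frac_spikein > 0, max_frac_spikein <= 1,
            min_frac_mapped >= 0, min_frac_mapped < 1,
            min_cells_per_gene >= 0)
  structure(list(min_log10_total = min_log10_total,
                 min_log10_features = min_log10_features,
                 max_log10_features = max_log10_features,
                 max_frac_top50 = max_frac_top50,
                 max_frac_mito = max_frac_mito,
                 max_frac_spikein = max_frac_spikein,
                 min_frac_mapped = min_frac_mapped,
                 min_cells_per_gene = as.integer(min_cells_per_gene)),
            class = "qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' Computes, from the raw count matrix, the quantities the cell filters act
#' on: log10 total counts, log10 number of features with more than one read,
#' fraction of counts in the 50 most expressed genes of the cell, fractions
#' of counts on mitochondrial and spike-in genes, and the mapped-read
#' fraction from the cell metadata. Cells with zero total counts receive
#' `-Inf` log metrics and zero fractions (they fail the filters downstream
#' rather than erroring; empty wells are legitimate on plates).
#'
#' @param m a [count_matrix()] `SingleCellExperiment`.
#' @return data.frame with one row per cell: `cell_id`, `log10_total`,
#'   `log10_features_gt1`, `frac_top50`, `frac_mito`, `frac_spikein`,
#'   `frac_mapped`.
#' @export
compute_qc_metrics <- function(m) {
  stopifnot(ncol(m) > 0)
  cnt <- counts(m)
  total <- Matrix::colSums(cnt)
  feats <- Matrix::colSums(cnt > 1)
  top50 <- vapply(seq_len(ncol(cnt)), function(j) {
    v <- cnt[, j]
    sum(sort(as.numeric(v), decreasing = TRUE)[seq_len(min(50, length(v)))])
  }, numeric(1))
  mito <- Matrix::colSums(cnt[is_mito(m), , drop = FALSE])
  spike <- Matrix::colSums(cnt[is_spikein(m), , drop = FALSE])
  safe_frac <- function(num) ifelse(total > 0, num / total, 0)
  data.frame(
    cell_id = colnames(m),
    log10_total = ifelse(total > 0, log10(total), -Inf),
    log10_features_gt1 = ifelse(feats > 0, log10(feats), -Inf),
    frac_top50 = safe_frac(top50),
    frac_mito = safe_frac(mito),
    frac_spikein = safe_frac(spike),
    frac_mapped = ifelse(colData(m)$total_reads > 0,
                         colData(m)$mapped_reads / colData(m)$total_reads, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the six cell filters
#'
#' A cell is retained iff all six rules hold with strict inequalities. The
#' returned table enumerates, per cell, every violated rule.
#'
#' @param q metrics from [compute_qc_metrics()].
#' @param t thresholds from [qc_thresholds()].
#' @return list with `retained` (character vector of retained cell ids) and
#'   `report` (data.frame `cell_id`, `retained`, `reasons`; `reasons` is a
#'   comma-separated list of violated rules, empty when retained).
#' @export
filter_cells <- function(q, t = qc_thresholds()) {
  stopifnot(inherits(t, "qc_thresholds"))
  rules <- cbind(
    low_total = q$log10_total > t$min_log10_total,
    few_features = q$log10_features_gt1 > t$min_log10_features,
    many_features = q$log10_features_gt1 < t$max_log10_features,
    top50 = q$frac_top50 < t$max_frac_top50,
    mito = q$frac_mito < t$max_frac_mito,
    spikein = q$frac_spikein < t$max_frac_spikein,
    unmapped = q$frac_mapped > t$min_frac_mapped)
  keep <- rowSums(!rules) == 0
  reasons <- apply(!rules, 1, function(v)
    paste(colnames(rules)[v], collapse = ","))
  list(retained = q$cell_id[keep],
       report = data.frame(cell_id = q$cell_id, retained = keep,
                           reasons = reasons, row.names = NULL,
                           stringsAsFactors = FALSE))
}

#' Gene detection filter
#'
#' Retains genes detected (count > 0) in at least `min_cells` cells. Note
#' the deliberate asymmetry with the cell-level feature rule, which counts
#' features with *more than one* read.
#'
#' @param m a [count_matrix()] `SingleCellExperiment`.
#' @param min_cells minimum number of cells with nonzero count.
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(m, min_cells = 3L) {
  stopifnot(min_cells >= 0)
  det <- Matrix::rowSums(counts(m) > 0)
  rownames(m)[det >= min_cells]
}

#' Run cell then gene filtering
#'
#' Convenience wrapper: computes metrics, filters cells, then re-evaluates
#' gene detection on the retained cells (so detection counts reflect the
#' analyzed cells). Idempotent: re-running on its output changes nothing.
#'
#' @inheritParams filter_cells
#' @param m a [count_matrix()] `SingleCellExperiment`.
#' @return list with the filtered `sce`, the QC `metrics`, and the
#'   `cell_report` from [filter_cells()].
#' @export
apply_qc <- function(m, t = qc_thresholds()) {
  q <- compute_qc_metrics(m)
  fc <- filter_cells(q, t)
  kept <- m[, fc$retained]
  genes <- filter_genes(kept, t$min_cells_per_gene)
  list(sce = kept[genes, ], metrics = q, cell_report = fc$report)
}
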