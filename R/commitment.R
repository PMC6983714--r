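#' Classify proliferating versus quiescent radial glia
#'
#' A radial glia cell is called proliferative when it carries at least
#' `min_reads` raw reads of the classifier gene (default `ccnd1`, a
#' G1-phase cyclin expressed throughout the cell cycle), quiescent
#' otherwise.
#'
#' @param raw a [count_matrix()] `SingleCellExperiment` or genes x cells
#'   count matrix.
#' @param rg_cells cell ids of the RG cluster.
#' @param gene classifier gene id.
#' @param min_reads read threshold for the proliferative call.
#' @return data.frame `cell_id`, `state` (factor, proliferative/quiescent).
#' @export
classify_proliferative <- function(raw, rg_cells, gene = "ccnd1",
                                   min_reads = 1L) {
  cnt <- if (is(raw, "SingleCellExperiment")) counts(raw) else raw
  if (!gene %in% rownames(cnt))
    stop("classifier gene '", gene, "' absent from the count matrix")
  stopifnot(all(rg_cells %in% colnames(cnt)))
  v <- as.numeric(cnt[gene, rg_cells])
  data.frame(cell_id = rg_cells,
             state = factor(ifelse(v >= min_reads, "proliferative",
                                   "quiescent"),
                            levels = c("proliferative", "quiescent")),
             reads = v, row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation of one gene list in another
#'
#' Upper-tail hypergeometric probability `P(X >= overlap)` with
#' `X ~ Hypergeom(universe, |a|, |b|)`: the chance of at least the observed
#' overlap when `|b|` genes are drawn from the universe at random.
#'
#' @param list_a,list_b gene sets drawn from the same universe.
#' @param universe universe size (number of genes both lists were ranked
#'   from).
#' @return list with `overlap`, `p_value`, and the input sizes.
#' @export
hypergeometric_overlap <- function(list_a, list_b, universe) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  if (length(list_a) > universe || length(list_b) > universe)
    stop("list larger than the universe")
  k <- length(intersect(list_a, list_b))
  p <- phyper(k - 1, length(list_a), universe - length(list_a),
              length(list_b), lower.tail = FALSE)
  list(overlap = k, p_value = p, n_a = length(list_a),
       n_b = length(list_b), universe = universe)
}

#' Neurogenic panel score
#'
#' Per-cell count of detected genes (raw count > 0) among a curated panel of
#' neurogenic fate determinants (default `ascl1a`, `sox4a`, `tmsb`,
#' `stmn1b`).
#'
#' @inheritParams classify_proliferative
#' @param cells cell ids to score.
#' @param panel panel gene ids; all must be present in the matrix.
#' @return data.frame `cell_id`, `score` (0..length(panel)).
#' @export
panel_score <- function(raw, cells, panel = c("ascl1a", "sox4a", "tmsb",
                                              "stmn1b")) {
  cnt <- if (is(raw, "SingleCellExperiment")) counts(raw) else raw
  missing <- setdiff(panel, rownames(cnt))
  if (length(missing))
    stop("panel gene(s) absent: ", paste(missing, collapse = ", "))
  stopifnot(all(cells %in% colnames(cnt)))
  sub <- cnt[panel, cells, drop = FALSE]
  data.frame(cell_id = cells,
             score = as.integer(Matrix::colSums(sub > 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare panel scores between proliferative and quiescent RG
#'
#' One-sided Wilcoxon rank-sum test of the hypothesis that proliferative RG
#' carry higher neurogenic panel scores than quiescent RG, plus the per-group
#' fraction of cells expressing at least two panel genes.
#'
#' @param scores data.frame from [panel_score()].
#' @param call data.frame from [classify_proliferative()].
#' @param exact_max see [wilcoxon_rank_sum()].
#' @return list with `p_value` (one-sided, proliferative > quiescent),
#'   `frac_ge2` (named: proliferative, quiescent), and the group sizes.
#' @export
compare_panel_scores <- function(scores, call, exact_max = 10) {
  m <- merge(scores, call, by = "cell_id")
  sp <- m$score[m$state == "proliferative"]
  sq <- m$score[m$state == "quiescent"]
  if (length(sp) == 0 || length(sq) == 0)
    stop("both proliferative and quiescent groups must be non-empty")
  w <- wilcoxon_rank_sum(sp, sq, alternative = "greater",
                         exact_max = exact_max)
  list(p_value = w$p_value,
       frac_ge2 = c(proliferative = mean(sp >= 2),
                    quiescent = mean(sq >= 2)),
       n = c(proliferative = length(sp), quiescent = length(sq)))
}

#' Neurogenic-commitment analysis of the RG cluster
#'
#' Orchestrates the commitment statistics: classifies proliferating RG by
#' the classifier gene, runs differential expression between the two RG
#' states, takes the top `n_top` genes higher expressed in proliferative RG
#' (ascending p among genes with positive direction), tests their overlap
#' with a reference marker list (e.g. the top NBN.1 markers) by the
#' hypergeometric test, and compares panel scores between the states.
#'
#' @param raw raw [count_matrix()] `SingleCellExperiment` (filtered).
#' @param norm matching log-normalized `SingleCellExperiment` or matrix.
#' @param rg_cells RG-cluster cell ids.
#' @param reference_markers gene list to test over-representation against;
#'   `NULL` skips the overlap test.
#' @param panel neurogenic panel gene ids.
#' @param gene classifier gene.
#' @param n_top genes taken from the proliferative-up ranking.
#' @return list with `call`, `de`, `top_proliferative`, `overlap` and
#'   `panel_comparison`.
#' @export
commitment_analysis <- function(raw, norm, rg_cells,
                                reference_markers = NULL,
                                panel = c("ascl1a", "sox4a", "tmsb",
                                          "stmn1b"),
                                gene = "ccnd1", n_top = 100) {
  call <- classify_proliferative(raw, rg_cells, gene = gene)
  prolif <- call$cell_id[call$state == "proliferative"]
  quies <- call$cell_id[call$state == "quiescent"]
  de <- pairwise_wilcoxon(norm, prolif, quies)
  up <- de[de$direction == "up", ]
  up <- up[order(up$p_value, -abs(up$log_fold_change)), ]
  top_up <- head(up$gene_id, n_top)
  overlap <- if (!is.null(reference_markers)) {
    nr <- if (is(raw, "SingleCellExperiment")) nrow(raw) else nrow(raw)
    hypergeometric_overlap(top_up, reference_markers, universe = nr)
  } else NULL
  sc <- panel_score(raw, rg_cells, panel)
  cmp <- compare_panel_scores(sc, call)
  list(call = call, de = de, top_proliferative = top_up, overlap = overlap,
       panel_scores = sc, panel_comparison = cmp)
}
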