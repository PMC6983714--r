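#' Default pipeline configuration
#'
#' All tunable stage parameters of the lineage and cross-species workflows,
#' with the defaults the pipeline was designed around. The configuration
#' round-trips through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]); unknown keys are rejected on read so typos
#' cannot silently fall back to defaults.
#'
#' @return nested list of stage parameter sections.
#' @export
pipeline_config <- function() {
  list(
    qc = unclass(qc_thresholds()),
    normalize = list(pool_sizes = c(21, 26, 31, 36, 41),
                     hvg_max_mean = 8, hvg_min_mean = 0.0125,
                     hvg_min_disp = 0.5, hvg_n_bins = 20),
    manifold = list(n_pcs = 10, k_graph = 10, k_sigma = 5,
                    resolution = 0.5, n_comps = 15, seed = 0,
                    drop_disconnected = TRUE),
    markers = list(l2_strength = 0.1, window = 15),
    commitment = list(gene = "ccnd1", min_reads = 1, n_top = 100,
                      panel = c("ascl1a", "sox4a", "tmsb", "stmn1b")),
    crossmap = list(n_pcs = 50, n_top_pairs = 1000, quantile = 0.66,
                    linkage = "complete", normalization = "per_cell"))
}

.check_keys <- function(x, ref, path = "") {
  extra <- setdiff(names(x), names(ref))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  for (nm in names(x))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      .check_keys(x[[nm]], ref[[nm]], paste0(path, nm, "$"))
  invisible(TRUE)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  ref <- pipeline_config()
  .check_keys(user, ref)
  for (sec in names(user))
    for (key in names(user[[sec]]))
      ref[[sec]][[key]] <- user[[sec]][[key]]
  ref
}

#' @rdname pipeline_config
#' @param config a configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a raw count matrix with sidecars
#'
#' Matrix Market (`matrix.mtx` + `genes.tsv` + `cells.tsv` in a directory)
#' or a dense TSV (gene rows, cell columns, first column gene ids) with the
#' same sidecars. The genes sidecar carries `gene_id`, `gene_name`,
#' `is_mito`, `is_spikein`; the cells sidecar `cell_id`, `total_reads`,
#' `mapped_reads`. Orientation is enforced to genes x cells;
#' `transpose = TRUE` declares the on-disk matrix as cells x genes.
#'
#' @param path directory (MTX) or TSV file.
#' @param format `"mtx"` or `"tsv"`.
#' @param transpose the on-disk matrix is cells x genes.
#' @return a [count_matrix()] `SingleCellExperiment`.
#' @export
read_count_matrix <- function(path, format = c("mtx", "tsv"),
                              transpose = FALSE) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir <- path
    mm <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
    cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    mm <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mm) <- tab[[1]]
    dir <- dirname(path)
    genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
    cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  }
  if (transpose) mm <- Matrix::t(mm)
  if (nrow(genes) != nrow(mm))
    stop("dimension mismatch: genes sidecar has ", nrow(genes),
         " rows, matrix has ", nrow(mm), " genes")
  if (nrow(cells) != ncol(mm))
    stop("dimension mismatch: cells sidecar has ", nrow(cells),
         " rows, matrix has ", ncol(mm), " cells")
  rownames(mm) <- genes$gene_id
  colnames(mm) <- cells$cell_id
  count_matrix(mm, genes, cells)
}

#' @rdname read_count_matrix
#' @param m a [count_matrix()] `SingleCellExperiment`.
#' @param dir output directory (created if missing).
#' @export
write_count_matrix <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(counts(m), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  genes <- data.frame(gene_id = rownames(m),
                      gene_name = rowData(m)$gene_name,
                      is_mito = rowData(m)$is_mito,
                      is_spikein = rowData(m)$is_spikein)
  cells <- data.frame(cell_id = colnames(m),
                      total_reads = colData(m)$total_reads,
                      mapped_reads = colData(m)$mapped_reads)
  write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# deterministic content hash for manifests (polynomial rolling hash over a
# subsample of the serialized object)
.content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  sub <- bytes[seq(1, length(bytes), by = max(1, length(bytes) %/% 4096))]
  h <- 0
  for (b in sub) h <- (h * 131 + b) %% 2147483647
  sprintf("%d-%d", h, length(bytes))
}

.manifest <- function(stage, params, inputs, seed = NA) {
  list(stage = stage, params = params,
       input_hash = .content_hash(inputs), seed = seed)
}

#' Run the lineage workflow end to end
#'
#' QC filtering, deconvolution normalization, HVG selection, scaling, PCA,
#' kNN graph, Louvain clustering, diffusion map and diffusion pseudotime,
#' marker detection and the neurogenic-commitment statistics, with a
#' manifest per stage recording parameters and input hashes so runs are
#' exactly reproducible.
#'
#' Cluster roles are resolved from the root cell: the RG cluster is the
#' cluster containing the root, and the NBN.1 cluster is the non-RG cluster
#' with the lowest mean pseudotime (the state closest to RG). When
#' `drop_disconnected` is set, the cluster most isolated in the kNN graph
#' (under 5% of its edge endpoints leaving the cluster) is excluded from the
#' trajectory, mirroring the exclusion of the transcriptionally disconnected
#' OPCs.
#'
#' @param m raw [count_matrix()] `SingleCellExperiment`.
#' @param config a [pipeline_config()] list.
#' @param root_cell trajectory root cell id; if `NULL`, the cell with the
#'   highest total log-normalized expression of `root_markers` is used.
#' @param root_markers marker genes used to pick the root (e.g. RG markers).
#' @return list of stage outputs (`qc`, `size_factors`, `norm`, `hvg`,
#'   `pca`, `knn`, `clusters`, `trajectory_cells`, `dmap`, `pseudotime`,
#'   `root_cell`, `rg_cluster`, `nbn1_cluster`, `markers`, `commitment`)
#'   plus `manifests`.
#' @export
run_lineage <- function(m, config = pipeline_config(), root_cell = NULL,
                        root_markers = NULL) {
  manifests <- list()
  thr <- do.call(qc_thresholds, config$qc)
  qc <- apply_qc(m, thr)
  filt <- qc$sce
  manifests$qc <- .manifest("qc", config$qc, m)

  sf <- deconvolution_size_factors(filt, config$normalize$pool_sizes)
  norm <- lognormalize(filt, sf)
  hvg <- select_hvg(norm, max_mean = config$normalize$hvg_max_mean,
                    min_mean = config$normalize$hvg_min_mean,
                    min_disp = config$normalize$hvg_min_disp,
                    n_bins = config$normalize$hvg_n_bins)
  scaled <- scale_unit_variance(norm, hvg$gene_id[hvg$selected])
  manifests$normalize <- .manifest("normalize", config$normalize, filt)

  mf <- config$manifold
  pca <- run_pca(scaled, n_pcs = mf$n_pcs)
  knn <- build_knn_graph(pca$scores, k = mf$k_graph, k_sigma = mf$k_sigma)
  clusters <- louvain_clusters(knn, resolution = mf$resolution,
                               seed = mf$seed)
  manifests$manifold <- .manifest("manifold", mf, pca$scores, mf$seed)

  # root selection
  if (is.null(root_cell)) {
    if (is.null(root_markers))
      stop("provide root_cell or root_markers")
    rm_use <- intersect(root_markers, rownames(norm))
    score <- colSums(logcounts(norm)[rm_use, , drop = FALSE])
    root_cell <- names(which.max(score))
  }
  rg_cluster <- clusters[[root_cell]]

  # optionally exclude the most isolated cluster from the trajectory
  traj_cells <- colnames(filt)
  dropped <- NULL
  if (isTRUE(mf$drop_disconnected)) {
    ed <- knn$edges
    cl_from <- clusters[ed$from]; cl_to <- clusters[ed$to]
    labs <- sort(unique(clusters))
    out_frac <- vapply(labs, function(cl)
      mean(cl_to[cl_from == cl] != cl), numeric(1))
    iso <- labs[which.min(out_frac)]
    if (min(out_frac) < 0.05 && iso != rg_cluster) {
      dropped <- iso
      traj_cells <- names(clusters)[clusters != iso]
    }
  }
  scores_tr <- pca$scores[traj_cells, , drop = FALSE]
  dmap <- diffusion_map(scores_tr, k_sigma = mf$k_sigma,
                        n_comps = min(mf$n_comps, length(traj_cells) - 1))
  pt <- diffusion_pseudotime(dmap, root_cell)
  nbn1_cluster <- {
    cand <- setdiff(unique(clusters[traj_cells]), rg_cluster)
    if (length(cand)) {
      mp <- vapply(cand, function(cl)
        mean(pt[names(clusters)[clusters == cl & names(clusters) %in%
                                  traj_cells]]), numeric(1))
      cand[which.min(mp)]
    } else NA
  }
  manifests$trajectory <- .manifest("trajectory",
                                    list(root = root_cell,
                                         dropped_cluster = dropped),
                                    scores_tr)

  mk <- marker_genes_logreg(filt, clusters,
                            l2_strength = config$markers$l2_strength,
                            seed = mf$seed)
  commit <- NULL
  cm <- config$commitment
  rg_cells <- names(clusters)[clusters == rg_cluster]
  if (all(c(cm$gene, cm$panel) %in% rownames(filt)) &&
      length(rg_cells) >= 4) {
    ref <- if (!is.na(nbn1_cluster))
      head(mk$gene_id[mk$cluster == nbn1_cluster], cm$n_top) else NULL
    commit <- tryCatch(
      commitment_analysis(filt, norm, rg_cells, reference_markers = ref,
                          panel = cm$panel, gene = cm$gene,
                          n_top = cm$n_top),
      error = function(e) {
        warning("commitment stage skipped: ", conditionMessage(e))
        NULL
      })
  }
  manifests$markers <- .manifest("markers", config$markers, filt, mf$seed)

  list(qc = qc, size_factors = sf, norm = norm, hvg = hvg, scaled = scaled,
       pca = pca, knn = knn, clusters = clusters,
       trajectory_cells = traj_cells, dropped_cluster = dropped,
       dmap = dmap, pseudotime = pt, root_cell = root_cell,
       rg_cluster = rg_cluster, nbn1_cluster = nbn1_cluster,
       markers = mk, commitment = commit, manifests = manifests)
}

#' Run the cross-species homology workflow
#'
#' Normalization of both species, orthologue-pair matrix construction,
#' species batch correction, HVG pair selection, joint PCA with cell-type
#' dendrogram, per-cell nearest-mouse-cell assignment, quantile rejection
#' and the cluster x type contingency.
#'
#' @param z_sce filtered zebrafish [count_matrix()] `SingleCellExperiment`.
#' @param z_clusters named cluster label per zebrafish cell.
#' @param m_sce mouse reference `SingleCellExperiment`.
#' @param m_types named cell-type label per mouse cell.
#' @param ortho orthologue table.
#' @param config a [pipeline_config()] list.
#' @return list with `cross` (see [build_cross_species_matrix()]),
#'   `corrected`, `hvg_pairs`, `dendrogram`, `assignment` (quantile
#'   filtered), `contingency` and `manifests`.
#' @export
run_crossmap <- function(z_sce, z_clusters, m_sce, m_types, ortho,
                         config = pipeline_config()) {
  cc <- config$crossmap
  z_norm <- normalize_for_crossmap(z_sce, cc$normalization)
  m_norm <- normalize_for_crossmap(m_sce, cc$normalization)
  cross <- build_cross_species_matrix(z_norm, m_norm, ortho)
  corrected <- combat_correct(cross$matrix, cross$species)
  hvg <- hvg_cellranger(corrected, n_top = cc$n_top_pairs)
  groups <- c(paste0("zf.", z_clusters[colnames(z_norm)]),
              paste0("m.", m_types[colnames(m_norm)]))
  dend <- joint_pca_and_dendrogram(corrected, groups, n_pcs = cc$n_pcs,
                                   rows = hvg$row_id[hvg$selected],
                                   method = cc$linkage)
  rownames(dend$pca$scores) <- colnames(corrected)
  assign <- nearest_mouse_cell(dend$pca$scores, colnames(z_norm),
                               colnames(m_norm), m_types)
  assign <- quantile_filter(assign, q = cc$quantile)
  contingency <- tabulate_homology(assign, z_clusters)
  manifests <- list(crossmap = .manifest("crossmap", cc,
                                         list(z_sce, m_sce, ortho)))
  list(cross = cross, corrected = corrected, hvg_pairs = hvg,
       dendrogram = dend, assignment = assign, contingency = contingency,
       manifests = manifests)
}
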