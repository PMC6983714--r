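#' Normalize a count matrix for cross-species comparison
#'
#' Default: per-cell total-count scaling to the median library size followed
#' by log1p. A per-gene variant (each gene scaled by its mean across cells
#' before log1p) is available behind the `method` switch.
#'
#' @param m a [count_matrix()] `SingleCellExperiment` or genes x cells count
#'   matrix.
#' @param method `"per_cell"` (default) or `"per_gene"`.
#' @return genes x cells matrix of normalized log expression.
#' @export
normalize_for_crossmap <- function(m, method = c("per_cell", "per_gene")) {
  method <- match.arg(method)
  cnt <- as.matrix(if (is(m, "SingleCellExperiment")) counts(m) else m)
  if (method == "per_cell") {
    lib <- colSums(cnt)
    lib[lib == 0] <- 1
    log1p(sweep(cnt, 2, lib / stats::median(lib), "/"))
  } else {
    mu <- rowMeans(cnt)
    mu[mu == 0] <- 1
    log1p(cnt / mu)
  }
}

#' Build the orthologue-pair cross-species matrix
#'
#' One row per orthologue pair (a, b); columns are the union of zebrafish
#' and mouse cells. Element `[(a, b), i]` is the normalized expression of
#' zebrafish gene `a` when `i` is a zebrafish cell and of mouse gene `b`
#' when `i` is a mouse cell — so for a zebrafish cell the rows (a, b1) and
#' (a, b2) hold the identical value, and symmetrically for mouse cells.
#' Pairs whose genes are missing from either matrix are dropped with a
#' warning.
#'
#' @param z_norm,m_norm normalized genes x cells expression matrices for
#'   zebrafish and mouse.
#' @param ortho orthologue table with columns `z_gene_id`, `m_gene_id`.
#' @return list with `matrix` (pairs x cells), `pairs` (the retained
#'   orthologue rows) and `species` (factor per column, zebrafish/mouse).
#' @export
build_cross_species_matrix <- function(z_norm, m_norm, ortho) {
  keep <- ortho$z_gene_id %in% rownames(z_norm) &
    ortho$m_gene_id %in% rownames(m_norm)
  if (!any(keep))
    stop("no orthologue pair has both genes present")
  if (any(!keep))
    warning(sum(!keep), " orthologue pair(s) dropped: gene(s) missing")
  ortho <- ortho[keep, , drop = FALSE]
  dup <- duplicated(ortho[, c("z_gene_id", "m_gene_id")])
  if (any(dup)) ortho <- ortho[!dup, , drop = FALSE]
  x <- cbind(as.matrix(z_norm)[ortho$z_gene_id, , drop = FALSE],
             as.matrix(m_norm)[ortho$m_gene_id, , drop = FALSE])
  rownames(x) <- paste(ortho$z_gene_id, ortho$m_gene_id, sep = "|")
  species <- factor(rep(c("zebrafish", "mouse"),
                        c(ncol(z_norm), ncol(m_norm))),
                    levels = c("zebrafish", "mouse"))
  list(matrix = x, pairs = ortho, species = species)
}

#' Empirical-Bayes batch correction across species
#'
#' Parametric location/scale adjustment (ComBat, via [sva::ComBat()]) with
#' the species as the batch key: rows are standardized against the pooled
#' model, per-batch per-row location and scale estimates are shrunk toward
#' normal / inverse-gamma priors fitted by method of moments, then adjusted
#' and back-transformed. Rows with zero pooled variance are passed through
#' unchanged; a batch with a single cell is an error (its scale is
#' undefined).
#'
#' @param x rows x cells matrix (e.g. the cross-species matrix).
#' @param batch factor of length `ncol(x)` (e.g. species).
#' @return corrected matrix of the same shape.
#' @export
combat_correct <- function(x, batch) {
  batch <- as.factor(batch)
  stopifnot(ncol(x) == length(batch))
  if (nlevels(droplevels(batch)) < 2) stop("need at least two batches")
  if (any(table(batch) < 2))
    stop("every batch needs at least two cells (scale undefined otherwise)")
  v <- apply(x, 1, var)
  const <- v < .Machine$double.eps
  out <- x
  if (any(!const)) {
    corrected <- suppressMessages(
      sva::ComBat(dat = x[!const, , drop = FALSE], batch = batch,
                  par.prior = TRUE, prior.plots = FALSE))
    out[!const, ] <- corrected
  }
  out
}

#' Highly variable rows, cell-ranger flavour
#'
#' Per-row mean and dispersion (variance/mean); dispersions are normalized
#' within percentile mean bins by the bin median and median absolute
#' deviation, and the top rows by normalized dispersion are selected. Bins
#' with fewer than two rows are merged into their neighbour.
#'
#' @param x rows x cells matrix.
#' @param n_top number of rows to select.
#' @param n_bins number of percentile mean bins.
#' @return data.frame `row_id`, `mean`, `dispersion`,
#'   `normalized_dispersion`, `selected`.
#' @export
hvg_cellranger <- function(x, n_top = 1000, n_bins = 20) {
  x <- as.matrix(x)
  if (nrow(x) < 20) stop("need at least 20 rows")
  n_top <- min(n_top, nrow(x))
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  disp <- ifelse(abs(mu) > .Machine$double.eps, v / mu, NA)
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1),
                        na.rm = TRUE))
  bin <- as.integer(cut(mu, breaks = br, include.lowest = TRUE))
  # merge undersized bins into the following (or preceding) bin
  repeat {
    tab <- table(bin)
    small <- as.integer(names(tab)[tab < 2])
    if (length(small) == 0 || length(tab) == 1) break
    b <- small[1]
    nxt <- if (any(bin > b)) min(bin[bin > b]) else max(bin[bin < b])
    bin[bin == b] <- nxt
  }
  nd <- rep(NA_real_, length(mu))
  for (b in unique(bin)) {
    i <- which(bin == b & !is.na(disp))
    if (length(i) == 0) next
    md <- median(disp[i])
    md_abs <- mad(disp[i], center = md)
    if (md_abs == 0) md_abs <- 1
    nd[i] <- (disp[i] - md) / md_abs
  }
  ord <- order(-nd, seq_along(nd), na.last = TRUE)
  selected <- rep(FALSE, length(mu))
  selected[ord[seq_len(n_top)]] <- !is.na(nd[ord[seq_len(n_top)]])
  data.frame(row_id = rownames(x), mean = mu, dispersion = disp,
             normalized_dispersion = nd, selected = selected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Joint PCA and cell-type dendrogram
#'
#' PCA of all cells on the selected orthologue pairs, per-group centroids in
#' PC space, and agglomerative clustering of the centroids with Pearson
#' correlation distance (1 - r). Complete linkage by default.
#'
#' @param x corrected pairs x cells matrix (restricted to selected pairs by
#'   the caller, or pass `rows`).
#' @param groups named group label per cell (zebrafish clusters and mouse
#'   cell types).
#' @param n_pcs number of principal components.
#' @param rows optional row subset (e.g. selected HVG pairs).
#' @param method linkage: `"complete"`, `"average"` or `"ward.D2"` (the
#'   latter on Euclidean distance of centroids).
#' @return list with `pca` (see [run_pca()]), `centroids`, `dist`
#'   (group x group correlation distance), `hclust` and `newick` (the tree
#'   in Newick format).
#' @export
joint_pca_and_dendrogram <- function(x, groups, n_pcs = 50, rows = NULL,
                                     method = c("complete", "average",
                                                "ward.D2")) {
  method <- match.arg(method)
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  stopifnot(ncol(x) == length(groups))
  pca <- run_pca(x, n_pcs = n_pcs)
  cent <- do.call(rbind, lapply(split(seq_len(ncol(x)), groups), function(i)
    colMeans(pca$scores[i, , drop = FALSE])))
  if (method == "ward.D2") {
    dd <- dist(cent)
  } else {
    dd <- stats::as.dist(1 - cor(t(cent)))
  }
  hc <- hclust(dd, method = method)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(pca = pca, centroids = cent, dist = as.matrix(dd), hclust = hc,
       newick = newick)
}

#' Nearest mouse cell per zebrafish cell
#'
#' For each zebrafish cell, the mouse cell minimizing the Pearson
#' correlation distance (1 - r) between their PC coordinate vectors; ties
#' are broken by mouse cell index. A constant (zero-variance) PC vector has
#' distance 2 (the maximum) to everything.
#'
#' @param pc_scores cells x PCs matrix covering both species.
#' @param z_cells,m_cells row names (or indices) of zebrafish and mouse
#'   cells.
#' @param m_types named mouse cell-type label per mouse cell.
#' @return data.frame `cell_id`, `mouse_cell`, `mouse_type`, `distance`,
#'   `retained` (initialized TRUE; see [quantile_filter()]).
#' @export
nearest_mouse_cell <- function(pc_scores, z_cells, m_cells, m_types) {
  stopifnot(length(z_cells) > 0, length(m_cells) > 0)
  zs <- pc_scores[z_cells, , drop = FALSE]
  ms <- pc_scores[m_cells, , drop = FALSE]
  std <- function(a) {
    ctr <- a - rowMeans(a)
    s <- sqrt(rowSums(ctr^2))
    bad <- s < .Machine$double.eps
    ctr <- ctr / ifelse(bad, Inf, s)
    list(x = ctr, bad = bad)
  }
  z <- std(zs); m <- std(ms)
  r <- z$x %*% t(m$x)                 # Pearson r between PC vectors
  d <- 1 - r
  d[z$bad, ] <- 2
  d[, m$bad] <- 2
  best <- apply(d, 1, which.min)      # which.min takes the first = lowest index
  data.frame(cell_id = z_cells,
             mouse_cell = m_cells[best],
             mouse_type = unname(m_types[m_cells[best]]),
             distance = d[cbind(seq_along(best), best)],
             retained = TRUE, row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantile rejection of poorly matching cells
#'
#' Cells whose nearest-mouse-cell distance lies above the empirical
#' `q`-quantile (linear interpolation) of the distance distribution are
#' flagged as not retained.
#'
#' @param h assignment from [nearest_mouse_cell()].
#' @param q quantile in (0, 1].
#' @return `h` with the `retained` flag updated.
#' @export
quantile_filter <- function(h, q = 0.66) {
  stopifnot(nrow(h) >= 2, q > 0, q <= 1)
  thr <- quantile(h$distance, probs = q, type = 7)
  h$retained <- h$distance <= thr
  h
}

#' Contingency of zebrafish clusters versus assigned mouse types
#'
#' Counts of retained zebrafish cells per (cluster, mouse type) pair, plus
#' the mean nearest-neighbour distance per pair.
#'
#' @param h assignment from [quantile_filter()].
#' @param z_clusters named cluster label per zebrafish cell.
#' @return list with `counts` (cluster x type matrix) and `mean_distance`
#'   (same shape, NA where empty).
#' @export
tabulate_homology <- function(h, z_clusters) {
  h <- h[h$retained, , drop = FALSE]
  cl <- z_clusters[h$cell_id]
  stopifnot(!anyNA(cl))
  counts <- table(cluster = cl, mouse_type = h$mouse_type)
  md <- tapply(h$distance, list(cl, h$mouse_type), mean)
  list(counts = unclass(counts), mean_distance = md)
}
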