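#' Principal component analysis of cells
#'
#' Projects cells onto the top right-singular directions of the cells x genes
#' matrix of scaled expression. Component signs are fixed by the convention
#' that the largest-magnitude gene loading of each component is positive, so
#' results are reproducible across linear-algebra backends.
#'
#' @param scaled genes x cells matrix (e.g. from [scale_unit_variance()],
#'   restricted to HVGs).
#' @param n_pcs number of components.
#' @return list with `scores` (cells x n_pcs), `loadings` (genes x n_pcs)
#'   and `sdev` (component standard deviations).
#' @export
run_pca <- function(scaled, n_pcs = 10) {
  x <- Matrix::t(scaled)                      # cells x genes
  if (n_pcs > min(dim(x))) stop("n_pcs exceeds min(cells, genes)")
  x <- as.matrix(x)
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(i) {
    l <- sv$v[, i]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(n_pcs), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_pcs)], n_pcs), 2, flip, "*")
  loadings <- sweep(sv$v[, seq_len(n_pcs), drop = FALSE], 2, flip, "*")
  rownames(scores) <- colnames(scaled)
  rownames(loadings) <- rownames(scaled)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_pcs))
  list(scores = scores, loadings = loadings,
       sdev = sv$d[seq_len(n_pcs)] / sqrt(max(1, nrow(x) - 1)))
}

#' k-nearest-neighbour graph in PC space
#'
#' Each cell connects to its `k` nearest Euclidean neighbours (self
#' excluded); distance ties are broken by cell index order. Edge weights are
#' Gaussian-adaptive: `w_ij = exp(-d_ij^2 / (2 s_i s_j))` with `s_i` the
#' distance from cell i to its `k_sigma`-th neighbour. The graph is
#' symmetrized by union for clustering.
#'
#' @param scores cells x PCs matrix from [run_pca()].
#' @param k neighbours per cell.
#' @param k_sigma neighbour rank defining the adaptive kernel width.
#' @return list with `edges` (data.frame `from`, `to`, `dist`, `weight`;
#'   directed k-neighbour relation), `graph` (undirected weighted
#'   [igraph::graph]) and `dist` (the full distance matrix, reused by the
#'   diffusion map).
#' @export
build_knn_graph <- function(scores, k = 10, k_sigma = 5) {
  n <- nrow(scores)
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(dist(scores))
  nb <- matrix(vapply(seq_len(n), function(i) {
    o <- order(d[i, ], seq_len(n))      # stable tie-break by index
    o <- o[o != i]
    o[seq_len(k)]
  }, integer(k)), nrow = n, ncol = k, byrow = TRUE)
  sigma <- vapply(seq_len(n), function(i) d[i, nb[i, min(k_sigma, k)]],
                  numeric(1))
  pos <- sigma[sigma > 0]
  if (length(pos) == 0) stop("all cells are duplicated points")
  sigma[sigma == 0] <- min(pos)
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(nb))
  dd <- d[cbind(from, to)]
  w <- exp(-dd^2 / (2 * sigma[from] * sigma[to]))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = TRUE,
    vertices = data.frame(name = seq_len(n)))
  g <- igraph::as_undirected(g, mode = "collapse",
                             edge.attr.comb = list(weight = "max"))
  igraph::V(g)$cell <- rownames(scores)
  list(edges = data.frame(from = from, to = to, dist = dd, weight = w),
       graph = g, dist = d, sigma = sigma)
}

#' Louvain clustering of the cell graph
#'
#' Greedy modularity optimization with a resolution parameter on the
#' union-symmetrized weighted kNN graph. Labels are 0-based, ordered by
#' decreasing cluster size. Deterministic under a fixed seed.
#'
#' @param knn result of [build_knn_graph()].
#' @param resolution Louvain resolution; higher values yield more clusters.
#' @param seed integer seed.
#' @return named integer vector, cluster label per cell.
#' @export
louvain_clusters <- function(knn, resolution = 0.5, seed = 0L) {
  g <- knn$graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- relabel[as.character(memb)]
  setNames(as.integer(out), igraph::V(g)$cell)
}

#' Diffusion map with locally adaptive Gaussian kernel
#'
#' Kernel `K(x, y) = exp(-||x - y||^2 / (2 s_x s_y))` with `s_x` the distance
#' from x to its `k_sigma`-th nearest neighbour; duplicated points
#' (`s_x = 0`) inherit the smallest positive width in the dataset. The kernel
#' is density-normalized (anisotropy 1, dividing by the product of row sums)
#' and converted to a transition matrix whose leading eigenvectors are the
#' diffusion components. The stationary component (eigenvalue 1) is retained
#' at index 1; eigenvalues are sorted descending.
#'
#' @param scores cells x PCs matrix.
#' @param k_sigma neighbour rank for the adaptive kernel width.
#' @param n_comps number of diffusion components to keep.
#' @param dist optional precomputed distance matrix.
#' @return list with `components` (cells x n_comps matrix of eigenvectors of
#'   the transition matrix), `eigenvalues`, and the kernel/transition
#'   matrices (`kernel`, `transition`).
#' @export
diffusion_map <- function(scores, k_sigma = 5, n_comps = 15, dist = NULL) {
  n <- nrow(scores)
  if (n_comps >= n) stop("n_comps must be smaller than the number of cells")
  d <- if (is.null(dist)) as.matrix(stats::dist(scores)) else dist
  sigma <- vapply(seq_len(n), function(i)
    sort(d[i, -i], partial = k_sigma)[k_sigma], numeric(1))
  pos <- sigma[sigma > 0]
  if (length(pos) == 0) stop("all cells are duplicated points")
  sigma[sigma == 0] <- min(pos)
  K <- exp(-d^2 / (2 * outer(sigma, sigma)))
  q <- rowSums(K)
  K1 <- K / outer(q, q)                    # density normalization
  Dr <- rowSums(K1)
  S <- K1 / outer(sqrt(Dr), sqrt(Dr))      # symmetric conjugate of P
  eg <- eigen(S, symmetric = TRUE)
  idx <- seq_len(n_comps)
  lam <- eg$values[idx]
  psi <- eg$vectors[, idx, drop = FALSE] / sqrt(Dr)
  # fix signs: largest-magnitude entry positive
  for (i in idx) {
    s <- sign(psi[which.max(abs(psi[, i])), i])
    psi[, i] <- psi[, i] * s
  }
  rownames(psi) <- rownames(scores)
  colnames(psi) <- paste0("DC", idx)
  list(components = psi, eigenvalues = lam, kernel = K,
       transition = K1 / Dr)
}

#' Diffusion pseudotime from a root cell
#'
#' `dpt(x, y)^2 = sum_{i >= 2} (lambda_i / (1 - lambda_i))^2
#' (psi_i(x) - psi_i(y))^2`, the expected random-walk distance on the
#' diffusion manifold; pseudotime of a cell is its dpt distance to the root.
#' Eigencomponents with eigenvalue >= `1 - eps` beyond the stationary one
#' are excluded (with a warning), as their weight diverges.
#'
#' @param dmap result of [diffusion_map()].
#' @param root_cell cell id (or index) used as trajectory root.
#' @param eps numerical guard band below eigenvalue 1.
#' @return named numeric vector of pseudotimes, 0 at the root.
#' @export
diffusion_pseudotime <- function(dmap, root_cell, eps = 1e-10) {
  psi <- dmap$components
  lam <- dmap$eigenvalues
  if (is.character(root_cell)) {
    root <- match(root_cell, rownames(psi))
    if (is.na(root)) stop("root cell '", root_cell, "' not found")
  } else root <- root_cell
  use <- seq_along(lam) > 1 & lam < 1 - eps
  if (any(seq_along(lam) > 1 & !use))
    warning("excluding ", sum(seq_along(lam) > 1 & !use),
            " eigencomponent(s) with eigenvalue numerically >= 1")
  w <- (lam[use] / (1 - lam[use]))^2
  diffs <- sweep(psi[, use, drop = FALSE], 2, psi[root, use], "-")
  pt <- sqrt(as.numeric(diffs^2 %*% w))
  setNames(pt, rownames(psi))
}

#' Pairwise diffusion-pseudotime distance
#'
#' @inheritParams diffusion_pseudotime
#' @param a,b cell ids or indices.
#' @return the symmetric dpt distance between cells `a` and `b`.
#' @export
dpt_distance <- function(dmap, a, b, eps = 1e-10) {
  pt <- diffusion_pseudotime(dmap, a, eps = eps)
  if (is.character(b)) pt[[b]] else pt[[b]]
}
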