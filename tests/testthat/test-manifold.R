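test_that("PCA matches a hand-computed eigendecomposition", {
  # three points in two dimensions; covariance is 2x2 and solvable by hand
  x <- rbind(c(0, 0), c(2, 1), c(4, 2))       # cells x genes
  scaled <- t(x)                              # genes x cells
  rownames(scaled) <- c("gx", "gy")
  colnames(scaled) <- c("a", "b", "c")
  p <- run_pca(scaled, n_pcs = 2)
  cent <- sweep(x, 2, colMeans(x))
  ev <- eigen(cov(cent))
  expected <- abs(cent %*% ev$vectors)        # signs fixed separately
  expect_equal(abs(unname(p$scores)), unname(expected), tolerance = 1e-8)
  # collinear points: PC1 captures everything
  expect_gt(p$sdev[1]^2 / sum(p$sdev^2), 0.999)
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(2), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("PCA rejects more components than the data supports", {
  scaled <- matrix(rnorm(20), 4, 5,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  expect_error(run_pca(scaled, n_pcs = 5), "n_pcs")
})

test_that("kNN graph uses index order to break distance ties", {
  scores <- cbind(c(0, 1, 2), 0)
  rownames(scores) <- c("lo", "mid", "hi")
  g <- build_knn_graph(scores, k = 1, k_sigma = 1)
  e <- g$edges
  expect_identical(e$to[e$from == 2], 1L)   # middle ties to the lower index
  g2 <- build_knn_graph(scores, k = 2, k_sigma = 1)
  expect_identical(nrow(g2$edges), 6L)      # k = n - 1: complete
})

test_that("well-separated blobs produce no cross-blob edges", {
  set.seed(8)
  for (rep in 1:3) {
    a <- matrix(rnorm(30 * 3, 0, 0.5), 30, 3)
    b <- matrix(rnorm(30 * 3, 50, 0.5), 30, 3)
    scores <- rbind(a, b)
    rownames(scores) <- paste0("c", 1:60)
    g <- build_knn_graph(scores, k = 5, k_sigma = 3)
    lab <- rep(1:2, each = 30)
    expect_identical(sum(lab[g$edges$from] != lab[g$edges$to]), 0L)
  }
})

test_that("Louvain resolves planted communities", {
  # two disconnected 5-cliques
  scores <- rbind(matrix(rnorm(5 * 2, 0, 0.1), 5, 2),
                  matrix(rnorm(5 * 2, 100, 0.1), 5, 2))
  rownames(scores) <- paste0("c", 1:10)
  g <- build_knn_graph(scores, k = 4, k_sigma = 2)
  cl <- louvain_clusters(g, resolution = 0.5, seed = 0)
  expect_identical(length(unique(cl)), 2L)
  expect_identical(length(unique(cl[1:5])), 1L)
  expect_identical(length(unique(cl[6:10])), 1L)
  # a single clique collapses to one community
  one <- build_knn_graph(scores[1:5, ], k = 4, k_sigma = 2)
  expect_identical(length(unique(louvain_clusters(one, 0.5, 0))), 1L)
})

test_that("cluster labels are invariant to cell order up to relabeling", {
  s <- small_sim()
  q <- apply_qc(s$sce)
  norm <- lognormalize(q$sce, deconvolution_size_factors(q$sce))
  hvg <- select_hvg(norm)
  sc <- scale_unit_variance(norm, hvg$gene_id[hvg$selected])
  p1 <- run_pca(sc, 10)
  cl1 <- louvain_clusters(build_knn_graph(p1$scores), seed = 0)
  set.seed(1)
  perm <- sample(ncol(sc))
  p2 <- run_pca(sc[, perm], 10)
  cl2 <- louvain_clusters(build_knn_graph(p2$scores), seed = 0)
  expect_equal(adjusted_rand(cl1[names(cl2)], cl2), 1)
})

test_that("diffusion kernel is symmetric with stochastic transitions", {
  set.seed(9)
  scores <- matrix(rnorm(40 * 4), 40, 4,
                   dimnames = list(paste0("c", 1:40), NULL))
  dm <- diffusion_map(scores, k_sigma = 5, n_comps = 10)
  expect_lt(max(abs(dm$kernel - t(dm$kernel))), 1e-10)
  expect_lt(max(abs(rowSums(dm$transition) - 1)), 1e-10)
  expect_true(all(diff(dm$eigenvalues) <= 1e-12))
  expect_equal(dm$eigenvalues[1], 1, tolerance = 1e-8)
})

test_that("the second diffusion component orders a one-dimensional chain", {
  set.seed(10)
  pos <- sort(runif(80)) * 30
  scores <- cbind(pos, rnorm(80, 0, 0.1))
  rownames(scores) <- paste0("c", 1:80)
  dm <- diffusion_map(scores, k_sigma = 5, n_comps = 5)
  expect_gt(abs(cor(dm$components[, 2], pos, method = "spearman")), 0.99)
})

test_that("duplicated points inherit the smallest positive kernel width", {
  scores <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0), d = c(2, 0),
                  e = c(3, 0))
  dm <- diffusion_map(scores, k_sigma = 1, n_comps = 3)
  expect_true(all(is.finite(dm$components)))
})

test_that("diffusion pseudotime is zero at the root and symmetric", {
  set.seed(11)
  scores <- matrix(rnorm(50 * 3), 50, 3,
                   dimnames = list(paste0("c", 1:50), NULL))
  dm <- diffusion_map(scores, k_sigma = 5, n_comps = 10)
  pt <- diffusion_pseudotime(dm, "c1")
  expect_identical(unname(pt["c1"]), 0)
  d_ab <- dpt_distance(dm, "c5", "c9")
  d_ba <- dpt_distance(dm, "c9", "c5")
  expect_equal(d_ab, d_ba, tolerance = 1e-10)
})

test_that("near-unity eigenvalues beyond the stationary one are excluded", {
  dm <- list(components = matrix(rnorm(20), 10, 2,
                                 dimnames = list(paste0("c", 1:10), NULL)),
             eigenvalues = c(1, 1 - 1e-14))
  expect_warning(pt <- diffusion_pseudotime(dm, "c1"), "eigenvalue")
  expect_true(all(pt == 0))
})
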