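test_that("cross-species matrix places species values by the pair rule", {
  z <- matrix(c(1, 2), 1, 2, dimnames = list("a", c("z1", "z2")))
  m <- matrix(c(9, 8), 1, 2, dimnames = list("b", c("m1", "m2")))
  x <- build_cross_species_matrix(z, m,
                                  data.frame(z_gene_id = "a", m_gene_id = "b"))
  expect_equal(unname(x$matrix), matrix(c(1, 2, 9, 8), 1))

  # one-to-many: zebrafish column identical across the two rows
  m2 <- matrix(c(9, 8, 7, 6), 2, 2,
               dimnames = list(c("b1", "b2"), c("m1", "m2")))
  x2 <- build_cross_species_matrix(
    z, m2, data.frame(z_gene_id = c("a", "a"), m_gene_id = c("b1", "b2")))
  expect_identical(nrow(x2$matrix), 2L)
  expect_equal(x2$matrix[1, c("z1", "z2")], x2$matrix[2, c("z1", "z2")])

  expect_error(build_cross_species_matrix(
    z, m, data.frame(z_gene_id = "missing", m_gene_id = "b")), "no orthologue")
})

test_that("fully crossed 2x2 pairs give the hand-enumerated 4x4 matrix", {
  z <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("a1", "a2"), c("z1", "z2")))
  m <- matrix(c(5, 6, 7, 8), 2, 2,
              dimnames = list(c("b1", "b2"), c("m1", "m2")))
  ortho <- expand.grid(z_gene_id = c("a1", "a2"), m_gene_id = c("b1", "b2"),
                       stringsAsFactors = FALSE)
  x <- build_cross_species_matrix(z, m, ortho)
  expected <- rbind(
    "a1|b1" = c(1, 3, 5, 7),
    "a2|b1" = c(2, 4, 5, 7),
    "a1|b2" = c(1, 3, 6, 8),
    "a2|b2" = c(2, 4, 6, 8))
  colnames(expected) <- c("z1", "z2", "m1", "m2")
  expect_equal(x$matrix, expected)
  # per-cell value multiset respects pair multiplicity
  expect_setequal(x$matrix[, "z1"], c(1, 2, 1, 2))
})

test_that("ComBat removes a pure additive species shift", {
  set.seed(15)
  n <- 40
  base <- matrix(rnorm(60 * n, 5, 1), 60, n) *
    matrix(runif(60, 0.5, 3), 60, n)
  shift <- 1.5 * apply(base, 1, sd)
  x <- cbind(base, base + shift)
  rownames(x) <- sprintf("r%02d", 1:60)
  colnames(x) <- sprintf("c%02d", seq_len(2 * n))
  batch <- rep(c("zf", "mouse"), each = n)
  corrected <- combat_correct(x, batch)
  bm <- rowMeans(corrected[, batch == "zf"]) -
    rowMeans(corrected[, batch == "mouse"])
  expect_lt(max(abs(bm)), 1e-6)
})

test_that("identical batches pass through ComBat essentially unchanged", {
  # the empirical-Bayes scale shrinkage perturbs each row by a small
  # rescaling even when the batches are identical; location structure and
  # batch means are preserved exactly
  set.seed(16)
  half <- matrix(rnorm(50 * 30, 2, 1), 50, 30)
  x <- cbind(half, half)
  dimnames(x) <- list(sprintf("r%02d", 1:50), sprintf("c%02d", 1:60))
  out <- combat_correct(x, rep(1:2, each = 30))
  expect_lt(max(abs(out - x)), 0.1)
  expect_equal(rowMeans(out[, 1:30]), rowMeans(out[, 31:60]))
  rc <- vapply(seq_len(nrow(x)), function(g) cor(out[g, ], x[g, ]),
               numeric(1))
  expect_true(all(rc > 1 - 1e-12))
})

test_that("ComBat guards degenerate inputs", {
  x <- matrix(rnorm(30), 5, 6,
              dimnames = list(paste0("r", 1:5), paste0("c", 1:6)))
  expect_error(combat_correct(x, c(1, 1, 1, 1, 1, 2)), "at least two cells")
  x2 <- rbind(x, const = 3)
  out <- combat_correct(x2, rep(1:2, each = 3))
  expect_equal(out["const", ], x2["const", ])
})

test_that("species batch correction collapses the species axis", {
  s <- small_sim()
  tg <- s$truth$genes
  bio <- tg$gene_id[!tg$is_mito & !tg$is_spikein]
  mk <- tg$gene_id[!is.na(tg$marker_of) | tg$panel]
  ortho <- make_ortholog_table(length(bio) - 20, 10, seed = 21,
                               z_genes = bio, include = mk)
  ms <- simulate_mouse_reference(s$truth$config, ortho, n_per_type = 40)
  z_norm <- normalize_for_crossmap(s$sce)
  m_norm <- normalize_for_crossmap(ms$sce)
  cross <- build_cross_species_matrix(z_norm, m_norm, ortho)
  corrected <- combat_correct(cross$matrix, cross$species)
  is_mouse <- as.numeric(cross$species == "mouse")
  pc_pre <- run_pca(cross$matrix, 2)$scores[, 1]
  pc_post <- run_pca(corrected, 2)$scores[, 1]
  expect_gt(abs(cor(pc_pre, is_mouse)), 0.8)
  expect_lt(abs(cor(pc_post, is_mouse)), 0.3)
})

test_that("cell-ranger HVG selection finds variance, not mean", {
  set.seed(17)
  x <- matrix(rpois(200 * 50, rep(2^runif(200, 0, 6), 50)), 200, 50)
  x <- log1p(x)
  rownames(x) <- sprintf("r%03d", 1:200)
  planted <- rnorm(50, 10, 8)
  x <- rbind(x, planted = pmax(planted, 0))
  hv <- hvg_cellranger(x, n_top = 20)
  expect_true(hv$selected[hv$row_id == "planted"])
  # null: selection score is not driven by the mean
  null_rows <- hv$row_id != "planted" & !is.na(hv$normalized_dispersion)
  expect_lt(abs(cor(rank(hv$normalized_dispersion[null_rows]),
                    rank(hv$mean[null_rows]))), 0.25)
  hv_all <- hvg_cellranger(x, n_top = nrow(x))
  expect_true(all(hv_all$selected[!is.na(hv_all$normalized_dispersion)]))
})

test_that("dendrogram reflects planted centroid correlations", {
  set.seed(18)
  base <- rnorm(60)
  g1 <- replicate(6, base + rnorm(60, 0, 0.2))        # correlated pair
  g2 <- replicate(6, base + rnorm(60, 0, 0.2))
  g3 <- replicate(6, rnorm(60))                       # unrelated
  x <- cbind(g1, g2, g3)
  rownames(x) <- sprintf("r%02d", 1:60)
  colnames(x) <- sprintf("c%02d", 1:18)
  groups <- rep(c("A", "B", "C"), each = 6)
  d <- joint_pca_and_dendrogram(x, groups, n_pcs = 10)
  expect_identical(length(d$hclust$labels), 3L)
  first_merge <- d$hclust$merge[1, ]
  expect_setequal(d$hclust$labels[-first_merge], c("A", "B"))
  expect_match(d$newick, "^\\(")
  # identical groups merge at height about zero (a third distinct group
  # keeps the shared centroid away from the origin)
  x2 <- cbind(g1, g1, g3)
  colnames(x2) <- sprintf("c%02d", 1:18)
  d2 <- joint_pca_and_dendrogram(x2, rep(c("A", "B", "C"), each = 6),
                                 n_pcs = 5)
  expect_lt(d2$hclust$height[1], 1e-6)
  expect_setequal(d2$hclust$labels[-d2$hclust$merge[1, ]], c("A", "B"))
})

test_that("nearest mouse cell minimizes Pearson distance with tie rule", {
  pc <- rbind(z1 = c(1, 2, 3, 4), z2 = c(-1, -2, -3, -4),
              m1 = c(1, 2, 3, 4), m2 = c(4, 3, 2, 1), m3 = c(1, 2, 3, 4))
  types <- c(m1 = "glial", m2 = "neuron", m3 = "opc")
  h <- nearest_mouse_cell(pc, c("z1", "z2"), c("m1", "m2", "m3"), types)
  expect_identical(h$mouse_cell[1], "m1")     # tie with m3: lower index wins
  expect_equal(h$distance[1], 0)
  # a cell whose only potential partner is its negation sits at distance 2
  h_neg <- nearest_mouse_cell(pc, "z2", "m1", types)
  expect_equal(h_neg$distance, 2)
  # constant vector: maximal distance to everything
  pc2 <- rbind(pc, zc = c(2, 2, 2, 2))
  h2 <- nearest_mouse_cell(pc2, "zc", c("m1", "m2", "m3"), types)
  expect_equal(h2$distance, 2)
})

test_that("quantile filter uses the interpolated empirical quantile", {
  h <- data.frame(cell_id = c("a", "b", "c"), mouse_cell = "m",
                  mouse_type = "t", distance = c(1, 2, 3), retained = TRUE)
  out <- quantile_filter(h, q = 0.66)
  expect_equal(unname(quantile(c(1, 2, 3), 0.66)), 2.32)
  expect_identical(out$retained, c(TRUE, TRUE, FALSE))
  expect_true(all(quantile_filter(h, q = 1)$retained))
  h2 <- h; h2$distance <- c(2, 2, 2)
  expect_true(all(quantile_filter(h2, q = 0.66)$retained))
})

test_that("homology contingency row sums equal retained counts", {
  h <- data.frame(cell_id = paste0("z", 1:6), mouse_cell = "m",
                  mouse_type = c("g", "g", "n", "n", "n", "g"),
                  distance = 1:6 / 10,
                  retained = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  cl <- setNames(c("A", "A", "A", "B", "B", "B"), paste0("z", 1:6))
  tab <- tabulate_homology(h, cl)
  expect_equal(rowSums(tab$counts), c(A = 3, B = 2))
  expect_equal(tab$counts["A", "g"], 2)
  # single cluster, single type: one nonzero cell
  tab2 <- tabulate_homology(h[h$mouse_type == "g", ], cl)
  expect_identical(dim(tab2$counts), c(2L, 1L))
})
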