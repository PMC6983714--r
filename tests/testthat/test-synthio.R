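test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_genes = 100, n_spikein = 60, n_mito = 40),
               "n_mito")
  expect_error(sim_config(n_cells_per_pop = c(RG = -3)), "non-negative")
  expect_error(sim_config(n_cells_per_pop = c(RG = 2.5)), "non-negative")
  expect_error(sim_config(marker_effect = 1), "marker_effect")
  expect_error(sim_config(dropout_rate = 1.2), "dropout_rate")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
})

test_that("simulation is deterministic and respects degenerate fractions", {
  cfg <- sim_config(n_cells_per_pop = c(RG = 20, NBN.1 = 20),
                    n_genes = 400, n_spikein = 15, n_mito = 5,
                    n_markers_per_pop = 20, frac_low_quality = 0, seed = 1L)
  a <- simulate_zebrafish(cfg)
  b <- simulate_zebrafish(cfg)
  expect_identical(counts(a$sce), counts(b$sce))
  expect_identical(a$truth, b$truth)
  expect_false(any(a$truth$cells$low_quality))
})

test_that("counts are non-negative integers and spike-ins present everywhere", {
  s <- small_sim()
  cnt <- as.matrix(counts(s$sce))
  expect_true(all(cnt >= 0))
  expect_true(all(cnt == round(cnt)))
  nonempty <- colSums(cnt) > 0
  spike_sum <- colSums(cnt[is_spikein(s$sce), ])
  expect_true(all(spike_sum[nonempty] > 0))
})

test_that("trajectory positions are defined exactly for non-OPC cells", {
  s <- small_sim()
  tc <- s$truth$cells
  expect_true(all(is.na(tc$t) == (tc$population == "OPC")))
  expect_true(all(tc$t >= 0 & tc$t <= 1, na.rm = TRUE))
  expect_setequal(tc$cell_id, colnames(s$sce))
})

test_that("population markers show the planted fold change", {
  cfg <- sim_config(n_cells_per_pop = c(RG = 200, NBN.1 = 200, NBN.2 = 200,
                                        MN = 200, OPC = 200),
                    marker_effect = 4, frac_low_quality = 0, seed = 3L)
  s <- simulate_zebrafish(cfg)
  cnt <- as.matrix(counts(s$sce))
  tc <- s$truth$cells
  tg <- s$truth$genes
  for (p in c("RG", "NBN.1", "NBN.2", "MN", "OPC")) {
    mk <- tg$gene_id[!is.na(tg$marker_of) & tg$marker_of == p]
    inside <- tc$cell_id[tc$population == p]
    outside <- setdiff(tc$cell_id, inside)
    lr <- log(mean(cnt[mk, inside]) / mean(cnt[mk, outside]))
    expect_gt(lr, 0.7 * log(4))
    expect_lt(lr, 1.3 * log(4))
  }
})

test_that("proliferating RG carry the cell-cycle classifier gene", {
  s <- default_sim()
  tc <- s$truth$cells
  prolif <- tc$cell_id[tc$proliferating & !tc$low_quality]
  quies <- tc$cell_id[!tc$proliferating & tc$population == "RG" &
                        !tc$low_quality]
  cnt <- counts(s$sce)
  expect_gt(mean(cnt["ccnd1", prolif] >= 1), 0.85)
  expect_lt(mean(cnt["ccnd1", quies] >= 1), 0.2)
})

test_that("ortholog table construction matches the requested structure", {
  t1 <- make_ortholog_table(3, 0, seed = 5)
  expect_identical(nrow(t1), 3L)
  expect_identical(anyDuplicated(t1$z_gene_id), 0L)

  t2 <- make_ortholog_table(0, 2, seed = 5)
  expect_identical(nrow(t2), 4L)
  expect_identical(sort(as.integer(table(t2$z_gene_id))), c(2L, 2L))

  t3 <- make_ortholog_table(5, 3, seed = 5)
  expect_identical(nrow(t3), 11L)
  expect_identical(anyDuplicated(t3[, c("z_gene_id", "m_gene_id")]), 0L)
})

test_that("mouse reference mirrors each population in one homologous type", {
  s <- small_sim()
  tg <- s$truth$genes
  bio <- tg$gene_id[!tg$is_mito & !tg$is_spikein]
  mk <- tg$gene_id[!is.na(tg$marker_of) | tg$panel]
  ortho <- make_ortholog_table(length(bio) - 20, 10, seed = 9,
                               z_genes = bio, include = mk)
  cfg <- s$truth$config
  m1 <- simulate_mouse_reference(cfg, ortho, n_per_type = 40)
  m2 <- simulate_mouse_reference(cfg, ortho, n_per_type = 40)
  expect_identical(counts(m1$sce), counts(m2$sce))

  hom <- m1$homology
  expect_identical(anyDuplicated(hom$population), 0L)
  expect_identical(sort(hom$population),
                   sort(c("RG", "NBN.1", "NBN.2", "MN", "OPC")))

  # centroid correlation over orthologous marker genes is highest for the
  # planted homologous type
  zc <- as.matrix(counts(s$sce))
  mc <- as.matrix(counts(m1$sce))
  tc <- s$truth$cells
  omk <- ortho[!is.na(tg$marker_of[match(ortho$z_gene_id, tg$gene_id)]), ]
  omk <- omk[!duplicated(omk$z_gene_id), ]
  types <- unique(m1$cell_types$cell_type)
  for (p in hom$population) {
    zcent <- log1p(rowMeans(zc[omk$z_gene_id, tc$cell_id[tc$population == p],
                               drop = FALSE]))
    cors <- vapply(types, function(ty) {
      mcent <- log1p(rowMeans(mc[omk$m_gene_id,
                                 m1$cell_types$cell_id[
                                   m1$cell_types$cell_type == ty],
                                 drop = FALSE]))
      cor(zcent, mcent)
    }, numeric(1))
    expect_identical(names(which.max(cors)),
                     hom$mouse_type[hom$population == p])
  }
})

test_that("mouse reference demands orthologues for all marker genes", {
  s <- small_sim()
  ortho <- make_ortholog_table(5, 0, seed = 1)  # misses nearly everything
  expect_error(simulate_mouse_reference(s$truth$config, ortho),
               "without orthologue")
})
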