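# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# the default-condition zebrafish dataset (~370 cells, 2000 genes)
default_sim <- function() cached("default_sim", simulate_zebrafish(sim_config()))

# QC-filtered default dataset plus normalization
default_filtered <- function() cached("default_filtered", {
  s <- default_sim()
  q <- apply_qc(s$sce)
  sf <- deconvolution_size_factors(q$sce)
  norm <- lognormalize(q$sce, sf)
  list(sim = s, qc = q, sf = sf, norm = norm)
})

# a small five-population dataset for fast module tests
small_sim <- function() cached("small_sim", {
  # fewer cells than the default conditions, but the full-size gene space:
  # the QC thresholds are calibrated to the library structure
  cfg <- sim_config(n_cells_per_pop = c(RG = 30, NBN.1 = 30, NBN.2 = 25,
                                        MN = 25, OPC = 10),
                    frac_low_quality = 0, seed = 42L)
  simulate_zebrafish(cfg)
})

truth_pop <- function(sim, cells) {
  tc <- sim$truth$cells
  setNames(tc$population[match(cells, tc$cell_id)], cells)
}

# minimal count container from a plain matrix
toy_matrix <- function(cnt, mito = rep(FALSE, nrow(cnt)),
                       spike = rep(FALSE, nrow(cnt)),
                       total = NULL, mapped = NULL) {
  if (is.null(rownames(cnt))) rownames(cnt) <- sprintf("g%02d", seq_len(nrow(cnt)))
  if (is.null(colnames(cnt))) colnames(cnt) <- sprintf("c%02d", seq_len(ncol(cnt)))
  cs <- colSums(cnt)
  if (is.null(mapped)) mapped <- pmax(round(cs * 1.2), 1)
  if (is.null(total)) total <- pmax(round(mapped / 0.8), mapped)
  count_matrix(cnt,
               data.frame(gene_id = rownames(cnt), is_mito = mito,
                          is_spikein = spike),
               data.frame(cell_id = colnames(cnt), total_reads = total,
                          mapped_reads = mapped))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
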