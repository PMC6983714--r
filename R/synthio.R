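#' Simulation configuration for the two-species synthetic dataset
#'
#' Parameters of the synthetic plate-based scRNA-seq generator. Defaults
#' emulate the study conditions of the adult zebrafish forebrain dataset the
#' pipeline targets: five populations (RG, NBN.1, NBN.2, MN, OPC) at the
#' published cluster sizes, a branching differentiation trajectory
#' RG -> NBN.1 -> {MN, NBN.2}, 92 ERCC-style spike-in transcripts,
#' mitochondrial genes, a minority of low-quality cells, and a proliferating
#' RG subset carrying cell-cycle and neurogenic-commitment programs.
#'
#' @param n_cells_per_pop named integer vector over
#'   `c("RG","NBN.1","NBN.2","MN","OPC")`; populations may be 0. Default
#'   mirrors the five published cluster sizes (76/80/54/44/10).
#' @param n_genes total number of matrix rows, including mitochondrial and
#'   spike-in rows.
#' @param n_spikein,n_mito number of spike-in / mitochondrial rows.
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`), shared across genes.
#' @param dropout_rate independent Bernoulli zero-inflation probability
#'   applied to biological genes.
#' @param frac_low_quality fraction of *all* emitted cells that are planted
#'   low-quality (they violate at least one QC rule); low-quality cells are
#'   added on top of `n_cells_per_pop`, so the default yields about 370 cells
#'   of which 264 are clean.
#' @param frac_proliferating_rg fraction of RG cells planted as proliferating
#'   (cell-cycle genes on, commitment panel enriched).
#' @param marker_effect fold-change (> 1) of population marker genes within
#'   their population.
#' @param panel_effect fold-enrichment of the 4-gene neurogenic panel
#'   (`ascl1a`, `sox4a`, `tmsb`, `stmn1b`) in proliferating relative to
#'   quiescent RG; set to 1 for a null dataset with no commitment program.
#' @param n_markers_per_pop planted marker genes per population.
#' @param seed integer seed; the full output is a deterministic function of
#'   the configuration.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells_per_pop = c(RG = 76, NBN.1 = 80, NBN.2 = 54,
                                           MN = 44, OPC = 10),
                       n_genes = 2000, n_spikein = 92, n_mito = 13,
                       nb_dispersion = 0.3, dropout_rate = 0.15,
                       frac_low_quality = 0.29,
                       frac_proliferating_rg = 0.41,
                       marker_effect = 4, panel_effect = 6,
                       n_markers_per_pop = 80, seed = 1L) {
  pops <- c("RG", "NBN.1", "NBN.2", "MN", "OPC")
  full <- setNames(integer(5), pops)
  if (is.null(names(n_cells_per_pop)) ||
      !all(names(n_cells_per_pop) %in% pops))
    stop("n_cells_per_pop must be named with populations among: ",
         paste(pops, collapse = ", "))
  full[names(n_cells_per_pop)] <- n_cells_per_pop
  chk_int <- function(x, nm) {
    if (any(x < 0) || any(x != round(x)))
      stop(nm, " must be non-negative integer(s)")
  }
  chk_int(full, "n_cells_per_pop")
  for (nm in c("n_genes", "n_spikein", "n_mito", "n_markers_per_pop", "seed"))
    chk_int(get(nm), nm)
  for (nm in c("dropout_rate", "frac_low_quality", "frac_proliferating_rg")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(nm, " must be in [0, 1]")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (marker_effect <= 1) stop("marker_effect must be > 1")
  if (panel_effect < 1) stop("panel_effect must be >= 1")
  if (n_mito + n_spikein >= n_genes)
    stop("n_mito + n_spikein must be smaller than n_genes")
  structure(list(n_cells_per_pop = full, n_genes = as.integer(n_genes),
                 n_spikein = as.integer(n_spikein),
                 n_mito = as.integer(n_mito),
                 nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
                 frac_low_quality = frac_low_quality,
                 frac_proliferating_rg = frac_proliferating_rg,
                 marker_effect = marker_effect, panel_effect = panel_effect,
                 n_markers_per_pop = as.integer(n_markers_per_pop),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Reserved gene names addressable downstream: cell-cycle classifiers and the
# curated neurogenic panel.
.cc_genes <- c("ccnd1", "mki67", "mcm5")
.panel_genes <- c("ascl1a", "sox4a", "tmsb", "stmn1b")

# Expected counts for the reserved genes at the reference library size,
# by cell state. Cell-cycle genes are essentially off outside proliferating
# RG; ccnd1 is expressed throughout the cycle while the S/G2/M genes
# (mki67, mcm5, ...) are on only in the cycling-phase subset of
# proliferating RG, as in vivo. The panel is lowly detected in quiescent
# RG, enriched panel_effect-fold in proliferating RG, and strongly
# expressed in NBN.1 (they are neurogenic fate determinants / NBN.1
# markers).
.special_targets <- function(config) {
  panel_base <- 0.3
  list(cc_off = 0.02, ccnd1_on = 4, phase_on = 4, phase_frac = 0.35,
       panel = c(RG = panel_base,
                 RG_prolif = panel_base * config$panel_effect,
                 NBN.1 = 2.5, NBN.2 = 1, MN = 1, OPC = 0.1))
}

# Deterministic gene-level architecture shared by the zebrafish and mouse
# simulators: baseline intensities, marker assignment, population anchor
# log-intensity profiles, spike-in and mitochondrial profiles. Consumes a
# fixed pseudo-random draw sequence under the config seed so both species
# see the identical architecture.
.sim_architecture <- function(config) {
  set.seed(config$seed)
  pops <- names(config$n_cells_per_pop)
  n_bio <- config$n_genes - config$n_spikein - config$n_mito
  reserved <- c(.cc_genes, .panel_genes)
  if (n_bio < length(reserved) + 5 * config$n_markers_per_pop + 10)
    stop("n_genes too small for the requested marker architecture")
  bio_ids <- c(reserved,
               sprintf("gene%04d", seq_len(n_bio - length(reserved))))
  mito_ids <- sprintf("mt-gene%02d", seq_len(config$n_mito))
  spike_ids <- sprintf("ERCC-%05d", seq_len(config$n_spikein))

  base <- rlnorm(n_bio, meanlog = 0, sdlog = 1.2)
  names(base) <- bio_ids
  base[reserved] <- 1e-12          # reserved genes driven by state targets

  # markers are drawn from the upper half of the baseline expression
  # distribution: cell-type markers are genes whose expression is readily
  # detectable, and fold changes on barely-expressed genes carry no signal
  pool <- setdiff(bio_ids, reserved)
  pool <- pool[base[pool] >= median(base[pool])]
  marker_of <- setNames(rep(NA_character_, n_bio), bio_ids)
  picked <- sample(pool, 5 * config$n_markers_per_pop)
  for (i in seq_along(pops)) {
    idx <- picked[seq_len(config$n_markers_per_pop) +
                    (i - 1) * config$n_markers_per_pop]
    marker_of[idx] <- pops[i]
  }

  lbase <- log(base)
  lfc <- log(config$marker_effect)
  anchor <- sapply(pops, function(p) {
    a <- lbase
    own <- !is.na(marker_of) & marker_of == p
    a[own] <- a[own] + lfc
    if (p == "OPC") {
      # the OPC program is disconnected from the neurogenic lineage: it
      # lacks the other populations' expression modules entirely
      other <- !is.na(marker_of) & marker_of != p
      a[other] <- a[other] - lfc
    }
    a
  })
  # maturation ramp programs: genes whose expression ramps continuously and
  # monotonically along the whole trajectory (down: stemness program lost
  # with differentiation; up: pan-neuronal maturation program), independent
  # of the population marker modules
  ramp <- setNames(rep(0, n_bio), bio_ids)
  n_ramp <- min(150L, length(setdiff(pool, picked)) %/% 2)
  ramp_pool <- sample(setdiff(pool, picked), 2 * n_ramp)
  ramp[ramp_pool[seq_len(n_ramp)]] <- 1
  ramp[ramp_pool[n_ramp + seq_len(n_ramp)]] <- -1
  # full-trajectory swing of the ramp programs: twice the marker log fold
  # change (maturation programs go from off to fully on across the lineage)
  ramp_amplitude <- 2 * lfc

  mito_prof <- rlnorm(config$n_mito, 0, 0.8)
  mito_prof <- mito_prof / sum(mito_prof)
  spike_prof <- rlnorm(config$n_spikein, 0, 1.5)
  spike_prof <- spike_prof / sum(spike_prof)

  # neurogenic commitment module: a subset of the NBN.1 program already
  # switched on (mildly) in proliferating RG
  commit_genes <- names(marker_of)[!is.na(marker_of) &
                                     marker_of == "NBN.1"][1:20]

  list(pops = pops, n_bio = n_bio, bio_ids = bio_ids, mito_ids = mito_ids,
       spike_ids = spike_ids, marker_of = marker_of, anchor = anchor,
       ramp = ramp, ramp_amplitude = ramp_amplitude,
       commit_genes = commit_genes, mito_prof = mito_prof,
       spike_prof = spike_prof, ref_library = 1.2e5)
}

# Log-intensity profile of the population marker modules along the
# branching trajectory. Each population drifts around its own anchor in the
# direction of the neighbouring anchors, covering a fraction .traj_drift of
# the inter-anchor gradient across its segment; the rest is a jump at the
# segment boundary (a commitment switch). Module expression changes
# continuously and monotonically with t inside every population while cell
# states remain density-separable; the smooth ramp programs (see
# .sim_architecture) provide the continuous gradient that spans the whole
# lineage.
.traj_drift <- 0.4
.trajectory_logint <- function(arch, t, branch) {
  a_rg <- arch$anchor[, "RG"]; a_n1 <- arch$anchor[, "NBN.1"]
  seg <- list(RG = c(0, 0.35), NBN.1 = c(0.35, 0.7), end = c(0.7, 1))
  a_end <- arch$anchor[, branch]
  if (t <= 0.35) {                      # RG segment
    s <- t / 0.35
    a_rg + .traj_drift * (s - 0.5) * (a_n1 - a_rg)
  } else if (t <= 0.7) {                # NBN.1 segment
    s <- (t - 0.35) / 0.35
    a_mid <- 0.5 * (arch$anchor[, "MN"] + arch$anchor[, "NBN.2"])
    dir <- if (s < 0.5) (a_n1 - a_rg) else (a_mid - a_n1)
    a_n1 + .traj_drift * (s - 0.5) * dir
  } else {                              # terminal branch segment
    s <- (t - 0.7) / 0.3
    a_end + .traj_drift * (s - 0.5) * (a_end - a_n1)
  }
}

#' Simulate the zebrafish radial-glia lineage dataset
#'
#' Draws negative-binomial counts with Bernoulli dropout around
#' population- and trajectory-dependent means. Expression programs vary
#' continuously along a branching trajectory RG -> NBN.1 -> {MN, NBN.2};
#' OPC cells carry a disconnected program. A configurable fraction of cells
#' is planted low-quality (shrunken library, inflated mitochondrial or
#' spike-in load, poorly mapped reads, or collapsed complexity), and a
#' configurable fraction of RG is planted as proliferating, with the
#' cell-cycle genes (including `ccnd1`) switched on and the neurogenic
#' panel enriched.
#'
#' @param config a [sim_config()].
#' @return list with elements `sce` (the raw [count_matrix()]
#'   `SingleCellExperiment`) and `truth` (list of `cells` and `genes`
#'   data.frames carrying planted labels, trajectory positions `t`,
#'   proliferation and low-quality flags, marker/mito/spike-in/cell-cycle/
#'   panel gene annotations, plus the generating `config`).
#' @export
simulate_zebrafish <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- .sim_architecture(config)
  tg <- .special_targets(config)
  pops <- arch$pops

  pop_of <- rep(pops, config$n_cells_per_pop)
  n_clean <- length(pop_of)
  if (n_clean == 0) stop("no cells requested")
  f <- config$frac_low_quality
  n_lq <- if (f > 0) round(f / (1 - f) * n_clean) else 0L
  lq_pop <- if (n_lq > 0)
    sample(pops, n_lq, replace = TRUE,
           prob = pmax(config$n_cells_per_pop, 0.5)) else character()
  pop_of <- c(pop_of, lq_pop)
  low_quality <- c(rep(FALSE, n_clean), rep(TRUE, n_lq))
  n_cells <- length(pop_of)
  cell_id <- sprintf("%s%s_%03d", ifelse(low_quality, "lq-", ""), pop_of,
                     stats::ave(seq_len(n_cells), pop_of, low_quality,
                                FUN = seq_along))

  # trajectory positions: beta(3,3) within the population segment, so cell
  # density is low at segment boundaries while expression still drifts with t
  seg <- list(RG = c(0, 0.35), NBN.1 = c(0.35, 0.7),
              NBN.2 = c(0.7, 1), MN = c(0.7, 1), OPC = c(NA, NA))
  tpos <- vapply(pop_of, function(p) {
    s <- seg[[p]]
    if (anyNA(s)) NA_real_ else s[1] + diff(s) * rbeta(1, 3, 3)
  }, numeric(1), USE.NAMES = FALSE)
  branch <- ifelse(pop_of %in% c("NBN.2"), "NBN.2",
                   ifelse(pop_of == "OPC", NA, "MN"))

  prolif <- pop_of == "RG" & runif(n_cells) < config$frac_proliferating_rg
  tg0 <- .special_targets(config)
  cycling_phase <- prolif & runif(n_cells) < tg0$phase_frac

  # per-cell technical quantities
  lib <- rlnorm(n_cells, log(arch$ref_library), 0.25)
  mito_share <- rbeta(n_cells, 6, 94)
  spike_share <- rbeta(n_cells, 6.4, 73.6)
  mapped_frac <- rbeta(n_cells, 40, 10)
  lq_mode <- rep(NA_character_, n_cells)
  if (n_lq > 0) {
    lq_mode[low_quality] <- sample(
      c("tiny_library", "high_mito", "high_spike", "low_mapped",
        "low_complexity"), n_lq, replace = TRUE)
    sel <- function(m) which(low_quality & lq_mode == m)
    i <- sel("tiny_library"); lib[i] <- lib[i] * 0.02
    i <- sel("high_mito"); mito_share[i] <- runif(length(i), 0.35, 0.6)
    i <- sel("high_spike"); spike_share[i] <- runif(length(i), 0.35, 0.6)
    i <- sel("low_mapped"); mapped_frac[i] <- runif(length(i), 0.02, 0.12)
  }

  # per-cell biological intensity (relative, then renormalized to shares)
  bio_int <- matrix(0, arch$n_bio, n_cells,
                    dimnames = list(arch$bio_ids, cell_id))
  for (j in seq_len(n_cells)) {
    li <- if (pop_of[j] == "OPC") arch$anchor[, "OPC"] else
      .trajectory_logint(arch, tpos[j], branch[j]) +
        arch$ramp * arch$ramp_amplitude * (tpos[j] - 0.5)
    # proliferating RG carry a commitment module: part of the NBN.1 program
    # at twice the quiescent level (absent in the panel_effect = 1 null)
    if (prolif[j] && config$panel_effect > 1)
      li[arch$commit_genes] <- li[arch$commit_genes] + log(2)
    bio_int[, j] <- exp(li)
  }
  # reserved-gene state targets: expressed as a fraction of the cell's
  # biological budget so the expected count matches the target at the
  # reference library size
  panel_level <- tg$panel[pop_of]
  panel_level[prolif] <- tg$panel[["RG_prolif"]]
  for (j in seq_len(n_cells)) {
    v <- bio_int[, j]
    v[.cc_genes] <- 0
    v[.panel_genes] <- 0
    tot <- sum(v)
    # choose intensities so that gene mean ~= target count when the cell's
    # biological budget is lib * bio_share at the reference library
    budget <- arch$ref_library
    cc <- setNames(rep(tg$cc_off, length(.cc_genes)), .cc_genes)
    if (prolif[j]) cc["ccnd1"] <- tg$ccnd1_on
    if (cycling_phase[j])
      cc[setdiff(.cc_genes, "ccnd1")] <- tg$phase_on
    v[.cc_genes] <- cc[.cc_genes] / budget * tot
    v[.panel_genes] <- panel_level[j] / budget * tot
    if (low_quality[j] && !is.na(lq_mode[j]) && lq_mode[j] == "low_complexity") {
      v <- (v / max(v))^4
    }
    bio_int[, j] <- v / sum(v)
  }

  bio_share <- 1 - mito_share - spike_share
  mu <- rbind(bio_int * rep(lib * bio_share, each = arch$n_bio),
              arch$mito_prof %o% (lib * mito_share),
              arch$spike_prof %o% (lib * spike_share))
  rownames(mu) <- c(arch$bio_ids, arch$mito_ids, arch$spike_ids)
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                nrow(mu), ncol(mu), dimnames = dimnames(mu))
  # dropout on biological genes; reserved genes carry planted detection
  # probabilities directly and are exempt
  drop_rows <- setdiff(arch$bio_ids, c(.cc_genes, .panel_genes))
  if (config$dropout_rate > 0) {
    dm <- matrix(runif(length(drop_rows) * n_cells) < config$dropout_rate,
                 length(drop_rows), n_cells)
    cnt[drop_rows, ][dm] <- 0
  }

  # exact expected non-spike-in count totals: the generating truth for
  # size-factor recovery (dropout halves the expectation of affected rows)
  expected <- mu
  expected[drop_rows, ] <- expected[drop_rows, ] * (1 - config$dropout_rate)
  sf_true <- colSums(expected[c(arch$bio_ids, arch$mito_ids), , drop = FALSE])
  sf_true <- sf_true / mean(sf_true)

  csum <- colSums(cnt)
  mapped_reads <- round(csum * 1.15)
  total_reads <- pmax(round(mapped_reads / mapped_frac), mapped_reads)

  gene_flags <- data.frame(
    gene_id = rownames(cnt),
    gene_name = rownames(cnt),
    is_mito = rownames(cnt) %in% arch$mito_ids,
    is_spikein = rownames(cnt) %in% arch$spike_ids)
  cell_meta <- data.frame(cell_id = cell_id, total_reads = total_reads,
                          mapped_reads = mapped_reads)
  sce <- count_matrix(cnt, gene_flags, cell_meta)

  truth_cells <- data.frame(
    cell_id = cell_id, population = pop_of, t = tpos,
    proliferating = prolif, low_quality = low_quality,
    lq_mode = lq_mode, library_scale = lib, size_factor = sf_true,
    stringsAsFactors = FALSE)
  truth_genes <- data.frame(
    gene_id = rownames(cnt),
    marker_of = c(arch$marker_of,
                  setNames(rep(NA_character_,
                               config$n_mito + config$n_spikein),
                           c(arch$mito_ids, arch$spike_ids)))[rownames(cnt)],
    is_mito = gene_flags$is_mito, is_spikein = gene_flags$is_spikein,
    cellcycle = rownames(cnt) %in% .cc_genes,
    panel = rownames(cnt) %in% .panel_genes,
    ramp = c(arch$ramp,
             setNames(rep(0, config$n_mito + config$n_spikein),
                      c(arch$mito_ids, arch$spike_ids)))[rownames(cnt)],
    row.names = NULL, stringsAsFactors = FALSE)

  list(sce = sce,
       truth = list(cells = truth_cells, genes = truth_genes,
                    config = config))
}

#' Generate a synthetic orthologue-pair table
#'
#' Builds a zebrafish-to-mouse orthologue table with `n_one_to_one` unique
#' pairs plus `n_one_to_many` zebrafish genes mapped to two mouse genes each,
#' mirroring the many-to-many structure of a Biomart orthologue export.
#'
#' @param n_one_to_one,n_one_to_many non-negative pair counts.
#' @param seed integer seed.
#' @param z_genes optional zebrafish gene universe to draw from (defaults to
#'   synthetic ids).
#' @param include zebrafish genes guaranteed to be present in the table
#'   (useful to ensure all marker genes have orthologues).
#' @return data.frame with columns `z_gene_id`, `z_gene_name`, `m_gene_id`,
#'   `m_gene_name`; no duplicated (z, m) rows.
#' @export
make_ortholog_table <- function(n_one_to_one, n_one_to_many, seed = 1L,
                                z_genes = NULL, include = NULL) {
  stopifnot(n_one_to_one >= 0, n_one_to_many >= 0)
  set.seed(seed)
  n_z <- n_one_to_one + n_one_to_many
  if (is.null(z_genes)) {
    zsel <- sprintf("zgene%05d", seq_len(n_z))
  } else {
    include <- intersect(include, z_genes)
    if (length(include) > n_z)
      stop("more 'include' genes than table slots")
    zsel <- c(include,
              sample(setdiff(z_genes, include), n_z - length(include)))
  }
  multi <- rep(FALSE, n_z)
  if (n_one_to_many > 0) multi[sample(n_z, n_one_to_many)] <- TRUE
  z <- c(zsel[!multi], rep(zsel[multi], each = 2))
  m_one <- if (any(!multi)) paste0("m.", zsel[!multi]) else character()
  m_multi <- if (any(multi))
    paste0("m.", rep(zsel[multi], each = 2), c(".1", ".2")) else character()
  m <- c(m_one, m_multi)
  data.frame(z_gene_id = z, z_gene_name = z, m_gene_id = m, m_gene_name = m,
             stringsAsFactors = FALSE)
}

#' Simulate a labelled mouse reference dataset
#'
#' Generates counts for six mouse cell types (radial-glia-like, neurogenic
#' intermediate progenitor, neuroblast, immature neuron, mature neuron, OPC)
#' whose expression programs mirror the zebrafish population programs through
#' the orthologue table, plus a per-gene species batch effect. Each zebrafish
#' population has exactly one designated homologous mouse type, recorded in
#' the output, so cross-species label transfer can be scored against truth.
#'
#' @param config the [sim_config()] used for the zebrafish dataset (the gene
#'   architecture is re-derived from its seed, so programs match).
#' @param ortho orthologue table as from [make_ortholog_table()]; every
#'   planted zebrafish marker gene must be mapped.
#' @param n_per_type mouse cells per type.
#' @return list with `sce` (mouse [count_matrix()]), `cell_types`
#'   (data.frame `cell_id`, `cell_type`) and `homology` (data.frame
#'   `population`, `mouse_type`), the planted zebrafish-to-mouse map.
#' @export
simulate_mouse_reference <- function(config, ortho, n_per_type = 80L) {
  stopifnot(inherits(config, "sim_config"))
  arch <- .sim_architecture(config)
  zf_markers <- names(arch$marker_of)[!is.na(arch$marker_of)]
  missing <- setdiff(c(zf_markers, .panel_genes), ortho$z_gene_id)
  if (length(missing))
    stop("zebrafish marker genes without orthologue: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")

  homology <- data.frame(
    population = c("RG", "NBN.1", "NBN.2", "MN", "OPC"),
    mouse_type = c("RGL", "Neuroblast", "Immature.Neuron", "Mature.Neuron",
                   "OPC.m"),
    stringsAsFactors = FALSE)
  types <- c("RGL", "nIPC", "Neuroblast", "Immature.Neuron", "Mature.Neuron",
             "OPC.m")

  # mouse log-intensity per type: orthologue-projected zebrafish anchors
  keep <- ortho$z_gene_id %in% arch$bio_ids
  ortho <- ortho[keep, , drop = FALSE]
  m_genes <- sort(unique(ortho$m_gene_id))
  z_of_m <- split(ortho$z_gene_id, ortho$m_gene_id)[m_genes]
  project <- function(a) vapply(z_of_m, function(z) mean(a[z]), numeric(1))
  with_ramp <- function(pop, t_anchor)
    arch$anchor[, pop] + arch$ramp * arch$ramp_amplitude * (t_anchor - 0.5)
  prog <- cbind(
    RGL = project(with_ramp("RG", 0.175)),
    nIPC = project(0.5 * with_ramp("RG", 0.175) +
                     0.5 * with_ramp("NBN.1", 0.525)),
    Neuroblast = project(with_ramp("NBN.1", 0.525)),
    Immature.Neuron = project(with_ramp("NBN.2", 0.85)),
    Mature.Neuron = project(with_ramp("MN", 0.85)),
    OPC.m = project(arch$anchor[, "OPC"]))

  set.seed(config$seed + 1L)
  species_shift <- stats::rnorm(length(m_genes), 0, 1.2)
  prog <- prog + species_shift   # per-gene batch effect shared across types

  type_of <- rep(types, each = n_per_type)
  n_cells <- length(type_of)
  cell_id <- sprintf("m-%s_%03d", type_of,
                     stats::ave(seq_len(n_cells), type_of, FUN = seq_along))
  lib <- rlnorm(n_cells, log(8e4), 0.25)
  int <- exp(prog[, type_of, drop = FALSE])
  int <- sweep(int, 2, colSums(int), "/")
  mu <- int * rep(lib, each = length(m_genes))
  dimnames(mu) <- list(m_genes, cell_id)
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                nrow(mu), ncol(mu), dimnames = dimnames(mu))
  if (config$dropout_rate > 0) {
    dm <- matrix(runif(length(cnt)) < config$dropout_rate, nrow(cnt))
    cnt[dm] <- 0
  }
  csum <- colSums(cnt)
  gene_flags <- data.frame(gene_id = m_genes, gene_name = m_genes,
                           is_mito = FALSE, is_spikein = FALSE)
  cell_meta <- data.frame(cell_id = cell_id,
                          total_reads = round(csum * 1.35),
                          mapped_reads = round(csum * 1.15))
  sce <- count_matrix(cnt, gene_flags, cell_meta)
  list(sce = sce,
       cell_types = data.frame(cell_id = cell_id, cell_type = type_of,
                               stringsAsFactors = FALSE),
       homology = homology)
}
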