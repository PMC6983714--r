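# rglineage

Single-cell transcriptomic analysis of the radial glia (RG) lineage in the
adult zebrafish forebrain, as a tested and reusable R pipeline.

Adult zebrafish continuously generate neurons from ventricular radial glia.
Sorting the lineage by reporter retention yields RG, newborn neurons (NBNs)
and mature neurons (MNs); plate-based (SMART-seq-style) single-cell RNA-seq
of a few hundred such cells resolves five transcriptional states — RG, two
newborn-neuron populations (NBN.1, NBN.2), MN, and a small OPC population —
along a branching differentiation trajectory RG → NBN.1 → {MN, NBN.2}.
`rglineage` implements every computational stage of that analysis for
anyone working with comparable plate-based single-cell data:

* **QC** — the six per-cell filters (log10 total counts > 4.5, log10
  features with >1 read in (2.7, 3.9), top-50-gene fraction < 0.5,
  mitochondrial fraction < 0.2, spike-in fraction < 0.25, mapped fraction
  > 0.2; all strict) and the ≥3-cell gene-detection filter.
* **Normalization** — scran pooled-deconvolution size factors (spike-ins
  excluded), natural-log `log1p`, dispersion-based HVG selection with the
  mean window capped at 8, unit-variance scaling.
* **Manifold** — PCA (10 components), 10-nearest-neighbour graph with
  adaptive Gaussian weights, Louvain clustering at resolution 0.5, a
  diffusion map with kernel width set by the distance to the 5th
  neighbour, and diffusion pseudotime
  `dpt(x, r)² = Σ_{i≥2} (λᵢ/(1−λᵢ))² (ψᵢ(x) − ψᵢ(r))²` from a root RG
  cell.
* **Markers / DE** — one-vs-rest L2 logistic regression on raw counts,
  pairwise Wilcoxon rank-sum tests (exact under ties for small groups),
  running-average expression profiles along pseudotime.
* **Commitment** — proliferating RG called by ≥1 read of *ccnd1*,
  hypergeometric over-representation of NBN.1 markers among
  proliferative-up genes, and the 4-gene neurogenic panel score
  (*ascl1a*, *sox4a*, *tmsb*, *stmn1b*) compared one-sidedly between RG
  states.
* **Cross-species homology** — an orthologue-pair expression matrix over
  zebrafish and mouse cells (many-to-many orthology preserved), ComBat
  batch correction with species as the batch, cell-ranger-flavour HVG
  pairs, 50-component joint PCA, a Pearson-distance dendrogram of cell
  types, nearest-mouse-cell label transfer and 66%-quantile rejection.
* **Synthetic data** — a two-species generator
  (`simulate_zebrafish()`, `simulate_mouse_reference()`,
  `make_ortholog_table()`) with planted populations, branching trajectory,
  proliferation/commitment programs, low-quality cells and orthologue
  structure, emitting full ground truth so every stage above is verifiable
  offline.

## Worked example

```r
library(rglineage)

sim <- simulate_zebrafish(sim_config(seed = 1))   # ~372 cells, 2000 genes
qc  <- apply_qc(sim$sce)
ncol(qc$sce) / ncol(sim$sce)
#> [1] 0.7096774        # 264/372 cells pass QC

rg_markers <- with(sim$truth$genes, gene_id[!is.na(marker_of) & marker_of == "RG"])
fit <- run_lineage(sim$sce, root_markers = rg_markers)
length(unique(fit$clusters))
#> [1] 5                # the five planted populations
fit$pseudotime[fit$root_cell]
#> [1] 0                # pseudotime starts at the root RG cell

cm <- fit$commitment
round(100 * cm$panel_comparison$frac_ge2)
#> proliferative     quiescent
#>            93            20
cm$panel_comparison$p_value
#> [1] 2.56059e-09
```

264 of 372 cells (71.0%) survive QC — the low-quality cells planted by the
generator are exactly the ones removed. Louvain clustering recovers the
five planted populations (adjusted Rand index 1.0 at these settings), and
pseudotime from the root RG cell orders the RG → NBN.1 → MN branch with
Spearman ρ ≈ 0.93 against the planted trajectory positions. Within the RG
cluster, 93% of proliferating RG express at least two of the four
neurogenic panel genes versus 20% of quiescent RG (one-sided rank-sum
p ≈ 3e-9): the planted neurogenic commitment of cycling radial glia.

For the cross-species arm, `simulate_mouse_reference()` plus
`run_crossmap()` assign each zebrafish cell its nearest mouse cell in
50-PC space after ComBat; at the default conditions ~96% of retained cells
receive their planted homologous mouse type and the modal type is correct
for all five clusters.

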