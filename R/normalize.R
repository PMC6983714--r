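#' Pooled-deconvolution size factors
#'
#' Estimates per-cell size factors by summing cells into overlapping pools
#' ordered on a library-size ring, normalizing each pool profile against the
#' average pseudo-cell, and deconvolving the stacked linear system
#' (the scran approach; computed here by [scran::calculateSumFactors()]).
#' Spike-in genes are excluded from the computation. Factors are rescaled to
#' mean 1. With fewer cells than the smallest pool, library-size factors are
#' returned with a warning.
#'
#' @param m a [count_matrix()] `SingleCellExperiment`.
#' @param pool_sizes integer pool sizes; clipped to at most the number of
#'   cells.
#' @param min_mean minimum mean count for a gene to enter the deconvolution
#'   (low-abundance genes destabilize the system).
#' @return named numeric vector of positive size factors, mean 1.
#' @export
deconvolution_size_factors <- function(m, pool_sizes = c(21, 26, 31, 36, 41),
                                       min_mean = 0.1) {
  cnt <- counts(m)[!is_spikein(m), , drop = FALSE]
  n <- ncol(cnt)
  if (n < min(pool_sizes)) {
    warning("fewer cells (", n, ") than the smallest pool (",
            min(pool_sizes), "); falling back to library-size factors")
    sf <- Matrix::colSums(cnt)
    if (any(sf <= 0)) stop("zero-count cell; cannot compute size factors")
    return(setNames(sf / mean(sf), colnames(cnt)))
  }
  sizes <- sort(unique(pmin(as.integer(pool_sizes), n)))
  sf <- scran::calculateSumFactors(as.matrix(cnt), sizes = sizes,
                                   min.mean = min_mean, positive = TRUE)
  if (any(sf <= 0)) {
    # non-positivity repair: fall back to library-size factors for the
    # offending cells, then rescale
    lib <- Matrix::colSums(cnt)
    sf[sf <= 0] <- (lib / mean(lib))[sf <= 0]
  }
  setNames(sf / mean(sf), colnames(cnt))
}

#' Log-normalize counts
#'
#' `log_values[g, c] = log(1 + count[g, c] / sf[c])` (natural log). The QC
#' stage alone uses log10, per the explicit wording of its rules; expression
#' values throughout the pipeline use natural-log log1p.
#'
#' @param m a [count_matrix()] `SingleCellExperiment`.
#' @param sf positive per-cell size factors (defaults to
#'   [deconvolution_size_factors()]).
#' @return the `SingleCellExperiment` with a `logcounts` assay, size factors
#'   stored, and `metadata(x)$transform` set to `"lognorm"`.
#' @export
lognormalize <- function(m, sf = NULL) {
  if (is.null(sf)) sf <- deconvolution_size_factors(m)
  if (any(sf <= 0)) stop("size factors must be positive")
  stopifnot(length(sf) == ncol(m))
  lc <- log1p(sweep(as.matrix(counts(m)), 2, sf, "/"))
  logcounts(m) <- lc
  sizeFactors(m) <- unname(sf)
  metadata(m)$transform <- "lognorm"
  m
}

#' Highly variable gene selection (dispersion-based)
#'
#' Computes, per gene, the mean and dispersion (variance/mean) of the
#' back-transformed expression (`expm1` of the log values), z-scores the
#' dispersions within equal-frequency mean bins, and selects genes with
#' `min_mean < mean < max_mean` and normalized dispersion above `min_disp`.
#' These are the Seurat-flavour semantics of the selection the analyzed
#' study ran with only `max_mean` overridden to 8.
#'
#' @param n a log-normalized `SingleCellExperiment` (or a plain genes x cells
#'   matrix of log values).
#' @param max_mean,min_mean mean-expression window; the upper cutoff excludes
#'   ubiquitous high-expression genes.
#' @param min_disp minimum normalized dispersion.
#' @param n_bins number of equal-frequency mean bins for dispersion
#'   normalization; a bin with a single gene (or zero dispersion spread)
#'   yields z-score 0.
#' @return data.frame per gene: `gene_id`, `mean`, `dispersion`,
#'   `normalized_dispersion`, `selected`.
#' @export
select_hvg <- function(n, max_mean = 8, min_mean = 0.0125, min_disp = 0.5,
                       n_bins = 20) {
  lv <- if (is(n, "SingleCellExperiment")) logcounts(n) else n
  x <- expm1(as.matrix(lv))
  raw_mu <- rowMeans(x)
  v <- apply(x, 1, var)
  disp <- ifelse(raw_mu > 0, v / raw_mu, 0)
  # mean and dispersion are compared on the log scale, as in the reference
  # implementation: cutoffs apply to log1p(mean), z-scores to log dispersion
  ldisp <- log(ifelse(disp > 0, disp, NA))
  mu <- log1p(raw_mu)
  nz <- sum(raw_mu > 0)
  if (nz < n_bins) stop("need at least n_bins genes with nonzero mean")
  br <- unique(quantile(mu[raw_mu > 0],
                        probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  zs <- rep(0, length(mu))
  for (b in levels(bin)) {
    i <- which(bin == b & !is.na(ldisp))
    if (length(i) < 2) next
    s <- sd(ldisp[i])
    if (is.na(s) || s == 0) next
    zs[i] <- (ldisp[i] - mean(ldisp[i])) / s
  }
  selected <- mu > min_mean & mu < max_mean & zs > min_disp
  data.frame(gene_id = rownames(lv), mean = mu, dispersion = disp,
             normalized_dispersion = zs, selected = selected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scale genes to zero mean and unit variance
#'
#' Per-gene centering and division by the sample standard deviation, applied
#' to the log-normalized values (optionally restricted to HVGs).
#' Zero-variance genes map to all-zero rows. No value clipping is applied.
#'
#' @param n a log-normalized `SingleCellExperiment` or matrix.
#' @param genes optional gene ids to restrict to (e.g. selected HVGs).
#' @return genes x cells matrix of scaled values.
#' @export
scale_unit_variance <- function(n, genes = NULL) {
  lv <- if (is(n, "SingleCellExperiment")) logcounts(n) else n
  lv <- as.matrix(lv)
  if (!is.null(genes)) lv <- lv[genes, , drop = FALSE]
  ctr <- lv - rowMeans(lv)
  s <- apply(lv, 1, sd)
  out <- ctr / ifelse(s > 0, s, Inf)
  out
}
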