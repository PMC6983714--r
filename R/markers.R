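#' Wilcoxon rank-sum test (exact small-sample branch with ties)
#'
#' Computes the Mann-Whitney U statistic on midranks. For pooled sample
#' sizes up to `exact_max` the p-value is computed by exhaustive enumeration
#' of all group assignments (valid under ties); otherwise a tie-corrected
#' normal approximation with continuity correction is used. Two-sided
#' p-values in the exact branch are `P(|U - E[U]| >= |u - E[U]|)` under the
#' permutation distribution.
#'
#' @param x,y numeric vectors (group a, group b).
#' @param alternative `"two.sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @param exact_max largest pooled size for the enumeration branch.
#' @return list with `statistic` (U of group a) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "greater",
                                                    "less"),
                              exact_max = 10) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  stopifnot(nx > 0, ny > 0)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (nx + ny <= exact_max) {
    idx <- combn(nx + ny, nx)
    us <- apply(idx, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
    p <- switch(alternative,
                two.sided = mean(abs(us - mu) >= abs(u - mu) - 1e-12),
                greater = mean(us >= u - 1e-12),
                less = mean(us <= u + 1e-12))
  } else {
    n <- nx + ny
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
    sig2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sig2 <= 0) return(list(statistic = u, p_value = 1))
    cc <- 0.5
    p <- switch(alternative,
                two.sided = {
                  z <- (abs(u - mu) - cc) / sqrt(sig2)
                  min(1, 2 * pnorm(z, lower.tail = FALSE))
                },
                greater = pnorm((u - mu - cc) / sqrt(sig2),
                                lower.tail = FALSE),
                less = pnorm((u - mu + cc) / sqrt(sig2)))
  }
  list(statistic = u, p_value = min(1, max(0, p)))
}

#' Pairwise differential expression by Wilcoxon rank-sum
#'
#' Per-gene two-sided rank-sum test between two cell groups on the
#' log-normalized expression, with Benjamini-Hochberg adjustment across
#' genes. Genes with all values tied give p = 1.
#'
#' @param n a log-normalized `SingleCellExperiment` or genes x cells matrix.
#' @param group_a,group_b disjoint, non-empty cell id (or index) sets.
#' @param exact_max see [wilcoxon_rank_sum()].
#' @return data.frame per gene: `gene_id`, `statistic` (U of group a),
#'   `p_value`, `adjusted_p`, `log_fold_change` (mean a minus mean b of the
#'   log values) and `direction` (`"up"` = higher in group a).
#' @export
pairwise_wilcoxon <- function(n, group_a, group_b, exact_max = 10) {
  lv <- if (is(n, "SingleCellExperiment")) logcounts(n) else n
  lv <- as.matrix(lv)
  if (is.character(group_a)) group_a <- match(group_a, colnames(lv))
  if (is.character(group_b)) group_b <- match(group_b, colnames(lv))
  stopifnot(length(group_a) > 0, length(group_b) > 0,
            !anyNA(group_a), !anyNA(group_b),
            length(intersect(group_a, group_b)) == 0)
  res <- t(vapply(seq_len(nrow(lv)), function(g) {
    xa <- lv[g, group_a]; xb <- lv[g, group_b]
    w <- wilcoxon_rank_sum(xa, xb, "two.sided", exact_max)
    c(w$statistic, w$p_value, mean(xa) - mean(xb))
  }, numeric(3)))
  data.frame(gene_id = rownames(lv), statistic = res[, 1],
             p_value = res[, 2],
             adjusted_p = stats::p.adjust(res[, 2], "BH"),
             log_fold_change = res[, 3],
             direction = ifelse(res[, 3] >= 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster markers by one-vs-rest logistic regression
#'
#' Fits, per cluster, an L2-regularized logistic regression of cluster
#' membership on the raw count matrix (no scaling) and ranks genes by
#' descending coefficient. Perfectly separating genes are handled by the
#' ridge penalty.
#'
#' @param raw a [count_matrix()] `SingleCellExperiment` or genes x cells
#'   matrix of raw counts.
#' @param clusters cluster label per cell.
#' @param l2_strength inverse regularization strength C; the ridge penalty
#'   is `lambda = 1 / (n_cells * C)`. The default (0.1) applies strong
#'   shrinkage, which stabilizes the per-gene coefficient ranking on raw
#'   counts; weaker penalties let the fit concentrate weight on a few
#'   low-count genes and degrade the marker ranking.
#' @param seed integer seed (the fit itself is deterministic; the seed fixes
#'   any backend initialization).
#' @return data.frame `cluster`, `gene_id`, `score` (coefficient), `rank`
#'   (1-based, per cluster, scores non-increasing).
#' @export
marker_genes_logreg <- function(raw, clusters, l2_strength = 0.1,
                                seed = 0L) {
  cnt <- if (is(raw, "SingleCellExperiment")) counts(raw) else raw
  x <- Matrix::t(cnt)
  labs <- as.character(clusters)
  stopifnot(ncol(cnt) == length(labs))
  tab <- table(labs)
  if (length(tab) < 2) stop("need at least two clusters")
  if (any(tab < 2)) stop("every cluster needs at least two cells")
  lambda <- 1 / (nrow(x) * l2_strength)
  set.seed(seed)
  out <- lapply(names(sort(tab, decreasing = TRUE)), function(cl) {
    y <- as.integer(labs == cl)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    beta <- as.numeric(fit$beta)
    o <- order(-beta, seq_along(beta))
    data.frame(cluster = cl, gene_id = rownames(cnt)[o], score = beta[o],
               rank = seq_along(beta), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Running-average expression along pseudotime
#'
#' Orders cells by pseudotime (ties broken by cell index) and replaces each
#' value by the mean of a window of `window` cells centred on its position;
#' windows are truncated (shrink) at the boundaries so the output keeps one
#' column per cell.
#'
#' @param expr a log-normalized `SingleCellExperiment` or genes x cells
#'   matrix.
#' @param ordering named pseudotime vector covering the columns of `expr`.
#' @param window odd or even window width in cells, `>= 1`.
#' @return genes x cells matrix, columns in pseudotime order.
#' @export
running_average <- function(expr, ordering, window = 15) {
  lv <- if (is(expr, "SingleCellExperiment")) logcounts(expr) else expr
  lv <- as.matrix(lv)
  stopifnot(window >= 1, window <= ncol(lv))
  ord <- order(ordering[colnames(lv)], seq_len(ncol(lv)))
  lv <- lv[, ord, drop = FALSE]
  n <- ncol(lv)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  cs <- cbind(0, t(apply(lv, 1, cumsum)))
  out <- lv
  for (j in seq_len(n)) {
    a <- max(1, j - half_lo); b <- min(n, j + half_hi)
    out[, j] <- (cs[, b + 1] - cs[, a]) / (b - a + 1)
  }
  out
}
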