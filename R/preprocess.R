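#' Filter, normalize and select highly variable genes
#'
#' Standard single-cell preprocessing on an expression trajectory, applied in
#' this order: (1) remove cells expressing fewer than `min_genes_per_cell`
#' genes; (2) remove genes detected in fewer than `min_cells_per_gene`
#' surviving cells; (3) optionally remove cells whose mitochondrial-count
#' fraction exceeds a dataset-specific quantile; (4) scale each cell's
#' counts to a common total (`target_sum`); (5) keep the `n_hvg` genes of
#' highest mean-binned normalized dispersion; (6) optionally `log1p`
#' transform.  Surviving cells keep their relative trajectory order.
#'
#' Dispersion ranking is deterministic: per-gene dispersion = variance/mean
#' of the normalized counts, z-scored within 20 equal-frequency mean bins;
#' ties break by input gene order.
#'
#' @param trajectory an [expression_trajectory()] of non-negative counts.
#' @param min_genes_per_cell,min_cells_per_gene non-negative count filters.
#' @param n_hvg number of highly variable genes to keep; `Inf` keeps all.
#' @param target_sum per-cell total after normalization.
#' @param mito_quantile optional quantile in (0,1); cells whose fraction of
#'   counts on genes matching `mito_pattern` exceeds this quantile of the
#'   per-cell distribution are removed. `NULL` (default) disables the filter.
#' @param mito_pattern regular expression identifying mitochondrial genes.
#' @param log1p whether to log-transform after normalization (default TRUE);
#'   the choice is recorded in the result's `preprocess` attribute.
#' @param hvg_bins number of equal-frequency mean bins for the dispersion
#'   z-score (1 ranks by raw dispersion).
#' @return a filtered [expression_trajectory()]; attribute `preprocess`
#'   records the parameters and the log choice.
#' @export
preprocess <- function(trajectory, min_genes_per_cell = 200,
                       min_cells_per_gene = 3, n_hvg = 500,
                       target_sum = 1e4, mito_quantile = NULL,
                       mito_pattern = "^(MT-|mt-)", log1p = TRUE,
                       hvg_bins = 20) {
  stopifnot(inherits(trajectory, "expression_trajectory"))
  if (min_genes_per_cell < 0 || min_cells_per_gene < 0)
    stop_config("filter thresholds must be non-negative")
  X <- trajectory$values
  keep_cells <- colSums(X > 0) >= min_genes_per_cell
  if (!any(keep_cells)) stop_structural("all cells removed by the gene-count filter")
  X <- X[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(X > 0) >= min_cells_per_gene
  if (!any(keep_genes)) stop_structural("all genes removed by the cell-count filter")
  X <- X[keep_genes, , drop = FALSE]
  if (!is.null(mito_quantile)) {
    mito_quantile <- check_prob(mito_quantile, "mito_quantile")
    mt <- grepl(mito_pattern, rownames(X))
    frac <- if (any(mt)) colSums(X[mt, , drop = FALSE]) / pmax(colSums(X), 1e-12)
            else rep(0, ncol(X))
    cut <- stats::quantile(frac, mito_quantile)
    ok <- frac <= cut
    if (!any(ok)) stop_structural("all cells removed by the mitochondrial filter")
    X <- X[, ok, drop = FALSE]
  }
  totals <- colSums(X)
  if (any(totals == 0)) stop_structural("cell with zero total counts after filtering")
  Xn <- sweep(X, 2L, totals / target_sum, "/")
  if (is.finite(n_hvg) && n_hvg < nrow(Xn)) {
    n_hvg <- check_count(n_hvg, "n_hvg", min = 1L)
    keep_hvg <- hvg_indices(Xn, n_hvg, n_bins = hvg_bins)
    Xn <- Xn[sort(keep_hvg), , drop = FALSE]
  }
  if (log1p) Xn <- log1p(Xn)
  surv_cells <- colnames(Xn)
  # keep surviving cells in the relative order the input trajectory gave them
  old_order <- trajectory$cell_names[trajectory$pseudotime_rank]
  new_order <- old_order[old_order %in% surv_cells]
  out <- expression_trajectory(Xn[, surv_cells, drop = FALSE],
                               pseudotime_rank = match(new_order, surv_cells))
  attr(out, "preprocess") <- list(min_genes_per_cell = min_genes_per_cell,
                                  min_cells_per_gene = min_cells_per_gene,
                                  n_hvg = n_hvg, target_sum = target_sum,
                                  mito_quantile = mito_quantile,
                                  log1p = log1p, hvg_bins = hvg_bins)
  out
}

# top-n genes by mean-binned normalized dispersion (variance/mean z-scored
# within 20 equal-frequency mean bins); deterministic, ties by row order
hvg_indices <- function(Xn, n_hvg, n_bins = 20L) {
  mu <- rowMeans(Xn)
  v <- apply(Xn, 1L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1L, min(n_bins, floor(nrow(Xn) / 2)))
  bins <- if (n_bins == 1L) rep(1L, nrow(Xn)) else
    cut(rank(mu, ties.method = "first"),
        breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  zd <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    zd[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  order(zd, decreasing = TRUE)[seq_len(n_hvg)]
}
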