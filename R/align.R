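#' Align expression, embeddings and edges onto a shared gene universe
#'
#' Restricts all three inputs to the intersection of the trajectory's and the
#' embedding table's gene sets (order taken from the trajectory) and drops
#' edges that touch removed genes, reporting how many were dropped via a
#' message.
#'
#' @param trajectory an [expression_trajectory()].
#' @param embeddings an [embedding_table()].
#' @param edges an [edge_set()] (may be `NULL` for prediction-only use).
#' @return object of class `aligned_dataset` with fields `trajectory`,
#'   `embeddings`, `edges`, `gene_names` and `dropped_edges` (count).
#' @export
align <- function(trajectory, embeddings, edges = NULL) {
  stopifnot(inherits(trajectory, "expression_trajectory"),
            inherits(embeddings, "embedding_table"))
  shared <- intersect(trajectory$gene_names, embeddings$gene_names)
  if (length(shared) == 0L)
    stop_structural("no genes shared between expression matrix and embedding table")
  shared <- trajectory$gene_names[trajectory$gene_names %in% shared]
  traj <- expression_trajectory(
    trajectory$values[shared, , drop = FALSE],
    gene_names = shared, cell_names = trajectory$cell_names,
    pseudotime_rank = trajectory$pseudotime_rank)
  emb <- embedding_table(embeddings$vectors[match(shared, embeddings$gene_names), ,
                                            drop = FALSE],
                         gene_names = shared)
  dropped <- 0L
  if (!is.null(edges)) {
    stopifnot(inherits(edges, "edge_set"))
    keep <- edges$edges$regulator %in% shared & edges$edges$target %in% shared
    dropped <- sum(!keep)
    if (dropped > 0L)
      message(sprintf("align: dropped %d edge(s) touching genes outside the shared universe", dropped))
    kept <- edges$edges[keep, , drop = FALSE]
    edges <- edge_set(kept,
                      regulator_universe =
                        intersect(edges$regulator_universe, shared))
  }
  structure(list(trajectory = traj, embeddings = emb, edges = edges,
                 gene_names = shared, dropped_edges = dropped),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("<aligned_dataset> %d genes, %d cells, embedding dim %d\n",
              length(x$gene_names), ncol(x$trajectory$values),
              x$embeddings$dim))
  if (!is.null(x$edges))
    cat(sprintf("  %d labeled edges (%d positive)\n", nrow(x$edges$edges),
                sum(x$edges$edges$label == 1L)))
  invisible(x)
}
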