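#' Build a train/test split plan over labeled edges
#'
#' Two schemes:
#' \describe{
#'   \item{`edge_kfold_inverted`}{edges are shuffled and partitioned into
#'     `k` disjoint shards; fold i *trains* on shard i (1/k of the edges)
#'     and tests on the remaining k-1 shards.  This is the deliberately
#'     data-poor protocol: with k = 10 only 10\% of the labels are seen in
#'     training.}
#'   \item{`tf_holdout`}{the regulator universe is shuffled and partitioned
#'     into `k` groups; fold i tests on all edges whose regulator is in
#'     group i and trains on the rest, so no regulator ever appears on both
#'     sides.}
#' }
#'
#' @param edges an [edge_set()].
#' @param scheme `"edge_kfold_inverted"` or `"tf_holdout"`.
#' @param k number of folds.
#' @param seed integer seed; plans are deterministic given it.
#' @return object of class `split_plan`: `scheme`, `k`, `seed`, and `folds`
#'   -- a list of lists with integer `train` and `test` edge row indices.
#' @export
make_split <- function(edges, scheme = c("edge_kfold_inverted", "tf_holdout"),
                       k = 10, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(edges, "edge_set"))
  k <- check_count(k, "k", 2L)
  ed <- edges$edges
  n <- nrow(ed)
  both_classes <- length(unique(ed$label)) == 2L
  folds <- with_seed(seed, {
    if (scheme == "edge_kfold_inverted") {
      if (n < k) stop_structural("fewer edges than folds")
      shard <- sample(rep_len(seq_len(k), n))
      lapply(seq_len(k), function(i)
        list(train = which(shard == i), test = which(shard != i)))
    } else {
      regs <- sample(edges$regulator_universe)
      if (length(regs) < k)
        stop_structural("fewer regulators than folds for tf_holdout")
      grp <- split(regs, rep_len(seq_len(k), length(regs)))
      lapply(seq_len(k), function(i) {
        test <- which(ed$regulator %in% grp[[i]])
        list(train = setdiff(seq_len(n), test), test = test)
      })
    }
  })
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    if (length(f$train) == 0L || length(f$test) == 0L)
      stop_structural(sprintf("fold %d has an empty train or test side", i))
    if (both_classes && length(unique(ed$label[f$train])) < 2L)
      stop_structural(sprintf(
        "fold %d has single-class training labels; re-seed or change k", i))
  }
  structure(list(scheme = scheme, k = k, seed = as.integer(seed),
                 folds = folds, n_edges = n),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$train), integer(1))
  cat(sprintf("<split_plan> %s, %d folds over %d edges (train sizes %s)\n",
              x$scheme, x$k, x$n_edges,
              paste(range(sizes), collapse = "-")))
  invisible(x)
}

#' Serialize / restore a split plan
#'
#' @param plan a [make_split()] result.
#' @param path JSON file path.
#' @return `path` invisibly / the restored `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$folds <- lapply(seq_len(nrow_or_len(x$folds)), function(i) {
    f <- if (is.data.frame(x$folds)) x$folds[i, ] else x$folds[[i]]
    list(train = as.integer(unlist(f$train)), test = as.integer(unlist(f$test)))
  })
  structure(x, class = "split_plan")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Remove train/test pair overlap for cross-dataset transfer
#'
#' Drops from `test_edges` every (regulator, target) pair that occurs in
#' `train_edges`, regardless of label, so a model trained on one dataset is
#' never evaluated on pairs it saw.
#'
#' @param train_edges,test_edges [edge_set()] objects.
#' @return the filtered test [edge_set()]; attribute `removed` carries the
#'   number of dropped pairs.
#' @export
cross_dataset_filter <- function(train_edges, test_edges) {
  stopifnot(inherits(train_edges, "edge_set"), inherits(test_edges, "edge_set"))
  shared <- edge_keys(test_edges) %in% edge_keys(train_edges)
  if (all(shared))
    stop_structural("no test edges remain after removing pairs shared with training")
  kept <- test_edges$edges[!shared, , drop = FALSE]
  out <- edge_set(kept, regulator_universe = test_edges$regulator_universe)
  attr(out, "removed") <- sum(shared)
  out
}
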