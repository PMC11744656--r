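#' Run a full train/evaluate protocol on an aligned dataset
#'
#' For each fold of the split plan: take the fold's positive training edges,
#' sample fresh fold-seeded label-0 negatives (train negatives avoid every
#' known positive; test negatives additionally avoid the train negatives),
#' train the link predictor on the fold's labeled training set, score the
#' held-out edges, and compute the full metric battery.  The autoencoder is
#' trained once on the whole trajectory (it never sees edge labels, so no
#' information leaks across folds) unless precomputed `temporal` features
#' are supplied.
#'
#' @param dataset an `aligned_dataset` whose `edges` carry the positive
#'   (label-1) pairs; any label-0 rows are ignored in favour of fold-local
#'   sampling.
#' @param scheme `"edge_kfold_inverted"` (train on 1/k of the edges, test on
#'   the rest) or `"tf_holdout"` (no regulator shared between sides).
#' @param k number of folds.
#' @param tcn a [tcn_config()] used when `temporal` is `NULL`.
#' @param predictor a [predictor_config()]; each fold trains with seed
#'   `predictor$seed + fold`.
#' @param negative_ratio negatives per positive on both sides of each fold.
#' @param seed integer seed for the split plan and negative sampling.
#' @param threshold threshold for the confusion-based metrics.
#' @param temporal optional precomputed `latent_features` (e.g. shared
#'   between a real run and a permuted control).
#' @param folds which folds to run (default all); indices into the plan.
#' @param permute_train_labels if `TRUE`, randomly permute the labels of
#'   each fold's training set (seeded) -- the chance-level control arm.
#' @return object of class `grn_protocol`: `per_fold` data.frame of metrics,
#'   `aggregate` (mean and sd per metric), the `plan`, and per-fold score
#'   tables.
#' @export
run_protocol <- function(dataset, scheme = c("edge_kfold_inverted", "tf_holdout"),
                         k = 10, tcn = tcn_config(),
                         predictor = predictor_config(),
                         negative_ratio = 1, seed = 1L, threshold = 0.5,
                         temporal = NULL, folds = NULL,
                         permute_train_labels = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "aligned_dataset"))
  pos <- dataset$edges$edges
  pos <- pos[pos$label == 1L, , drop = FALSE]
  if (nrow(pos) == 0L) stop_structural("dataset has no positive edges")
  pos_set <- edge_set(pos, regulator_universe = dataset$edges$regulator_universe)
  universe <- dataset$gene_names
  if (is.null(temporal)) {
    ae <- fit_autoencoder(dataset$trajectory, tcn)
    temporal <- encode_trajectory(dataset$trajectory, ae)
  }
  plan <- make_split(pos_set, scheme, k = k, seed = seed)
  if (is.null(folds)) folds <- seq_len(plan$k)
  base_seed <- (as.integer(seed) %% 1000000L) * 1000L  # keep fold seeds < 2^31
  rows <- list(); tables <- list()
  for (f in folds) {
    fold <- plan$folds[[f]]
    tr_pos <- edge_set(pos[fold$train, , drop = FALSE])
    te_pos <- edge_set(pos[fold$test, , drop = FALSE])
    tr_neg <- sample_negatives(tr_pos, universe, negative_ratio,
                               seed = base_seed + f * 10L + 1L,
                               exclude = pos_set)
    te_neg <- sample_negatives(te_pos, universe, negative_ratio,
                               seed = base_seed + f * 10L + 2L,
                               exclude = combine_edges(pos_set, tr_neg))
    train_edges <- combine_edges(tr_pos, tr_neg)
    if (permute_train_labels) {
      perm <- with_seed(base_seed + f * 10L + 3L,
                        sample.int(nrow(train_edges$edges)))
      train_edges$edges$label <- train_edges$edges$label[perm]
    }
    cfg_f <- predictor
    cfg_f$seed <- predictor$seed + f
    model <- train_predictor(dataset$embeddings, temporal, train_edges, cfg_f)
    test_edges <- combine_edges(te_pos, te_neg)$edges
    sc <- predict(model, test_edges[, c("regulator", "target")], sort = FALSE)
    rep <- metric_report(sc$score, test_edges$label, threshold)
    tab <- cbind(test_edges, score = sc$score)
    rows[[length(rows) + 1L]] <- cbind(fold = f, metric_report_row(rep))
    tables[[length(tables) + 1L]] <- tab
  }
  per_fold <- do.call(rbind, rows)
  mets <- per_fold[, setdiff(names(per_fold), "fold"), drop = FALSE]
  aggregate <- data.frame(metric = names(mets),
                          mean = vapply(mets, mean, numeric(1)),
                          sd = vapply(mets, stats::sd, numeric(1)),
                          row.names = NULL)
  structure(list(per_fold = per_fold, aggregate = aggregate, plan = plan,
                 score_tables = tables, threshold = threshold,
                 scheme = scheme, permuted = permute_train_labels),
            class = "grn_protocol")
}

#' @export
print.grn_protocol <- function(x, ...) {
  cat(sprintf("<grn_protocol> %s%s, %d fold(s) evaluated\n", x$scheme,
              if (x$permuted) " (label-permuted control)" else "",
              nrow(x$per_fold)))
  agg <- x$aggregate
  for (m in c("auroc", "auprc"))
    cat(sprintf("  %s: %.4f (sd %.4f)\n", m, agg$mean[agg$metric == m],
                agg$sd[agg$metric == m]))
  invisible(x)
}
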