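#' Fit the full regulatory-link model
#'
#' One-call interface tying the pipeline together: trains the
#' temporal-convolutional autoencoder on the pseudotime-ordered expression
#' matrix, encodes each gene into latent temporal features, fuses them with
#' the prior-knowledge embeddings, samples negatives to balance the labeled
#' positive edges, and trains the Transformer link predictor.
#'
#' @param data an `aligned_dataset` from [align()] or [make_benchmark()].
#' @param edges training [edge_set()]; defaults to the dataset's edges.
#'   Label-1 rows are the positives; when no label-0 rows are present,
#'   negatives are sampled at `negative_ratio`.
#' @param tcn a [tcn_config()].
#' @param predictor a [predictor_config()].
#' @param negative_ratio negatives sampled per positive (used only when
#'   `edges` has no label-0 rows).
#' @param seed integer seed for negative sampling.
#' @return object of class `grn_fit` with components `autoencoder`,
#'   `temporal`, `predictor`, `train_edges` and the dataset's gene universe.
#' @examples
#' bench <- make_benchmark(sim_config(n_genes = 20, n_tfs = 3, n_cells = 50))
#' fit <- grn_fit(bench$dataset,
#'                tcn = tcn_config(epochs = 5),
#'                predictor = predictor_config(epochs = 5))
#' head(predict(fit, all_pairs = TRUE))
#' @export
grn_fit <- function(data, edges = data$edges, tcn = tcn_config(),
                    predictor = predictor_config(), negative_ratio = 1,
                    seed = 1L) {
  stopifnot(inherits(data, "aligned_dataset"))
  if (is.null(edges)) stop_usage("no training edges supplied")
  ae <- fit_autoencoder(data$trajectory, tcn)
  temporal <- encode_trajectory(data$trajectory, ae)
  if (!any(edges$edges$label == 0L)) {
    neg <- sample_negatives(edges, data$gene_names, negative_ratio,
                            seed = seed)
    edges <- combine_edges(edges, neg)
  }
  pred <- train_predictor(data$embeddings, temporal, edges, predictor)
  structure(list(autoencoder = ae, temporal = temporal, predictor = pred,
                 train_edges = edges, gene_names = data$gene_names,
                 regulator_universe = edges$regulator_universe,
                 seed = as.integer(seed)),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("Regulatory link model\n")
  cat(sprintf("  genes: %d   training edges: %d (%d positive)\n",
              length(x$gene_names), nrow(x$train_edges$edges),
              sum(x$train_edges$edges$label == 1L)))
  cat(sprintf("  temporal features: %d dims (autoencoder MSE %.4g -> %.4g over %d epochs)\n",
              ncol(x$temporal$features),
              if (length(x$autoencoder$loss)) x$autoencoder$loss[1] else NA,
              if (length(x$autoencoder$loss)) tail_val(x$autoencoder$loss) else NA,
              length(x$autoencoder$loss)))
  cat(sprintf("  predictor BCE %.4f -> %.4f over %d epochs\n",
              if (length(x$predictor$loss)) x$predictor$loss[1] else NA,
              if (length(x$predictor$loss)) tail_val(x$predictor$loss) else NA,
              length(x$predictor$loss)))
  invisible(x)
}

tail_val <- function(x) x[length(x)]

#' @export
summary.grn_fit <- function(object, ...) {
  sc <- predict(object, object$train_edges$edges[, c("regulator", "target")],
                sort = FALSE)
  rep <- metric_report(sc$score, object$train_edges$edges$label)
  out <- list(fit = object, train_metrics = rep)
  class(out) <- "summary.grn_fit"
  out
}

#' @export
print.summary.grn_fit <- function(x, ...) {
  print(x$fit)
  cat("Training-set metrics (in-sample, optimistic):\n")
  print(x$train_metrics)
  invisible(x)
}

#' Score candidate edges with a fitted model
#'
#' @param object a [grn_fit()] result.
#' @param pairs data.frame of `regulator`, `target` pairs; or `NULL` with
#'   `all_pairs = TRUE` to score every (regulator, gene) pair, self-pairs
#'   excluded, using the model's regulator universe by default.
#' @param all_pairs score all pairs instead of an explicit list.
#' @param regulators regulators for `all_pairs` (default: the training
#'   regulator universe).  Regulators never seen in training edges may be
#'   scored as long as they are in the gene universe.
#' @param sort sort by descending score.
#' @param ... unused.
#' @return data.frame `regulator`, `target`, `score`.
#' @export
predict.grn_fit <- function(object, pairs = NULL, all_pairs = FALSE,
                            regulators = NULL, sort = TRUE, ...) {
  if (all_pairs && is.null(regulators)) regulators <- object$regulator_universe
  predict(object$predictor, pairs = pairs, all_pairs = all_pairs,
          regulators = regulators, sort = sort)
}

#' Plot training diagnostics of a fitted model
#'
#' Two panels: the autoencoder reconstruction-loss curve and the predictor
#' BCE curve.
#'
#' @param x a [grn_fit()] result.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.grn_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$autoencoder$loss, type = "l", xlab = "epoch",
       ylab = "reconstruction MSE", main = "TCN autoencoder", ...)
  plot(x$predictor$loss, type = "l", xlab = "epoch", ylab = "BCE",
       main = "link predictor", ...)
  invisible(x)
}

#' Save / load a fitted model
#'
#' Single-file checkpoint with all parameters and configs embedded.
#'
#' @param object a `grn_fit`, `grn_predictor` or `tcn_autoencoder` object.
#' @param path checkpoint file path.
#' @return `path` invisibly / the restored object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("checkpoint not found: %s", path))
  readRDS(path)
}
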