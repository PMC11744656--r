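#' Labeled edge set
#'
#' Directed regulator -> target pairs with binary labels (1 = known
#' regulatory interaction, 0 = sampled non-interaction).  The regulator
#' universe records which genes are eligible edge sources (typically
#' transcription factors); by default it is the set of regulators observed
#' among the edges.
#'
#' @param edges data.frame with columns `regulator`, `target` (character)
#'   and `label` (0/1; defaults to all 1 when absent).
#' @param regulator_universe character vector of genes eligible as sources.
#' @return object of class `edge_set` with fields `edges` (data.frame) and
#'   `regulator_universe`.
#' @export
edge_set <- function(edges, regulator_universe = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("regulator", "target") %in% names(edges)))
    stop_structural("edge set needs 'regulator' and 'target' columns")
  if (is.null(edges$label)) edges$label <- 1L
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  edges$label <- as.integer(edges$label)
  if (!all(edges$label %in% c(0L, 1L)))
    stop_structural("edge labels must be 0 or 1")
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    lab_per_pair <- tapply(edges$label, key, function(l) length(unique(l)))
    if (any(lab_per_pair > 1L))
      stop_structural(sprintf("conflicting labels for pair(s): %s",
        paste(gsub("\r", "->", names(lab_per_pair)[lab_per_pair > 1L]),
              collapse = ", ")))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  if (is.null(regulator_universe))
    regulator_universe <- unique(edges$regulator)
  regulator_universe <- unique(as.character(regulator_universe))
  pos_reg <- unique(edges$regulator[edges$label == 1L])
  if (!all(pos_reg %in% regulator_universe))
    stop_structural("every regulator of a positive edge must be in the regulator universe")
  rownames(edges) <- NULL
  structure(list(edges = edges[, c("regulator", "target", "label")],
                 regulator_universe = regulator_universe),
            class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set> %d edges (%d positive), %d regulators\n",
              nrow(x$edges), sum(x$edges$label == 1L),
              length(x$regulator_universe)))
  invisible(x)
}

edge_keys <- function(es) paste(es$edges$regulator, es$edges$target, sep = "\r")

#' Read a labeled edge list
#'
#' TSV with header `regulator<TAB>target[<TAB>label]`; when the label column
#' is absent every pair is a positive (label 1).  Duplicate rows with the
#' same label are collapsed; the same pair carrying conflicting labels is a
#' structural error.
#'
#' @param path file path.
#' @return an [edge_set()].
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop_parse(sprintf("cannot parse %s: %s", path,
                                           conditionMessage(e))))
  if (!all(c("regulator", "target") %in% names(tab)))
    stop_parse(sprintf("%s: header must contain 'regulator' and 'target'", path))
  edge_set(tab)
}

#' Write a labeled edge list
#'
#' @param es an [edge_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(es, path) {
  stopifnot(inherits(es, "edge_set"))
  utils::write.table(es$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sample negative (label-0) edges
#'
#' Draws `ceiling(ratio * n_positive)` directed pairs uniformly without
#' replacement from the candidate set \{(r, t): r in the regulator universe,
#' t in `universe`, r != t\} minus the positive pairs and any pairs in
#' `exclude`.  Constraining sources to the observed regulator universe
#' matches the evaluation task (ranking TF -> gene pairs); pass
#' `regulators = universe` for unconstrained sampling.
#'
#' @param positives an [edge_set()]; its label-1 edges define the positives
#'   and its `regulator_universe` the candidate sources.
#' @param universe character vector of all genes eligible as targets.
#' @param ratio positive real; number of negatives per positive.
#' @param seed integer seed (sampling is deterministic given it).
#' @param exclude optional [edge_set()] whose pairs are removed from the
#'   candidate pool (e.g. negatives already drawn for another fold).
#' @param regulators optional override of the candidate source set.
#' @return an [edge_set()] of label-0 pairs.
#' @export
sample_negatives <- function(positives, universe, ratio = 1, seed = 1L,
                             exclude = NULL, regulators = NULL) {
  stopifnot(inherits(positives, "edge_set"))
  if (!is.numeric(ratio) || ratio <= 0) stop_config("'ratio' must be positive")
  universe <- unique(as.character(universe))
  regs <- if (is.null(regulators)) positives$regulator_universe else
    unique(as.character(regulators))
  pos <- positives$edges[positives$edges$label == 1L, , drop = FALSE]
  n_neg <- ceiling(ratio * nrow(pos))
  cand_r <- rep(regs, each = length(universe))
  cand_t <- rep(universe, times = length(regs))
  keep <- cand_r != cand_t
  key <- paste(cand_r, cand_t, sep = "\r")
  banned <- paste(pos$regulator, pos$target, sep = "\r")
  if (!is.null(exclude)) banned <- c(banned, edge_keys(exclude))
  keep <- keep & !(key %in% banned)
  idx <- which(keep)
  if (length(idx) < n_neg)
    stop_structural(sprintf(
      "only %d candidate non-edges available but %d negatives requested",
      length(idx), n_neg))
  pick <- with_seed(seed, sample(idx, n_neg, replace = FALSE))
  edge_set(data.frame(regulator = cand_r[pick], target = cand_t[pick],
                      label = 0L, stringsAsFactors = FALSE),
           regulator_universe = regs)
}

# rbind two edge sets (labels kept), regulator universe is the union
combine_edges <- function(a, b) {
  edge_set(rbind(a$edges, b$edges),
           regulator_universe = union(a$regulator_universe, b$regulator_universe))
}
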