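#' Expression trajectory container
#'
#' Holds a genes x cells expression matrix whose cells are ordered along a
#' trajectory (pseudotime).  The ordering itself is an input to this package:
#' any trajectory-inference tool may produce it upstream.  `pseudotime_rank`
#' is a permutation of cell indices giving the trajectory order; by default
#' cells are taken in column order.
#'
#' @param values numeric matrix, genes in rows, cells in columns. All entries
#'   must be finite and non-negative.
#' @param gene_names,cell_names unique identifiers for rows / columns. Taken
#'   from `dimnames(values)` when omitted.
#' @param pseudotime_rank integer permutation of `seq_len(ncol(values))`;
#'   `pseudotime_rank[k]` is the column index of the k-th cell along the
#'   trajectory. Defaults to the identity.
#' @return an object of class `expression_trajectory` with fields
#'   `values`, `gene_names`, `cell_names`, `pseudotime_rank`.
#' @export
expression_trajectory <- function(values, gene_names = rownames(values),
                                  cell_names = colnames(values),
                                  pseudotime_rank = seq_len(ncol(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(nrow(values)))
  if (is.null(cell_names)) cell_names <- paste0("cell", seq_len(ncol(values)))
  gene_names <- as.character(gene_names)
  cell_names <- as.character(cell_names)
  if (length(gene_names) != nrow(values) || length(cell_names) != ncol(values))
    stop_structural("matrix dimensions do not match gene/cell name lengths")
  if (anyDuplicated(gene_names))
    stop_structural(sprintf("duplicated gene names: %s",
      paste(unique(gene_names[duplicated(gene_names)]), collapse = ", ")))
  if (anyDuplicated(cell_names))
    stop_structural("duplicated cell names")
  if (!all(is.finite(values)))
    stop_structural("expression values must all be finite")
  pseudotime_rank <- as.integer(pseudotime_rank)
  if (length(pseudotime_rank) != ncol(values) ||
      !identical(sort(pseudotime_rank), seq_len(ncol(values))))
    stop_structural("pseudotime_rank must be a permutation of cell indices")
  dimnames(values) <- list(gene_names, cell_names)
  structure(list(values = values, gene_names = gene_names,
                 cell_names = cell_names, pseudotime_rank = pseudotime_rank),
            class = "expression_trajectory")
}

#' @export
print.expression_trajectory <- function(x, ...) {
  cat(sprintf("<expression_trajectory> %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  ident <- identical(x$pseudotime_rank, seq_len(ncol(x$values)))
  cat(sprintf("  pseudotime order: %s\n",
              if (ident) "column order" else "explicit rank"))
  invisible(x)
}

#' @export
dim.expression_trajectory <- function(x) dim(x$values)

# values with columns permuted into trajectory order
trajectory_ordered_values <- function(traj) {
  traj$values[, traj$pseudotime_rank, drop = FALSE]
}

#' Read an expression matrix
#'
#' Two on-disk layouts are supported: a dense TSV with genes as rows (first
#' column gene id, header row of cell names) and MatrixMarket, where `path`
#' names the `.mtx` file and sibling files `genes.tsv` / `cells.tsv` in the
#' same directory carry the row and column names (1-based indices per the
#' MTX standard; rows are genes).
#'
#' @param path file path (`.tsv` or `.mtx`).
#' @param format `"dense-tsv"` or `"matrix-market"`.
#' @return an [expression_trajectory()] with cells in file order and an
#'   identity pseudotime rank.
#' @export
read_expression <- function(path, format = c("dense-tsv", "matrix-market")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  if (format == "dense-tsv") {
    tab <- tryCatch(
      utils::read.delim(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE),
      error = function(e) stop_parse(sprintf("cannot parse %s: %s", path,
                                             conditionMessage(e))))
    if (ncol(tab) < 2L) stop_parse(sprintf("%s: expected gene column plus at least one cell column", path))
    genes <- as.character(tab[[1L]])
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(mat)) {
      bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))[1L]
      stop_parse(sprintf("%s: non-numeric values in column '%s'",
                         path, colnames(tab)[-1L][bad]))
    }
    expression_trajectory(mat, gene_names = genes, cell_names = colnames(tab)[-1L])
  } else {
    m <- tryCatch(as.matrix(Matrix::readMM(path)),
                  error = function(e) stop_parse(sprintf("cannot parse %s: %s",
                                                         path, conditionMessage(e))))
    dir <- dirname(path)
    gf <- file.path(dir, "genes.tsv"); cf <- file.path(dir, "cells.tsv")
    if (!file.exists(gf) || !file.exists(cf))
      stop_parse(sprintf("matrix-market input needs %s and %s", gf, cf))
    genes <- readLines(gf); cells <- readLines(cf)
    genes <- genes[nzchar(genes)]; cells <- cells[nzchar(cells)]
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop_structural(sprintf(
        "matrix is %d x %d but %d gene and %d cell names were supplied",
        nrow(m), ncol(m), length(genes), length(cells)))
    expression_trajectory(m, gene_names = genes, cell_names = cells)
  }
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; the round trip is value-exact for the
#' dense TSV format (values are written with full precision) and for
#' MatrixMarket.
#'
#' @param traj an [expression_trajectory()].
#' @param path output path; for `"matrix-market"` the `.mtx` file (name files
#'   are written alongside).
#' @param format `"dense-tsv"` or `"matrix-market"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(traj, path, format = c("dense-tsv", "matrix-market")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "expression_trajectory"))
  if (format == "dense-tsv") {
    df <- data.frame(gene = traj$gene_names,
                     format(traj$values, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene", traj$cell_names)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(traj$values, sparse = TRUE), path)
    writeLines(traj$gene_names, file.path(dirname(path), "genes.tsv"))
    writeLines(traj$cell_names, file.path(dirname(path), "cells.tsv"))
  }
  invisible(path)
}
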