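#' Per-gene embedding table
#'
#' Fixed-length numeric prior-knowledge vectors, one per gene.  The package
#' treats these as opaque inputs: any upstream source (e.g. language-model
#' embeddings of gene descriptions) may produce them, and the synthetic
#' generator ([generate_embeddings()]) emulates their key property that
#' genes with shared regulatory context embed nearby.
#'
#' @param vectors numeric matrix, genes x dim; all entries finite.
#' @param gene_names unique gene identifiers (defaults to rownames).
#' @return object of class `embedding_table` with fields `vectors`,
#'   `gene_names`, `dim`.
#' @export
embedding_table <- function(vectors, gene_names = rownames(vectors)) {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (is.null(gene_names)) stop_structural("embedding table needs gene names")
  gene_names <- as.character(gene_names)
  if (length(gene_names) != nrow(vectors))
    stop_structural("gene name count does not match embedding rows")
  if (anyDuplicated(gene_names))
    stop_structural("duplicated gene names in embedding table")
  if (!all(is.finite(vectors)))
    stop_structural("embedding vectors must be finite")
  rownames(vectors) <- gene_names
  structure(list(vectors = vectors, gene_names = gene_names,
                 dim = ncol(vectors)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d genes, dim %d\n", nrow(x$vectors), x$dim))
  invisible(x)
}

#' Read an embedding table
#'
#' Headerless TSV: gene id in column 1 followed by a constant number of
#' numeric columns.  The embedding dimension is inferred from the column
#' count and must be identical on every row.
#'
#' @param path file path.
#' @return an [embedding_table()].
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_parse(sprintf("%s: empty embedding file", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop_structural(sprintf("%s: ragged rows (widths %s)", path,
                            paste(unique(widths), collapse = "/")))
  if (widths[1L] < 2L) stop_parse(sprintf("%s: need at least one numeric column", path))
  genes <- vapply(fields, `[[`, character(1), 1L)
  num <- suppressWarnings(
    t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(widths[1L] - 1L))))
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1L, any))[1L]
    stop_parse(sprintf("%s: non-numeric value on line %d", path, bad))
  }
  embedding_table(num, gene_names = genes)
}

#' Write an embedding table
#'
#' @param emb an [embedding_table()].
#' @param path output path (headerless TSV, gene id first).
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_table"))
  txt <- apply(emb$vectors, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(emb$gene_names, txt, sep = "\t"), path)
  invisible(path)
}
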