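# Shared fixture builders.  Heavy objects (default-scale benchmarks and
# their trained autoencoders) are cached per (seed, dropout) so the
# protocol-level tests can share them.

.fixture_cache <- new.env(parent = emptyenv())

# default-scale benchmark + temporal features, cached
bench_with_temporal <- function(seed, dropout_rate = 0.3) {
  key <- sprintf("b_%d_%g", seed, dropout_rate)
  if (is.null(.fixture_cache[[key]])) {
    bench <- make_benchmark(sim_config(seed = seed, dropout_rate = dropout_rate),
                            embedding_fixture_config(seed = seed))
    ae <- fit_autoencoder(bench$dataset$trajectory, tcn_config(seed = seed))
    .fixture_cache[[key]] <- list(
      dataset = bench$dataset, grn = bench$grn, autoencoder = ae,
      temporal = encode_trajectory(bench$dataset$trajectory, ae))
  }
  .fixture_cache[[key]]
}

# small quick benchmark for plumbing tests
small_benchmark <- function(seed = 1) {
  make_benchmark(sim_config(n_genes = 20, n_tfs = 3, n_cells = 40,
                            edge_prob = 0.3, seed = seed),
                 embedding_fixture_config(dim = 8, seed = seed))
}

quick_tcn <- function(seed = 1, epochs = 3) {
  tcn_config(n_blocks = 2, channel_schedule = c(4, 4), epochs = epochs,
             seed = seed)
}

quick_predictor <- function(seed = 1, epochs = 20) {
  predictor_config(hidden_dim = 16, n_heads = 2, ff_dim = 16,
                   epochs = epochs, seed = seed)
}

# toy expression trajectory with named genes/cells
toy_trajectory <- function(n_genes = 4, n_cells = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_genes * n_cells, 0, 5), n_genes, n_cells,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("c", seq_len(n_cells))))
  expression_trajectory(m)
}

# hand-built planted network (two targets sharing identical regulation)
toy_grn <- function() {
  genes <- c("T1", "T2", "A", "B", "C")
  structure(list(genes = genes, tfs = c("T1", "T2"),
                 edges = data.frame(
                   tf = c("T1", "T1", "T2"),
                   target = c("A", "B", "C"),
                   sign = c(1, 1, -1),
                   weight = c(1.2, 1.2, -0.8),
                   stringsAsFactors = FALSE),
                 seed = 1L),
            class = "planted_grn")
}

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)
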