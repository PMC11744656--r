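#' Simulation configuration for the synthetic benchmark
#'
#' Defines the planted network and the trajectory dynamics.  Defaults give
#' the package's standard desk-scale benchmark: 50 genes, 5 transcription
#' factors, 200 pseudotime-ordered cells, edge probability 0.15 and a 30\%
#' dropout rate -- small enough that a full protocol run takes minutes on
#' one CPU while leaving enough planted edges for stable metrics.
#'
#' @param n_genes,n_tfs,n_cells problem sizes (`n_tfs <= n_genes`).
#' @param edge_prob probability that any given (TF, target) pair is a
#'   planted edge.
#' @param noise_sd additive per-step Gaussian noise in the dynamics.
#' @param dropout_rate probability in [0,1) that an observed entry is zeroed
#'   (scRNA-seq dropout).
#' @param decay first-order decay rate of expression.
#' @param step_size Euler step of the dynamics.
#' @param seed integer seed; all generators are bit-reproducible given it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50, n_tfs = 5, n_cells = 200,
                       edge_prob = 0.15, noise_sd = 0.05, dropout_rate = 0.3,
                       decay = 0.1, step_size = 0.3, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", 2L)
  n_tfs <- check_count(n_tfs, "n_tfs", 1L)
  if (n_tfs > n_genes) stop_config("n_tfs must not exceed n_genes")
  n_cells <- check_count(n_cells, "n_cells", 2L)
  edge_prob <- check_prob(edge_prob, "edge_prob")
  dropout_rate <- check_prob(dropout_rate, "dropout_rate", upper_open = TRUE)
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (!is.numeric(decay) || decay <= 0) stop_config("decay must be positive")
  if (!is.numeric(step_size) || step_size <= 0) stop_config("step_size must be positive")
  structure(list(n_genes = n_genes, n_tfs = n_tfs, n_cells = n_cells,
                 edge_prob = edge_prob, noise_sd = noise_sd,
                 dropout_rate = dropout_rate, decay = decay,
                 step_size = step_size, seed = as.integer(seed)),
            class = "sim_config")
}

#' Embedding-fixture configuration
#'
#' Controls the synthetic per-gene embedding vectors.  Each gene's signed
#' regulatory context (its adjacency row as a regulator concatenated with
#' its adjacency column as a target) is projected to `dim` coordinates with
#' a seeded random matrix, standardized per coordinate, and mixed with
#' Gaussian noise: `e = signal_fraction * signal + (1 - signal_fraction) *
#' noise`.  `signal_fraction` therefore interpolates between pure noise (0)
#' and embeddings that fully expose shared regulatory context (1),
#' emulating the presence/absence of informative prior-knowledge vectors.
#'
#' @param dim embedding dimension (default 64: large enough to preserve the
#'   pairwise geometry of the 2 x n_genes context vectors at benchmark
#'   scale).
#' @param signal_fraction mixing weight in [0, 1].
#' @param noise_sd standard deviation of the noise component.
#' @param seed integer seed.
#' @return object of class `embedding_fixture_config`.
#' @export
embedding_fixture_config <- function(dim = 64, signal_fraction = 0.8,
                                     noise_sd = 1, seed = 1L) {
  dim <- check_count(dim, "dim", 1L)
  signal_fraction <- check_prob(signal_fraction, "signal_fraction")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(list(dim = dim, signal_fraction = signal_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "embedding_fixture_config")
}

#' Plant a ground-truth regulatory network
#'
#' Genes are named `G001`, `G002`, ...; the first `n_tfs` genes are the
#' transcription factors.  Every directed (TF, target) pair with
#' `target != TF` is included independently with probability `edge_prob`;
#' signs are +/- with equal probability and magnitudes Uniform(0.5, 1.5).
#'
#' @param cfg a [sim_config()].
#' @return object of class `planted_grn`: `genes`, `tfs`, and an `edges`
#'   data.frame (`tf`, `target`, `sign`, `weight`).
#' @export
generate_grn <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  tfs <- genes[seq_len(cfg$n_tfs)]
  with_seed(cfg$seed, {
    src <- rep(tfs, each = cfg$n_genes)
    dst <- rep(genes, times = cfg$n_tfs)
    ok <- src != dst
    src <- src[ok]; dst <- dst[ok]
    draw <- stats::runif(length(src)) < cfg$edge_prob
    src <- src[draw]; dst <- dst[draw]
    if (length(src) == 0L)
      stop_structural("no edges drawn; increase edge_prob or network size")
    sign <- sample(c(-1, 1), length(src), replace = TRUE)
    weight <- sign * stats::runif(length(src), 0.5, 1.5)
    structure(list(genes = genes, tfs = tfs,
                   edges = data.frame(tf = src, target = dst, sign = sign,
                                      weight = weight,
                                      stringsAsFactors = FALSE),
                   seed = cfg$seed),
              class = "planted_grn")
  })
}

#' @export
print.planted_grn <- function(x, ...) {
  cat(sprintf("<planted_grn> %d genes, %d TFs, %d signed edges\n",
              length(x$genes), length(x$tfs), nrow(x$edges)))
  invisible(x)
}

# signed adjacency matrix (regulator rows, target columns)
grn_adjacency <- function(grn) {
  A <- matrix(0, length(grn$genes), length(grn$genes),
              dimnames = list(grn$genes, grn$genes))
  A[cbind(grn$edges$tf, grn$edges$target)] <- grn$edges$weight
  A
}

#' Simulate a pseudotime expression trajectory driven by a planted network
#'
#' Discrete-time dynamics with cells indexed by pseudotime t = 1..n_cells:
#' `x_g(t+1) = max(0, x_g(t) + step_size * (tanh(sum_r w_rg x_r(t)) -
#' decay * x_g(t)) + eps)` with `eps ~ N(0, noise_sd^2)` and initial state
#' Uniform(0, 1).  The tanh squashing keeps trajectories bounded.  After
#' simulation each entry is independently zeroed with probability
#' `dropout_rate` to emulate scRNA-seq dropout.
#'
#' @param grn a [generate_grn()] result.
#' @param cfg a [sim_config()] (its `seed` drives initial state, noise and
#'   dropout).
#' @return an [expression_trajectory()], cells in pseudotime order.
#' @export
simulate_trajectory <- function(grn, cfg = sim_config()) {
  stopifnot(inherits(grn, "planted_grn"), inherits(cfg, "sim_config"))
  A <- grn_adjacency(grn)
  G <- length(grn$genes); L <- cfg$n_cells
  with_seed(cfg$seed + 1L, {
    X <- matrix(0, G, L, dimnames = list(grn$genes, NULL))
    x <- stats::runif(G)
    X[, 1L] <- x
    for (t in seq_len(L - 1L)) {
      drive <- tanh(as.numeric(crossprod(A, x)))
      eps <- stats::rnorm(G, 0, cfg$noise_sd)
      x <- pmax(0, x + cfg$step_size * (drive - cfg$decay * x) + eps)
      if (!all(is.finite(x)))
        stop_training(sprintf("non-finite trajectory at step %d", t + 1L))
      X[, t + 1L] <- x
    }
    if (cfg$dropout_rate > 0) {
      keep <- matrix(stats::runif(G * L) >= cfg$dropout_rate, G, L)
      X <- X * keep
    }
    colnames(X) <- sprintf("cell%03d", seq_len(L))
    expression_trajectory(X)
  })
}

#' Generate structure-correlated embedding vectors
#'
#' Emulates prior-knowledge gene embeddings: each gene's context vector is
#' the magnitude of its adjacency row (as regulator) concatenated with the
#' magnitude of its adjacency column (as target); a seeded random
#' projection with unit-RMS coordinates maps contexts to `cfg$dim`
#' dimensions and the result is mixed with Gaussian noise:
#' `e_g = signal_fraction * (M u_g) + (1 - signal_fraction) * eta_g`,
#' so `signal_fraction` mixes the two components on a common scale.
#' Contexts use absolute interaction strengths, not signs, so that pairwise
#' embedding similarity tracks *shared regulatory context* the way
#' text-derived gene embeddings do -- a gene description reflects who
#' regulates a gene, while activation versus repression lives in the
#' simulated dynamics.  Genes with identical regulatory context receive
#' identical signal components; genes with empty context carry only the
#' noise term.
#'
#' @param grn a [generate_grn()] result.
#' @param cfg an [embedding_fixture_config()].
#' @return an [embedding_table()] over the network's genes.
#' @export
generate_embeddings <- function(grn, cfg = embedding_fixture_config()) {
  stopifnot(inherits(grn, "planted_grn"),
            inherits(cfg, "embedding_fixture_config"))
  A <- abs(grn_adjacency(grn))
  U <- cbind(A, t(A))                     # genes x 2G context
  with_seed(cfg$seed + 2L, {
    M <- matrix(stats::rnorm(ncol(U) * cfg$dim, 0, 1 / sqrt(ncol(U))),
                ncol(U), cfg$dim)
    S <- U %*% M
    # unit-RMS projection coordinates (no centering: empty-context genes
    # stay at the origin), so signal_fraction mixes signal and noise on a
    # common scale
    rms <- sqrt(colMeans(S^2))
    S <- sweep(S, 2L, ifelse(rms > 0, rms, 1), "/")
    N <- matrix(stats::rnorm(nrow(U) * cfg$dim, 0, cfg$noise_sd),
                nrow(U), cfg$dim)
    E <- cfg$signal_fraction * S + (1 - cfg$signal_fraction) * N
    embedding_table(E, gene_names = grn$genes)
  })
}

#' Bundle a complete synthetic benchmark
#'
#' Plants a network, simulates its trajectory, generates embeddings, and
#' assembles the positive edge set (planted edges, label 1, regulator
#' universe = the TFs), aligned and ready for any protocol.
#'
#' @param cfg a [sim_config()].
#' @param emb_cfg an [embedding_fixture_config()].
#' @return list with `dataset` (an `aligned_dataset`) and `grn` (the
#'   planted ground truth).
#' @export
make_benchmark <- function(cfg = sim_config(),
                           emb_cfg = embedding_fixture_config()) {
  grn <- generate_grn(cfg)
  traj <- simulate_trajectory(grn, cfg)
  emb <- generate_embeddings(grn, emb_cfg)
  pos <- edge_set(data.frame(regulator = grn$edges$tf,
                             target = grn$edges$target, label = 1L,
                             stringsAsFactors = FALSE),
                  regulator_universe = grn$tfs)
  list(dataset = align(traj, emb, pos), grn = grn)
}
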