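#' Link-predictor configuration
#'
#' Settings for the attention-fusion + Transformer edge classifier.  Genes
#' are unordered tokens, so no positional encoding is used; one encoder
#' block is applied (multi-head self-attention, residual + LayerNorm,
#' feed-forward, residual + LayerNorm).
#'
#' @param hidden_dim hidden width H (must be divisible by `n_heads`).
#' @param n_heads number of attention heads.
#' @param ff_dim feed-forward inner width.
#' @param dropout_p dropout probability (training only).
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param negative_ratio negatives sampled per positive edge.
#' @param batch_size edges per optimization step; gene features are
#'   re-encoded every step so all parameters receive gradients.
#' @param weight_decay decoupled (AdamW-style) L2 decay applied to weight
#'   matrices (never biases or layer-norm parameters).  Labeled edge sets at
#'   the scale this package targets are orders of magnitude smaller than the
#'   parameter count, so regularization carries real weight; the default is
#'   the conventional 1e-2.
#' @param standardize standardize each fused input feature column (zero
#'   mean, unit variance across genes) before the fusion layer; the
#'   transform is stored in the model and re-applied at prediction.
#'   Equalizes the scales of the embedding and temporal branches.
#' @param seed integer seed for initialization, dropout and shuffling.
#' @return object of class `predictor_config`.
#' @export
predictor_config <- function(hidden_dim = 128, n_heads = 4, ff_dim = 256,
                             dropout_p = 0.1, epochs = 100,
                             learning_rate = 1e-3, negative_ratio = 1,
                             batch_size = 64, weight_decay = 1e-2,
                             standardize = TRUE, seed = 1L) {
  hidden_dim <- check_count(hidden_dim, "hidden_dim", 1L)
  n_heads <- check_count(n_heads, "n_heads", 1L)
  if (hidden_dim %% n_heads != 0L)
    stop_config("hidden_dim must be divisible by n_heads")
  ff_dim <- check_count(ff_dim, "ff_dim", 1L)
  dropout_p <- check_prob(dropout_p, "dropout_p", upper_open = TRUE)
  epochs <- check_count(epochs, "epochs", 0L)
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_config("learning_rate must be positive")
  if (!is.numeric(negative_ratio) || negative_ratio <= 0)
    stop_config("negative_ratio must be positive")
  batch_size <- check_count(batch_size, "batch_size", 1L)
  if (!is.numeric(weight_decay) || weight_decay < 0)
    stop_config("weight_decay must be >= 0")
  structure(list(hidden_dim = hidden_dim, n_heads = n_heads, ff_dim = ff_dim,
                 dropout_p = dropout_p, epochs = epochs,
                 learning_rate = learning_rate,
                 negative_ratio = as.numeric(negative_ratio),
                 batch_size = batch_size,
                 weight_decay = as.numeric(weight_decay),
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "predictor_config")
}

# --- parameter constructors ----------------------------------------------

#' Initialize fusion-layer parameters
#' @param input_dim concatenated feature width (F + F').
#' @param hidden_dim hidden width H.
#' @return list with `att_score` (linear to 1) and `embed` (linear to H).
#' @export
fusion_params <- function(input_dim, hidden_dim) {
  list(att_score = init_linear(input_dim, 1L),
       embed = init_linear(input_dim, hidden_dim))
}

#' Initialize Transformer-encoder-block parameters
#' @param hidden_dim hidden width H.
#' @param ff_dim feed-forward inner width.
#' @return list of projection, layer-norm and feed-forward parameters.
#' @export
encoder_params <- function(hidden_dim, ff_dim) {
  list(q = init_linear(hidden_dim, hidden_dim),
       k = init_linear(hidden_dim, hidden_dim),
       v = init_linear(hidden_dim, hidden_dim),
       o = init_linear(hidden_dim, hidden_dim),
       ln1 = init_layernorm(hidden_dim),
       ff1 = init_linear(hidden_dim, ff_dim),
       ff2 = init_linear(ff_dim, hidden_dim),
       ln2 = init_layernorm(hidden_dim))
}

#' Initialize edge-decoder parameters
#' @param hidden_dim hidden width H (the decoder sees 2H).
#' @return list with a single linear layer `dec`.
#' @export
decoder_params <- function(hidden_dim) {
  list(dec = init_linear(2L * hidden_dim, 1L))
}

predictor_init <- function(input_dim, cfg) {
  c(fusion_params(input_dim, cfg$hidden_dim),
    encoder_params(cfg$hidden_dim, cfg$ff_dim),
    decoder_params(cfg$hidden_dim))
}

# --- fusion ---------------------------------------------------------------

fuse_fwd <- function(h0, p) {
  a <- linear_fwd(h0, p$att_score)
  alpha <- softmax_vec(a[, 1L])
  h0att <- h0 * alpha
  h1 <- linear_fwd(h0att, p$embed)
  list(alpha = alpha, h0att = h0att, h1 = h1)
}

fuse_bwd <- function(dh1, h0, fw, p) {
  be <- linear_bwd(dh1, fw$h0att, p$embed)
  dh0att <- be$dx
  dh0 <- dh0att * fw$alpha
  dalpha <- rowSums(dh0att * h0)
  da <- fw$alpha * (dalpha - sum(fw$alpha * dalpha))
  ba <- linear_bwd(matrix(da, ncol = 1L), h0, p$att_score)
  list(dh0 = dh0 + ba$dx,
       grads = list(att_score = list(W = ba$dW, b = ba$db),
                    embed = list(W = be$dW, b = be$db)))
}

#' Fuse embedding and temporal features with softmax attention
#'
#' Concatenates each gene's prior-knowledge embedding with its latent
#' temporal features, scores every gene with a linear layer, normalizes the
#' scores with a softmax over genes (so the weights sum to 1), rescales each
#' gene's concatenated features by its weight, and projects to the hidden
#' dimension.
#'
#' @param embeddings an [embedding_table()].
#' @param temporal a `latent_features` object from [encode_trajectory()].
#' @param params fusion parameters ([fusion_params()]); freshly initialized
#'   from `seed` when omitted.
#' @param hidden_dim hidden width used when `params` is omitted.
#' @param seed seed for default initialization.
#' @return list with `h0` (genes x (F+F')), `alpha` (attention weights,
#'   non-negative, summing to 1), `h0_att`, and `h1` (genes x H).
#' @export
fuse <- function(embeddings, temporal, params = NULL, hidden_dim = 128,
                 seed = 1L) {
  stopifnot(inherits(embeddings, "embedding_table"))
  if (!identical(embeddings$gene_names, temporal$gene_names))
    stop_usage("embedding and temporal feature gene orders differ")
  h0 <- cbind(embeddings$vectors, temporal$features)
  if (is.null(params))
    params <- with_seed(seed, fusion_params(ncol(h0), hidden_dim))
  fw <- fuse_fwd(h0, params)
  list(h0 = h0, alpha = fw$alpha, h0_att = fw$h0att, h1 = fw$h1)
}

# --- transformer encoder block -------------------------------------------

encoder_fwd <- function(h1, p, cfg, training) {
  H <- ncol(h1); nh <- cfg$n_heads; dk <- H %/% nh
  Q <- linear_fwd(h1, p$q); K <- linear_fwd(h1, p$k); V <- linear_fwd(h1, p$v)
  O <- matrix(0, nrow(h1), H)
  A_list <- vector("list", nh)
  for (h in seq_len(nh)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk)
    A <- softmax_rows(S)
    A_list[[h]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  h2 <- linear_fwd(O, p$o)
  m2 <- dropout_mask(dim(h2), cfg$dropout_p, training)
  r1 <- h1 + apply_mask(h2, m2)
  l1 <- layernorm_fwd(r1, p$ln1)
  h3 <- l1$out
  f1pre <- linear_fwd(h3, p$ff1)
  f1 <- relu(f1pre)
  h4 <- linear_fwd(f1, p$ff2)
  m4 <- dropout_mask(dim(h4), cfg$dropout_p, training)
  r2 <- h3 + apply_mask(h4, m4)
  l2 <- layernorm_fwd(r2, p$ln2)
  list(h5 = l2$out,
       cache = list(h1 = h1, Q = Q, K = K, V = V, O = O, A = A_list,
                    m2 = m2, l1 = l1$cache, h3 = h3, f1pre = f1pre, f1 = f1,
                    m4 = m4, l2 = l2$cache, attn = A_list))
}

encoder_bwd <- function(dh5, cache, p, cfg) {
  H <- ncol(dh5); nh <- cfg$n_heads; dk <- H %/% nh
  l2 <- layernorm_bwd(dh5, cache$l2, p$ln2)
  dh3 <- l2$dx
  dh4 <- apply_mask(l2$dx, cache$m4)
  bf2 <- linear_bwd(dh4, cache$f1, p$ff2)
  df1pre <- bf2$dx * (cache$f1pre > 0)
  bf1 <- linear_bwd(df1pre, cache$h3, p$ff1)
  dh3 <- dh3 + bf1$dx
  l1 <- layernorm_bwd(dh3, cache$l1, p$ln1)
  dh1 <- l1$dx
  dh2 <- apply_mask(l1$dx, cache$m2)
  bo <- linear_bwd(dh2, cache$O, p$o)
  dO <- bo$dx
  dQ <- matrix(0, nrow(dh5), H); dK <- dQ; dV <- dQ
  for (h in seq_len(nh)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(A * dA))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dk)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  bq <- linear_bwd(dQ, cache$h1, p$q)
  bk <- linear_bwd(dK, cache$h1, p$k)
  bv <- linear_bwd(dV, cache$h1, p$v)
  dh1 <- dh1 + bq$dx + bk$dx + bv$dx
  list(dh1 = dh1,
       grads = list(q = list(W = bq$dW, b = bq$db),
                    k = list(W = bk$dW, b = bk$db),
                    v = list(W = bv$dW, b = bv$db),
                    o = list(W = bo$dW, b = bo$db),
                    ln1 = list(g = l1$dg, b = l1$db),
                    ff1 = list(W = bf1$dW, b = bf1$db),
                    ff2 = list(W = bf2$dW, b = bf2$db),
                    ln2 = list(g = l2$dg, b = l2$db)))
}

#' Transformer encoding of fused gene features
#'
#' One encoder block exactly as the model defines it: multi-head
#' self-attention with the fused features as query, key and value, then
#' residual + dropout + LayerNorm, a ReLU feed-forward network, and a second
#' residual + dropout + LayerNorm.  Without positional encodings the block
#' is permutation-equivariant over genes.
#'
#' @param h1 genes x H matrix of fused features.
#' @param params block parameters ([encoder_params()]); freshly initialized
#'   from `seed` when omitted.
#' @param cfg a [predictor_config()] (supplies `n_heads`, `ff_dim`,
#'   `dropout_p`).
#' @param mode `"eval"` (deterministic) or `"train"`.
#' @param seed seed for default initialization.
#' @return list with `h5` (genes x H encoded features) and `attn` (per-head
#'   attention matrices).
#' @export
encode_genes <- function(h1, params = NULL, cfg = predictor_config(),
                         mode = c("eval", "train"), seed = 1L) {
  mode <- match.arg(mode)
  h1 <- as.matrix(h1)
  if (ncol(h1) %% cfg$n_heads != 0L)
    stop_config("hidden width must be divisible by n_heads")
  if (is.null(params))
    params <- with_seed(seed, encoder_params(ncol(h1), cfg$ff_dim))
  fw <- encoder_fwd(h1, params, cfg, training = mode == "train")
  list(h5 = fw$h5, attn = fw$cache$attn)
}

# --- edge decoder ---------------------------------------------------------

edge_logits <- function(h5, src, dst, p) {
  Zcat <- cbind(h5[src, , drop = FALSE], h5[dst, , drop = FALSE])
  list(logits = as.numeric(linear_fwd(Zcat, p$dec)), Zcat = Zcat)
}

edge_bwd <- function(dlogit, Zcat, src, dst, p, n_genes) {
  H <- ncol(Zcat) %/% 2L
  dZcat <- outer(dlogit, p$dec$W[, 1L])
  dWf <- crossprod(Zcat, dlogit)
  dh5 <- matrix(0, n_genes, H)
  acc <- rowsum(rbind(dZcat[, seq_len(H), drop = FALSE],
                      dZcat[, H + seq_len(H), drop = FALSE]),
                group = c(src, dst))
  dh5[as.integer(rownames(acc)), ] <- acc
  list(dh5 = dh5, grads = list(dec = list(W = dWf, b = sum(dlogit))))
}

#' Score candidate regulator-target pairs
#'
#' The logit of a directed pair (i, j) is an affine function of the
#' concatenation of the encoded features of the regulator i and the target
#' j, in that order; a sigmoid maps it to a probability.  Ordered
#' concatenation makes the score direction-sensitive.
#'
#' @param h5 genes x H matrix of encoded gene features, rows named by gene.
#' @param pairs data.frame with columns `regulator` and `target`.
#' @param params decoder parameters ([decoder_params()]); freshly
#'   initialized from `seed` when omitted.
#' @param seed seed for default initialization.
#' @return data.frame `regulator`, `target`, `score` with scores in [0, 1].
#' @export
score_edges <- function(h5, pairs, params = NULL, seed = 1L) {
  h5 <- as.matrix(h5)
  genes <- rownames(h5)
  if (is.null(genes)) stop_usage("h5 must have gene row names")
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(c(pairs$regulator, pairs$target)), genes)
  if (length(unknown))
    stop_usage(sprintf("unknown gene(s) in pairs: %s",
                       paste(unknown, collapse = ", ")))
  if (is.null(params))
    params <- with_seed(seed, decoder_params(ncol(h5)))
  src <- match(pairs$regulator, genes)
  dst <- match(pairs$target, genes)
  lg <- edge_logits(h5, src, dst, params)
  data.frame(regulator = pairs$regulator, target = pairs$target,
             score = sigmoid(lg$logits), stringsAsFactors = FALSE)
}

#' Binary cross-entropy of predicted edge probabilities
#'
#' Scores are clipped to `(eps, 1 - eps)` before the logarithms so the loss
#' is finite for any score vector.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 labels of the same length.
#' @param eps clipping constant.
#' @return mean negative log-likelihood (non-negative scalar).
#' @export
bce_loss <- function(scores, labels, eps = 1e-7) {
  if (length(scores) == 0L) stop_usage("bce_loss: empty input")
  if (length(scores) != length(labels))
    stop_usage("bce_loss: scores and labels differ in length")
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(s) + (1 - labels) * log(1 - s))
}

# --- full forward / backward over genes + edges --------------------------

predictor_fwd <- function(h0, src, dst, params, cfg, training) {
  fu <- fuse_fwd(h0, params)
  en <- encoder_fwd(fu$h1, params, cfg, training)
  lg <- edge_logits(en$h5, src, dst, params)
  list(scores = sigmoid(lg$logits), fu = fu, en = en, lg = lg)
}

predictor_bwd <- function(fw, h0, src, dst, labels, params, cfg) {
  M <- length(labels)
  dlogit <- (fw$scores - labels) / M
  eb <- edge_bwd(dlogit, fw$lg$Zcat, src, dst, params, nrow(h0))
  enb <- encoder_bwd(eb$dh5, fw$en$cache, params, cfg)
  fub <- fuse_bwd(enb$dh1, h0, fw$fu, params)
  c(fub$grads, enb$grads, eb$grads)
}

#' Train the Transformer link predictor
#'
#' End-to-end optimization of the fusion, encoder and decoder parameters
#' against [bce_loss()] on labeled edges, with Adam.  The temporal features
#' are taken as fixed inputs (the autoencoder is trained separately and
#' frozen).  Mini-batches are drawn over edges; the gene features are
#' re-encoded at every step so all parameters receive gradients.
#' Deterministic given `cfg$seed`.
#'
#' @param embeddings an [embedding_table()].
#' @param temporal `latent_features` from [encode_trajectory()], same gene
#'   order.
#' @param train_edges an [edge_set()] containing both labels (run
#'   [sample_negatives()] first if you only have positives).
#' @param cfg a [predictor_config()].
#' @return object of class `grn_predictor`: parameters, config, the gene
#'   universe with its fused input features, and the per-epoch loss curve.
#' @export
train_predictor <- function(embeddings, temporal, train_edges,
                            cfg = predictor_config()) {
  stopifnot(inherits(embeddings, "embedding_table"),
            inherits(train_edges, "edge_set"),
            inherits(cfg, "predictor_config"))
  if (!identical(embeddings$gene_names, temporal$gene_names))
    stop_usage("embedding and temporal feature gene orders differ")
  genes <- embeddings$gene_names
  ed <- train_edges$edges
  if (length(unique(ed$label)) < 2L)
    stop_structural("training edges must contain both labels; sample negatives first")
  unknown <- setdiff(unique(c(ed$regulator, ed$target)), genes)
  if (length(unknown))
    stop_usage(sprintf("edge gene(s) missing from the dataset: %s",
                       paste(unknown, collapse = ", ")))
  h0 <- cbind(embeddings$vectors, temporal$features)
  scaling <- NULL
  if (cfg$standardize) {
    ctr <- colMeans(h0)
    scl <- apply(h0, 2L, stats::sd)
    scl[scl == 0] <- 1
    scaling <- list(center = ctr, scale = scl)
    h0 <- sweep(sweep(h0, 2L, ctr, "-"), 2L, scl, "/")
  }
  src <- match(ed$regulator, genes)
  dst <- match(ed$target, genes)
  y <- ed$label
  M <- length(y)
  with_seed(cfg$seed, {
    params <- predictor_init(ncol(h0), cfg)
    opt <- adam_init(params)
    losses <- numeric(0)
    if (cfg$epochs > 0L) {
      losses <- numeric(cfg$epochs)
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(M)
        starts <- seq(1L, M, by = cfg$batch_size)
        ep_loss <- 0
        for (s in starts) {
          b <- ord[s:min(s + cfg$batch_size - 1L, M)]
          fw <- predictor_fwd(h0, src[b], dst[b], params, cfg,
                              training = TRUE)
          loss <- bce_loss(fw$scores, y[b])
          if (!is.finite(loss))
            stop_training(sprintf("non-finite training loss at epoch %d", ep))
          ep_loss <- ep_loss + loss * length(b)
          g <- predictor_bwd(fw, h0, src[b], dst[b], y[b], params, cfg)
          st <- adam_step(params, g, opt, cfg$learning_rate,
                          weight_decay = cfg$weight_decay)
          params <- st$params
          opt <- st$state
        }
        losses[ep] <- ep_loss / M
      }
    }
    structure(list(params = params, cfg = cfg, gene_names = genes,
                   h0 = h0, scaling = scaling, loss = losses,
                   n_train_edges = M, trained = cfg$epochs > 0L),
              class = "grn_predictor")
  })
}

#' @export
print.grn_predictor <- function(x, ...) {
  cat(sprintf("<grn_predictor> %d genes, hidden dim %d, %d heads\n",
              length(x$gene_names), x$cfg$hidden_dim, x$cfg$n_heads))
  if (length(x$loss))
    cat(sprintf("  trained %d epochs on %d edges; BCE %.4f -> %.4f\n",
                length(x$loss), x$n_train_edges, x$loss[1],
                x$loss[length(x$loss)]))
  invisible(x)
}

#' Score candidate edges with a trained predictor
#'
#' Runs the fusion/encoder/decoder stack in eval mode (deterministic, no
#' dropout).  Any gene in the model's universe may appear as a regulator,
#' including genes that never occurred as a source in the training edges --
#' the unseen-regulator use case.
#'
#' @param object a trained [train_predictor()] result.
#' @param pairs data.frame with columns `regulator`, `target`; or `NULL`
#'   with `all_pairs = TRUE`.
#' @param all_pairs if `TRUE`, score every regulator x gene pair (self-pairs
#'   excluded) for the regulators in `regulators`.
#' @param regulators source genes used for `all_pairs` scoring.
#' @param sort sort the result by descending score (default `TRUE`;
#'   `FALSE` keeps input pair order).
#' @param ... unused.
#' @return data.frame `regulator`, `target`, `score` (probabilities).
#' @export
predict.grn_predictor <- function(object, pairs = NULL, all_pairs = FALSE,
                                  regulators = NULL, sort = TRUE, ...) {
  genes <- object$gene_names
  if (all_pairs) {
    if (is.null(regulators)) stop_usage("all_pairs scoring needs 'regulators'")
    unknown <- setdiff(regulators, genes)
    if (length(unknown))
      stop_usage(sprintf("unknown regulator(s): %s",
                         paste(unknown, collapse = ", ")))
    pairs <- expand.grid(target = genes, regulator = regulators,
                         stringsAsFactors = FALSE)[, c("regulator", "target")]
    pairs <- pairs[pairs$regulator != pairs$target, , drop = FALSE]
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(c(pairs$regulator, pairs$target)), genes)
  if (length(unknown))
    stop_usage(sprintf("unknown gene(s) in pairs: %s",
                       paste(unknown, collapse = ", ")))
  src <- match(pairs$regulator, genes)
  dst <- match(pairs$target, genes)
  fw <- predictor_fwd(object$h0, src, dst, object$params, object$cfg,
                      training = FALSE)
  out <- data.frame(regulator = pairs$regulator, target = pairs$target,
                    score = fw$scores, stringsAsFactors = FALSE)
  if (sort) out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
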