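#' Temporal-convolutional autoencoder configuration
#'
#' Architecture and optimization settings for the trajectory autoencoder.
#' Each temporal block applies a dilated causal convolution (left padding of
#' `(kernel_size - 1) * dilation` so output length equals input length),
#' ReLU, dropout, a second such convolution stack, and a residual connection
#' (1x1 convolution when channel counts differ) followed by ReLU.  The
#' encoder stacks `n_blocks` blocks whose output channels follow
#' `channel_schedule` (the last entry is the latent dimension F'); the
#' decoder mirrors the block structure and ends in a 1x1 projection back to
#' one channel.
#'
#' @param n_blocks number of temporal blocks in the encoder.
#' @param channel_schedule integer vector of per-block output channels;
#'   its last entry is the latent dimension.
#' @param kernel_size convolution kernel width (>= 1).
#' @param dilation_schedule per-block dilation factors (default `2^(i-1)`).
#' @param dropout_p dropout probability inside blocks (training only).
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param seed integer seed controlling initialization and dropout.
#' @return object of class `tcn_config`.
#' @export
tcn_config <- function(n_blocks = 3, channel_schedule = c(16, 32, 32),
                       kernel_size = 3, dilation_schedule = 2^(seq_len(n_blocks) - 1),
                       dropout_p = 0.1, learning_rate = 1e-3, epochs = 200,
                       seed = 1L) {
  n_blocks <- check_count(n_blocks, "n_blocks", 1L)
  if (length(channel_schedule) != n_blocks)
    stop_config("channel_schedule length must equal n_blocks")
  channel_schedule <- vapply(channel_schedule, check_count, integer(1),
                             name = "channel_schedule", min = 1L)
  kernel_size <- check_count(kernel_size, "kernel_size", 1L)
  dilation_schedule <- vapply(dilation_schedule, check_count, integer(1),
                              name = "dilation_schedule", min = 1L)
  if (length(dilation_schedule) != n_blocks)
    stop_config("dilation_schedule length must equal n_blocks")
  dropout_p <- check_prob(dropout_p, "dropout_p", upper_open = TRUE)
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_config("learning_rate must be positive")
  epochs <- check_count(epochs, "epochs", 0L)
  structure(list(n_blocks = n_blocks, channel_schedule = channel_schedule,
                 kernel_size = kernel_size,
                 dilation_schedule = dilation_schedule,
                 dropout_p = dropout_p, latent_dim = channel_schedule[n_blocks],
                 learning_rate = learning_rate, epochs = epochs,
                 seed = as.integer(seed)),
            class = "tcn_config")
}

# --- temporal block -------------------------------------------------------

#' Initialize the parameters of one temporal block
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel_size kernel width.
#' @return list with conv1, conv2 and (when channel counts differ) a 1x1
#'   `down` convolution for the residual path.
#' @export
temporal_block_params <- function(in_channels, out_channels, kernel_size) {
  p <- list(conv1 = init_conv(in_channels, out_channels, kernel_size),
            conv2 = init_conv(out_channels, out_channels, kernel_size))
  if (in_channels != out_channels)
    p$down <- init_conv(in_channels, out_channels, 1L)
  p
}

tblock_fwd <- function(X, p, dilation, dropout_p, training) {
  c1 <- conv1d_fwd(X, p$conv1, dilation)
  pos1 <- c1$out > 0
  m1 <- dropout_mask(dim(c1$out), dropout_p, training)
  d1 <- apply_mask(c1$out * pos1, m1)
  c2 <- conv1d_fwd(d1, p$conv2, dilation)
  pos2 <- c2$out > 0
  m2 <- dropout_mask(dim(c2$out), dropout_p, training)
  d2 <- apply_mask(c2$out * pos2, m2)
  if (is.null(p$down)) {
    res <- X; rcache <- NULL
  } else {
    rc <- conv1d_fwd(X, p$down, 1L)
    res <- rc$out; rcache <- rc$cache
  }
  pre <- d2 + res
  pos_out <- pre > 0
  list(out = pre * pos_out,
       cache = list(c1 = c1$cache, pos1 = pos1, m1 = m1,
                    c2 = c2$cache, pos2 = pos2, m2 = m2,
                    rcache = rcache, pos_out = pos_out))
}

tblock_bwd <- function(dY, cache, p) {
  dpre <- dY * cache$pos_out
  dc2 <- apply_mask(dpre, cache$m2) * cache$pos2
  b2 <- conv1d_bwd(dc2, cache$c2, p$conv2)
  dc1 <- apply_mask(b2$dX, cache$m1) * cache$pos1
  b1 <- conv1d_bwd(dc1, cache$c1, p$conv1)
  dX <- b1$dX
  g <- list(conv1 = list(W = b1$dW, b = b1$db),
            conv2 = list(W = b2$dW, b = b2$db))
  if (is.null(p$down)) {
    dX <- dX + dpre
  } else {
    bd <- conv1d_bwd(dpre, cache$rcache, p$down)
    dX <- dX + bd$dX
    g$down <- list(W = bd$dW, b = bd$db)
  }
  list(dX = dX, grads = g)
}

#' Forward pass of a single temporal block
#'
#' Mainly a testing and inspection surface; [fit_autoencoder()] uses the
#' same code path internally.  The block is causal: output at position t
#' depends only on input positions `<= t`.
#'
#' @param x numeric matrix, channels x length.
#' @param params block parameters from [temporal_block_params()] (weights
#'   may be overwritten to probe specific configurations).
#' @param dilation dilation factor (>= 1).
#' @param dropout_p dropout probability (active in `"train"` mode only).
#' @param mode `"eval"` (dropout is identity) or `"train"`.
#' @return channels x length matrix of the same length as the input.
#' @export
temporal_block_forward <- function(x, params, dilation = 1L, dropout_p = 0,
                                   mode = c("eval", "train")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop_usage("input length must be >= 1")
  dilation <- check_count(dilation, "dilation", 1L)
  if (dim(params$conv1$W)[3L] < 1L) stop_config("kernel_size must be >= 1")
  X <- array(0, c(nrow(x), 1L, ncol(x)))
  X[, 1L, ] <- x
  out <- tblock_fwd(X, params, dilation, dropout_p, mode == "train")$out
  matrix(out[, 1L, ], dim(out)[1L], dim(out)[3L])
}

# --- encoder / decoder stacks --------------------------------------------

tcn_init_params <- function(cfg) {
  ch_in <- c(1L, cfg$channel_schedule[-cfg$n_blocks])
  enc <- mapply(temporal_block_params, ch_in, cfg$channel_schedule,
                MoreArgs = list(kernel_size = cfg$kernel_size),
                SIMPLIFY = FALSE)
  rev_ch <- rev(cfg$channel_schedule)
  dec <- list()
  if (cfg$n_blocks > 1L) {
    dec_in <- rev_ch[-length(rev_ch)]
    dec_out <- rev_ch[-1L]
    dec <- mapply(temporal_block_params, dec_in, dec_out,
                  MoreArgs = list(kernel_size = cfg$kernel_size),
                  SIMPLIFY = FALSE)
  }
  proj_in <- if (cfg$n_blocks > 1L) rev_ch[length(rev_ch)] else cfg$latent_dim
  list(enc = enc, dec = dec, proj = init_conv(proj_in, 1L, 1L))
}

tcn_encoder_fwd <- function(X, params, cfg, training) {
  caches <- vector("list", cfg$n_blocks)
  H <- X
  for (i in seq_len(cfg$n_blocks)) {
    r <- tblock_fwd(H, params$enc[[i]], cfg$dilation_schedule[i],
                    cfg$dropout_p, training)
    H <- r$out
    caches[[i]] <- r$cache
  }
  list(Z = H, caches = caches)
}

tcn_decoder_fwd <- function(Z, params, cfg, training) {
  caches <- vector("list", length(params$dec))
  H <- Z
  dil <- rev(cfg$dilation_schedule)
  for (i in seq_along(params$dec)) {
    r <- tblock_fwd(H, params$dec[[i]], dil[i], cfg$dropout_p, training)
    H <- r$out
    caches[[i]] <- r$cache
  }
  pr <- conv1d_fwd(H, params$proj, 1L)
  list(Xhat = pr$out, caches = caches, proj_cache = pr$cache)
}

tcn_fwd <- function(X, params, cfg, training) {
  enc <- tcn_encoder_fwd(X, params, cfg, training)
  dec <- tcn_decoder_fwd(enc$Z, params, cfg, training)
  list(Z = enc$Z, Xhat = dec$Xhat, enc = enc, dec = dec)
}

tcn_bwd <- function(dXhat, fw, params, cfg) {
  g <- list(enc = vector("list", cfg$n_blocks),
            dec = vector("list", length(params$dec)))
  bp <- conv1d_bwd(dXhat, fw$dec$proj_cache, params$proj)
  g$proj <- list(W = bp$dW, b = bp$db)
  dH <- bp$dX
  for (i in rev(seq_along(params$dec))) {
    r <- tblock_bwd(dH, fw$dec$caches[[i]], params$dec[[i]])
    g$dec[[i]] <- r$grads
    dH <- r$dX
  }
  for (i in rev(seq_len(cfg$n_blocks))) {
    r <- tblock_bwd(dH, fw$enc$caches[[i]], params$enc[[i]])
    g$enc[[i]] <- r$grads
    dH <- r$dX
  }
  g
}

# --- loss -----------------------------------------------------------------

#' Reconstruction loss of the autoencoder
#'
#' Sum of squared reconstruction errors over all entries divided by the
#' number of genes (rows) only -- not by genes x cells.  This is the exact
#' normalization the model defines, and the training objective uses it as
#' printed.
#'
#' @param X,X_hat numeric matrices of identical shape (genes x cells).
#' @return a non-negative scalar.
#' @export
mse_loss <- function(X, X_hat) {
  if (!identical(dim(X), dim(X_hat)))
    stop_usage("mse_loss: shape mismatch between input and reconstruction")
  sum((X - X_hat)^2) / nrow(X)
}

# --- training -------------------------------------------------------------

#' Fit the temporal-convolutional autoencoder
#'
#' Trains the encoder/decoder on the pseudotime-ordered expression matrix,
#' treating each gene as an independent single-channel sequence (genes form
#' the batch).  Full-batch Adam minimizes [mse_loss()].  Given the same
#' config (including its seed) the run is bit-reproducible.
#'
#' @param trajectory an [expression_trajectory()].
#' @param cfg a [tcn_config()].
#' @return object of class `tcn_autoencoder` with fields `params`, `cfg`,
#'   `loss` (per-epoch training loss) and `trained`.
#' @export
fit_autoencoder <- function(trajectory, cfg = tcn_config()) {
  stopifnot(inherits(trajectory, "expression_trajectory"),
            inherits(cfg, "tcn_config"))
  Xmat <- trajectory_ordered_values(trajectory)
  C <- nrow(Xmat); L <- ncol(Xmat)
  if (C == 0L || L == 0L) stop_structural("empty trajectory")
  X <- array(0, c(1L, C, L))  # [channel, gene batch, pseudotime]
  X[1L, , ] <- Xmat
  with_seed(cfg$seed, {
    params <- tcn_init_params(cfg)
    opt <- adam_init(params)
    losses <- numeric(0)
    if (cfg$epochs > 0L) {
      losses <- numeric(cfg$epochs)
      for (ep in seq_len(cfg$epochs)) {
        fw <- tcn_fwd(X, params, cfg, training = TRUE)
        err <- fw$Xhat - X
        loss <- sum(err^2) / C
        if (!is.finite(loss))
          stop_training(sprintf("non-finite training loss at epoch %d", ep))
        losses[ep] <- loss
        st <- adam_step(params, tcn_bwd(2 * err / C, fw, params, cfg),
                        opt, cfg$learning_rate)
        params <- st$params
        opt <- st$state
      }
    }
    structure(list(params = params, cfg = cfg, loss = losses,
                   trained = cfg$epochs > 0L),
              class = "tcn_autoencoder")
  })
}

#' @export
print.tcn_autoencoder <- function(x, ...) {
  cat(sprintf("<tcn_autoencoder> %d blocks, channels [%s], latent dim %d\n",
              x$cfg$n_blocks, paste(x$cfg$channel_schedule, collapse = ","),
              x$cfg$latent_dim))
  if (length(x$loss))
    cat(sprintf("  trained %d epochs; loss %.4g -> %.4g\n", length(x$loss),
                x$loss[1], x$loss[length(x$loss)]))
  else cat("  untrained (initialized only)\n")
  invisible(x)
}

#' Encode genes into latent temporal features
#'
#' Runs each gene's pseudotime profile through the trained encoder in eval
#' mode and mean-pools the latent sequence over the temporal axis, yielding
#' one F'-vector per gene.
#'
#' @param trajectory an [expression_trajectory()] (any length).
#' @param model a trained [fit_autoencoder()] result.
#' @return object of class `latent_features`: `gene_names` plus a genes x F'
#'   `features` matrix in trajectory gene order.
#' @export
encode_trajectory <- function(trajectory, model) {
  stopifnot(inherits(trajectory, "expression_trajectory"),
            inherits(model, "tcn_autoencoder"))
  if (!isTRUE(model$trained))
    stop_usage("autoencoder has not been trained; fit it before encoding")
  Xmat <- trajectory_ordered_values(trajectory)
  X <- array(0, c(1L, nrow(Xmat), ncol(Xmat)))
  X[1L, , ] <- Xmat
  Z <- tcn_encoder_fwd(X, model$params, model$cfg, training = FALSE)$Z
  feats <- t(rowMeans(Z, dims = 2L))  # genes x F'
  rownames(feats) <- trajectory$gene_names
  structure(list(gene_names = trajectory$gene_names, features = feats),
            class = "latent_features")
}

#' @export
print.latent_features <- function(x, ...) {
  cat(sprintf("<latent_features> %d genes x %d dims\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Reconstruct an expression matrix through the autoencoder
#'
#' @param trajectory an [expression_trajectory()].
#' @param model a trained [fit_autoencoder()] result.
#' @return numeric matrix with the same shape and dimnames as
#'   `trajectory$values` (columns returned in storage order).
#' @export
reconstruct <- function(trajectory, model) {
  stopifnot(inherits(trajectory, "expression_trajectory"),
            inherits(model, "tcn_autoencoder"))
  if (!isTRUE(model$trained))
    stop_usage("autoencoder has not been trained; fit it before reconstructing")
  Xmat <- trajectory_ordered_values(trajectory)
  X <- array(0, c(1L, nrow(Xmat), ncol(Xmat)))
  X[1L, , ] <- Xmat
  fw <- tcn_fwd(X, model$params, model$cfg, training = FALSE)
  R <- matrix(fw$Xhat[1L, , ], nrow(Xmat), ncol(Xmat))
  # un-permute columns back to storage order
  out <- R
  out[, trajectory$pseudotime_rank] <- R
  dimnames(out) <- dimnames(trajectory$values)
  out
}
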