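# Minimal neural-network primitives: forward passes, hand-derived backward
# passes, and an Adam optimizer operating on nested parameter lists.  All
# randomness (initialization, dropout masks, batch shuffles) comes from the
# R RNG so training is bit-reproducible under a seed.

# --- initialization -------------------------------------------------------

# fan-in-scaled uniform init, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_linear <- function(fan_in, fan_out) {
  b <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out),
       b = stats::runif(fan_out, -b, b))
}

# conv kernel [out_ch, in_ch, k]
init_conv <- function(in_ch, out_ch, k) {
  b <- 1 / sqrt(in_ch * k)
  list(W = array(stats::runif(out_ch * in_ch * k, -b, b), c(out_ch, in_ch, k)),
       b = stats::runif(out_ch, -b, b))
}

init_layernorm <- function(d) list(g = rep(1, d), b = rep(0, d))

# --- elementwise pieces ---------------------------------------------------

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# inverted dropout; returns the mask so backward can reuse it
dropout_mask <- function(dim_, p, training) {
  if (!training || p <= 0) return(NULL)
  m <- (stats::runif(prod(dim_)) >= p) / (1 - p)
  dim(m) <- dim_
  m
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# column-vector softmax (over rows of a one-column matrix / a vector)
softmax_vec <- function(a) {
  e <- exp(a - max(a))
  e / sum(e)
}

# row-wise softmax of a matrix
softmax_rows <- function(S) {
  e <- exp(S - apply(S, 1L, max))
  e / rowSums(e)
}

# --- dense layer ----------------------------------------------------------

linear_fwd <- function(x, p) sweep(x %*% p$W, 2L, p$b, "+")

linear_bwd <- function(dy, x, p) {
  list(dx = dy %*% t(p$W),
       dW = crossprod(x, dy),
       db = colSums(dy))
}

# --- layer norm (per row over the feature axis) ---------------------------

layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / s
  list(out = sweep(xhat * rep(p$g, each = nrow(x)), 2L, p$b, "+"),
       cache = list(xhat = xhat, s = s))
}

layernorm_bwd <- function(dy, cache, p) {
  xhat <- cache$xhat; s <- cache$s
  dxhat <- dy * rep(p$g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / s
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# --- causal dilated 1-D convolution --------------------------------------
# X: [channels, batch, L] (channels-first so tap slices reshape to matrices
# without copies).  Left zero-padding of (k-1)*dilation followed by a
# full-length convolution is algebraically identical to symmetric padding
# plus chomp; output length always equals input length.

conv1d_fwd <- function(X, p, dilation) {
  list(out = conv1d_fwd_cpp(X, p$W, p$b, dilation),
       cache = list(X = X, dilation = dilation))
}

conv1d_bwd <- function(dY, cache, p) {
  conv1d_bwd_cpp(dY, cache$X, p$W, cache$dilation)
}

# --- Adam over nested parameter lists ------------------------------------

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# Adam with optional decoupled weight decay (AdamW); decay is applied to
# weight matrices only -- names 'W' -- never to biases or layer-norm params.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v, decay) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + decay * p)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- if (is.list(p[[nm]])) walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
             else upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]],
                      if (nm == "W") weight_decay else 0)
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else upd(p, g, m, v, 0)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# elementwise sum of two grad trees with identical shape
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grad_add(a[[nm]], b[[nm]])
    a
  } else a + b
}
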