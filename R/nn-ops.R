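# Minimal CNN engine used by the segmentation backbone and the alignment
# model. Tensors are numeric arrays with dim c(H, W, B, C); the matrix view
# matrix(x, H*W*B, C) is column-major-contiguous, which makes per-channel
# batch statistics cheap. Patch extraction and its adjoint live in
# src/conv.cpp; the matrix products go through BLAS.

out_size <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# Shared-kernel convolution. w: array (kh, kw, Cin, Cout); b: length Cout.
conv_fw <- function(x, w, b, stride = 1L, pad = 1L) {
  d <- dim(x); k <- dim(w)
  stopifnot(d[4] == k[3])
  P <- cpp_im2col(x, d[1], d[2], d[3], d[4], k[1], k[2], stride, pad)
  wm <- w; dim(wm) <- c(k[1] * k[2] * k[3], k[4])
  y <- P %*% wm
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(out_size(d[1], k[1], stride, pad),
              out_size(d[2], k[2], stride, pad), d[3], k[4])
  list(out = y, P = P, indim = d, kdim = k, stride = stride, pad = pad)
}

# Backward pass: returns dX (scatter-add adjoint of patch extraction),
# dW and db. `w` must be the kernel used in the forward pass.
conv_bw_full <- function(dy, cache, w, need_dx = TRUE, need_dw = TRUE) {
  k <- cache$kdim; d <- cache$indim
  n <- nrow(cache$P)
  dym <- dy; dim(dym) <- c(n, k[4])
  dW <- NULL; db <- NULL
  if (need_dw) {
    dW <- crossprod(cache$P, dym)
    dim(dW) <- k
    db <- colSums(dym)
  }
  dx <- NULL
  if (need_dx) {
    wm <- w; dim(wm) <- c(k[1] * k[2] * k[3], k[4])
    dP <- tcrossprod(dym, wm)                   # (n, taps*Cin)
    dx <- cpp_col2im(dP, d[1], d[2], d[3], d[4], k[1], k[2],
                     cache$stride, cache$pad)
  }
  list(dx = dx, dW = dW, db = db)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lrelu_fw <- function(x, slope = 0.01) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(out = x, neg = neg)
}

lrelu_bw <- function(dy, cache, slope = 0.01) {
  dy[cache$neg] <- dy[cache$neg] * slope
  dy
}

# Batch normalization over (H, W, B) per channel. Population (biased)
# variance throughout so batch moments and running moments are commensurate.
bn_fw <- function(x, gamma, beta, rmean, rvar, eps = 1e-5,
                  training = TRUE, momentum = 0.1, keep_xc = FALSE) {
  d <- dim(x); n <- d[1] * d[2] * d[3]
  xm <- x; dim(xm) <- c(n, d[4])
  mu_b <- colMeans(xm)
  var_b <- colMeans(xm * xm) - mu_b^2
  var_b[var_b < 0] <- 0
  xc_b <- if (keep_xc) xm - rep(mu_b, each = n) else NULL
  if (training) { mu <- mu_b; va <- var_b } else { mu <- rmean; va <- rvar }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = n)) * rep(invstd, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  dim(y) <- d
  new_rmean <- rmean; new_rvar <- rvar
  if (training) {
    new_rmean <- (1 - momentum) * rmean + momentum * mu_b
    new_rvar <- (1 - momentum) * rvar + momentum * var_b
  }
  list(out = y, xhat = xhat, invstd = invstd, gamma = gamma, d = d,
       training = training, batch_mean = mu_b, batch_var = var_b,
       xc_b = xc_b, rmean = new_rmean, rvar = new_rvar)
}

bn_bw <- function(dy, cache) {
  d <- cache$d; n <- d[1] * d[2] * d[3]
  dym <- dy; dim(dym) <- c(n, d[4])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  if (cache$training) {
    m1 <- dbeta / n
    m2 <- dgamma / n
    dx <- (dym - rep(m1, each = n) - cache$xhat * rep(m2, each = n)) *
      rep(cache$gamma * cache$invstd, each = n)
  } else {
    dx <- dym * rep(cache$gamma * cache$invstd, each = n)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Global average pooling (H, W, B, C) -> (B, C).
gap_fw <- function(x) {
  d <- dim(x)
  y <- .colMeans(x, d[1] * d[2], d[3] * d[4])
  dim(y) <- c(d[3], d[4])
  list(out = y, d = d)
}

gap_bw <- function(dy, cache) {
  d <- cache$d
  dx <- array(rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
  dx
}

softmax_mat <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

kaiming_weight <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

# Global-norm gradient clipping: rescale the whole gradient so its L2 norm
# is at most `max_norm`. Keeps early ill-conditioned steps (e.g. an
# untrained demodulated synthesis branch on highly correlated inputs) from
# saturating Adam's second-moment state.
clip_global_norm <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm) {
    sc <- max_norm / total
    grads <- lapply(grads, function(g) g * sc)
  }
  grads
}

# ---- Adam over a named flat list of numeric arrays ----------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Coerce a stack of 2-D slices (H x W matrix, list of matrices, or
# H x W x N array) into the internal (H, W, N, 1) tensor.
as_image_stack <- function(x) {
  if (is.list(x)) {
    stopifnot(length(x) >= 1)
    d <- dim(x[[1]])
    x <- array(unlist(x, use.names = FALSE), c(d[1], d[2], length(x)))
  }
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3)
  dim(x) <- c(dim(x), 1L)
  x
}
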