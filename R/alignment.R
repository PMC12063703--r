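# Input-specific visual prompt generation: a double-branch alignment model.
# The encoder branch compresses an image into a latent prompt code; the
# synthesis branch turns the image into an image-shaped additive prompt
# through a stack of prompt blocks whose convolutions are modulated by the
# code (per-input-channel additive weight offsets) and then demodulated
# (per-output-channel rescaling back to unit variance).

#' Build an alignment model (input-specific prompt generator)
#'
#' The synthesis branch has `blocks` prompt blocks of two 3x3
#' modulated-demodulated convolutions each (no up/downsampling, so the
#' prompt always matches the input shape); hidden widths default to 16,
#' first layer maps 1 -> width, last maps width -> 1 and has no
#' nonlinearity so the additive prompt can be signed. The encoder branch is
#' four stride-2 3x3 convolutions with leaky-ReLU, global average pooling,
#' and a linear map to the prompt code (dimension `code_dim`, 1024 by
#' default). Each modulated convolution has its own linear style map from
#' the code to its input-channel dimension. Weights are Kaiming-He normal,
#' biases zero; construction is deterministic given `seed`.
#'
#' @param code_dim Prompt-code dimension `D`.
#' @param blocks Number of prompt blocks `n` (the synthesis branch then has
#'   `2n` conv layers).
#' @param width Hidden channel width of the synthesis branch.
#' @param eps Demodulation stabilizer added under the square root.
#' @param mode `"specific"` (modulated-demodulated, the default) or
#'   `"plain"` (the ablation: ordinary convolutions, no code guidance).
#' @param enc_widths Channel widths of the four encoder stages.
#' @param seed Integer seed.
#' @return An object of class `vps_am`.
#'
#' @details The full prompt decomposes as `delta(x) = a*x + b + S(x)`: a
#' trainable global affine component (initialized at zero; optionally
#' warm-started by a coarse search, see [train_alignment()]) plus the
#' convolutional synthesis branch `S`. The affine part captures the bulk
#' orientation of a modality shift (e.g. contrast inversion), which a
#' purely convolutional branch can represent but reaches only through a
#' badly conditioned optimization; the synthesis branch then refines the
#' prompt per image. Both parts are input-specific and both are trained
#' by the same batch-statistics loss.
#' @export
build_alignment_model <- function(code_dim = 1024L, blocks = 5L, width = 16L,
                                  eps = 1e-8, mode = c("specific", "plain"),
                                  enc_widths = c(16L, 16L, 16L, 16L),
                                  seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(blocks >= 1L, code_dim >= 1L, width >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nlay <- 2L * as.integer(blocks)
  cins <- c(1L, rep(width, nlay - 1L))
  couts <- c(rep(width, nlay - 1L), 1L)
  syn <- vector("list", nlay)
  for (i in seq_len(nlay)) {
    syn[[i]] <- list(
      theta = kaiming_weight(3L, 3L, cins[i], couts[i]),
      b = numeric(couts[i]),
      # style maps start small so the modulated kernel is dominated by its
      # Kaiming base at init; large initial styles make the kernels nearly
      # rank-1 (coherent smoothing filters), which destabilizes early
      # optimization of the batch-statistics objective
      Ws = if (mode == "specific")
        matrix(stats::rnorm(code_dim * cins[i], sd = 0.1 / sqrt(code_dim)),
               code_dim, cins[i]) else NULL,
      bs = if (mode == "specific") numeric(cins[i]) else NULL,
      cin = cins[i], cout = couts[i]
    )
  }
  enc <- vector("list", length(enc_widths))
  cin <- 1L
  for (i in seq_along(enc_widths)) {
    enc[[i]] <- list(W = kaiming_weight(3L, 3L, cin, enc_widths[i]),
                     b = numeric(enc_widths[i]))
    cin <- enc_widths[i]
  }
  fc <- list(W = matrix(stats::rnorm(cin * code_dim, sd = sqrt(1 / cin)),
                        cin, code_dim),
             b = numeric(code_dim))
  structure(list(mode = mode, code_dim = as.integer(code_dim),
                 blocks = as.integer(blocks), width = as.integer(width),
                 eps = eps, enc = enc, fc = fc, syn = syn,
                 affine = c(a = 0, b = 0), seed = seed, log = NULL),
            class = "vps_am")
}

#' @export
print.vps_am <- function(x, ...) {
  cat("<vps_am> mode:", x$mode, "| prompt blocks:", x$blocks,
      "| code dim:", x$code_dim, "| width:", x$width, "\n")
  invisible(x)
}

am_params <- function(am) {
  out <- list()
  for (i in seq_along(am$enc)) {
    out[[paste0("enc", i, ".W")]] <- am$enc[[i]]$W
    out[[paste0("enc", i, ".b")]] <- am$enc[[i]]$b
  }
  out[["fc.W"]] <- am$fc$W
  out[["fc.b"]] <- am$fc$b
  out[["affine"]] <- am$affine
  for (i in seq_along(am$syn)) {
    out[[paste0("syn", i, ".theta")]] <- am$syn[[i]]$theta
    out[[paste0("syn", i, ".b")]] <- am$syn[[i]]$b
    if (am$mode == "specific") {
      out[[paste0("syn", i, ".Ws")]] <- am$syn[[i]]$Ws
      out[[paste0("syn", i, ".bs")]] <- am$syn[[i]]$bs
    }
  }
  out
}

set_am_params <- function(am, flat) {
  for (nm in names(flat)) {
    if (nm == "affine") { am$affine <- flat[[nm]]; next }
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    slot <- parts[1]; field <- parts[2]
    if (slot == "fc") {
      am$fc[[field]] <- flat[[nm]]
    } else if (startsWith(slot, "enc")) {
      am$enc[[as.integer(sub("enc", "", slot))]][[field]] <- flat[[nm]]
    } else {
      am$syn[[as.integer(sub("syn", "", slot))]][[field]] <- flat[[nm]]
    }
  }
  am
}

# ---- encoder branch ------------------------------------------------------

encoder_forward <- function(am, x, keep_cache = FALSE) {
  d <- dim(x)
  if (am$mode == "specific" && (d[1] < 16L || d[2] < 16L)) {
    stop("images must be at least 16x16 for the prompt-code encoder",
         call. = FALSE)
  }
  caches <- list()
  h <- x
  for (i in seq_along(am$enc)) {
    cc <- conv_fw(h, am$enc[[i]]$W, am$enc[[i]]$b, stride = 2L, pad = 1L)
    ac <- lrelu_fw(cc$out, 0.01)
    h <- ac$out
    if (keep_cache) {
      cc$out <- NULL
      caches[[i]] <- list(conv = cc, act = ac["neg"])
    }
  }
  gp <- gap_fw(h)                                  # (B, Cenc)
  code <- gp$out %*% am$fc$W + rep(am$fc$b, each = nrow(gp$out))
  list(code = code, caches = caches, gap = gp, pooled = gp$out)
}

encoder_backward <- function(am, enc_cache, dcode) {
  grads <- list()
  grads[["fc.W"]] <- crossprod(enc_cache$gap$out, dcode)
  grads[["fc.b"]] <- colSums(dcode)
  dpool <- tcrossprod(dcode, am$fc$W)              # (B, Cenc)
  g <- gap_bw(dpool, enc_cache$gap)
  for (i in rev(seq_along(am$enc))) {
    g <- lrelu_bw(g, enc_cache$caches[[i]]$act, 0.01)
    bb <- conv_bw_full(g, enc_cache$caches[[i]]$conv, am$enc[[i]]$W,
                       need_dx = i > 1L, need_dw = TRUE)
    grads[[paste0("enc", i, ".W")]] <- bb$dW
    grads[[paste0("enc", i, ".b")]] <- bb$db
    g <- bb$dx
  }
  grads
}

#' Encode an image into its prompt code
#'
#' Runs the encoder branch (strided convolutions, global average pooling,
#' linear map) and returns the latent code that steers prompt synthesis.
#'
#' @param am A `vps_am` built with `mode = "specific"`.
#' @param images Image stack (matrix, list of matrices, or `H x W x N`).
#' @return Numeric matrix `N x code_dim`.
#' @export
encode_prompt_code <- function(am, images) {
  stopifnot(inherits(am, "vps_am"))
  if (am$mode != "specific") {
    stop("prompt codes exist only in 'specific' mode", call. = FALSE)
  }
  x <- as_image_stack(images)
  encoder_forward(am, x)$code
}

# ---- modulated-demodulated convolution ----------------------------------

# Effective kernel for one sample: additive per-input-channel modulation
# theta_hat = theta + s_i, then per-output-channel demodulation by
# sqrt(sum_{i,k} theta_hat^2 + eps).
demod_kernel <- function(theta_flat, s, K, eps) {
  theta_hat <- theta_flat + rep(s, each = K)       # recycled over columns
  dj <- sqrt(colSums(theta_hat^2) + eps)
  list(theta_hat = theta_hat, dj = dj,
       w_eff = theta_hat * rep(1 / dj, each = nrow(theta_flat)))
}

#' Modulated-demodulated convolution (single feature map)
#'
#' Adds a per-input-channel style offset to the base kernel
#' (`theta_hat[i,j,k] = theta[i,j,k] + style[i]`), rescales each output
#' channel by `1 / sqrt(sum_{i,k} theta_hat^2 + eps)` so that i.i.d.
#' unit-variance inputs yield (approximately) unit-variance outputs, and
#' applies the resulting kernel as an ordinary padded stride-1 convolution.
#'
#' @param m Feature map: `H x W` matrix or `H x W x Cin` array.
#' @param theta Base kernel, array `kh x kw x Cin x Cout`.
#' @param style Numeric vector of per-input-channel offsets (length `Cin`).
#' @param eps Demodulation stabilizer.
#' @return Array `H x W x Cout` (same spatial size).
#' @export
modulated_demodulated_conv <- function(m, theta, style, eps = 1e-8) {
  if (length(dim(m)) == 2) dim(m) <- c(dim(m), 1L)
  k <- dim(theta)
  if (dim(m)[3] != k[3]) {
    stop("channel mismatch: feature map has ", dim(m)[3],
         " channels, kernel expects ", k[3], call. = FALSE)
  }
  if (length(style) != k[3]) {
    stop("style length must equal the kernel's input channels", call. = FALSE)
  }
  theta_flat <- theta; dim(theta_flat) <- c(k[1] * k[2] * k[3], k[4])
  dk <- demod_kernel(theta_flat, style, k[1] * k[2], eps)
  w <- dk$w_eff; dim(w) <- k
  x4 <- m; dim(x4) <- c(dim(m)[1], dim(m)[2], 1L, dim(m)[3])
  y <- conv_fw(x4, w, numeric(k[4]), stride = 1L, pad = (k[1] - 1L) %/% 2L)$out
  array(y, c(dim(y)[1], dim(y)[2], k[4]))
}

# Batched synthesis-branch layer. h: (H, W, B, Cin); styles: (B, Cin) or
# NULL (plain mode). Returns output and caches for backprop.
syn_layer_forward <- function(layer, h, styles, eps, keep_cache = FALSE) {
  d <- dim(h)
  k <- dim(layer$theta)
  if (is.null(styles)) {                           # plain: shared kernel
    cc <- conv_fw(h, layer$theta, layer$b, stride = 1L, pad = 1L)
    out <- list(out = cc$out, plain = TRUE)
    if (keep_cache) { cc$out <- NULL; out$cache <- cc }
    return(out)
  }
  P <- cpp_im2col(h, d[1], d[2], d[3], d[4], k[1], k[2], 1L, 1L)
  npix <- d[1] * d[2]                              # same-padded stride 1
  theta_flat <- layer$theta; dim(theta_flat) <- c(k[1] * k[2] * k[3], k[4])
  y <- matrix(0, npix * d[3], k[4])
  dks <- vector("list", d[3])
  for (b in seq_len(d[3])) {
    dk <- demod_kernel(theta_flat, styles[b, ], k[1] * k[2], eps)
    rows <- ((b - 1L) * npix + 1L):(b * npix)
    y[rows, ] <- P[rows, , drop = FALSE] %*% dk$w_eff
    if (keep_cache) dks[[b]] <- dk
  }
  y <- y + rep(layer$b, each = nrow(y))
  dim(y) <- c(d[1], d[2], d[3], k[4])
  out <- list(out = y, plain = FALSE)
  if (keep_cache) out$cache <- list(P = P, indim = d, dks = dks, kdim = k,
                                    theta_flat = theta_flat)
  out
}

syn_layer_backward <- function(layer, cache, dy, styles, need_dx = TRUE) {
  cc <- cache$cache
  k <- cc$kdim; d <- cc$indim
  npix <- d[1] * d[2]
  B <- d[3]
  dym <- dy; dim(dym) <- c(npix * B, k[4])
  db <- colSums(dym)
  K <- k[1] * k[2]
  dtheta <- matrix(0, K * k[3], k[4])
  dstyles <- matrix(0, B, k[3])
  dP <- matrix(0, npix * B, K * k[3])
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * npix + 1L):(b * npix)
    dk <- cc$dks[[b]]
    gy <- dym[rows, , drop = FALSE]
    dW_eff <- crossprod(cc$P[rows, , drop = FALSE], gy)
    if (need_dx) dP[rows, ] <- tcrossprod(gy, dk$w_eff)
    inner <- colSums(dW_eff * dk$theta_hat)        # per output channel
    dth <- dW_eff * rep(1 / dk$dj, each = nrow(dW_eff)) -
      dk$theta_hat * rep(inner / dk$dj^3, each = nrow(dW_eff))
    dtheta <- dtheta + dth
    dstyles[b, ] <- colSums(matrix(rowSums(dth), K, k[3]))
  }
  dx <- NULL
  if (need_dx) {
    dx <- cpp_col2im(dP, d[1], d[2], B, k[3], k[1], k[2], 1L, 1L)
  }
  dtheta_arr <- dtheta; dim(dtheta_arr) <- k
  list(dtheta = dtheta_arr, db = db, dstyles = dstyles, dx = dx)
}

# Full AM forward on an (H, W, B, 1) stack. Returns delta (H, W, B, 1).
am_forward <- function(am, x, keep_cache = FALSE) {
  d <- dim(x)
  styles <- NULL
  enc <- NULL
  if (am$mode == "specific") {
    enc <- encoder_forward(am, x, keep_cache = keep_cache)
  }
  nlay <- length(am$syn)
  caches <- vector("list", nlay)
  style_list <- vector("list", nlay)
  h <- x
  for (i in seq_len(nlay)) {
    st <- NULL
    if (am$mode == "specific") {
      ly <- am$syn[[i]]
      st <- enc$code %*% ly$Ws + rep(ly$bs, each = nrow(enc$code)) # (B, cin)
      style_list[[i]] <- st
    }
    sf <- syn_layer_forward(am$syn[[i]], h, st, am$eps, keep_cache = keep_cache)
    h <- sf$out
    if (i < nlay) {
      ac <- lrelu_fw(h, 0.01)
      h <- ac$out
      if (keep_cache) sf$act <- ac["neg"]
    }
    if (keep_cache) { sf$out <- NULL; caches[[i]] <- sf }
  }
  h <- h + am$affine[["a"]] * x + am$affine[["b"]]
  list(delta = h, caches = caches, enc = enc, styles = style_list, x = x)
}

# Backward through the AM given dL/ddelta; returns flat gradient list.
am_backward <- function(am, fwd, ddelta) {
  grads <- list()
  grads[["affine"]] <- c(a = sum(ddelta * fwd$x), b = sum(ddelta))
  nlay <- length(am$syn)
  g <- ddelta
  dcode <- NULL
  for (i in rev(seq_len(nlay))) {
    if (i < nlay) g <- lrelu_bw(g, fwd$caches[[i]]$act, 0.01)
    if (am$mode == "specific") {
      bb <- syn_layer_backward(am$syn[[i]], fwd$caches[[i]], g,
                               fwd$styles[[i]], need_dx = i > 1L)
      grads[[paste0("syn", i, ".theta")]] <- bb$dtheta
      grads[[paste0("syn", i, ".b")]] <- bb$db
      code <- fwd$enc$code
      grads[[paste0("syn", i, ".Ws")]] <- crossprod(code, bb$dstyles)
      grads[[paste0("syn", i, ".bs")]] <- colSums(bb$dstyles)
      dci <- tcrossprod(bb$dstyles, am$syn[[i]]$Ws)     # (B, D)
      dcode <- if (is.null(dcode)) dci else dcode + dci
    } else {
      bb <- conv_bw_full(g, fwd$caches[[i]]$cache, am$syn[[i]]$theta,
                         need_dx = i > 1L)
      grads[[paste0("syn", i, ".theta")]] <- bb$dW
      grads[[paste0("syn", i, ".b")]] <- bb$db
    }
    g <- bb$dx
  }
  if (am$mode == "specific") {
    grads <- c(grads, encoder_backward(am, fwd$enc, dcode))
  }
  grads
}

#' Generate input-specific visual prompts
#'
#' Runs the double-branch alignment model: the prompt code is extracted by
#' the encoder branch, then the synthesis branch transforms the image into
#' an additive prompt, layer by layer, with every convolution modulated by
#' the code; the model's global affine component `a*x + b` (zero until
#' trained) is added on top. The prompt has exactly the shape of the
#' input image.
#'
#' @param am A `vps_am`.
#' @param images Image stack.
#' @return Prompt(s): a matrix for a single image, else an `H x W x N` array.
#' @export
generate_prompt <- function(am, images) {
  stopifnot(inherits(am, "vps_am"))
  x <- as_image_stack(images)
  delta <- am_forward(am, x)$delta
  d <- dim(delta)
  if (d[3] == 1L && (is.matrix(images) || length(dim(images)) == 2))
    return(matrix(delta, d[1], d[2]))
  array(delta, d[1:3])
}

#' Fuse an image with its visual prompt
#'
#' Additive fusion: the prompted image is `x + delta`, elementwise, with no
#' clamping (prompts are signed perturbations).
#'
#' @param x Image (matrix or array).
#' @param prompt Prompt of identical shape.
#' @return The fused image.
#' @export
fuse <- function(x, prompt) {
  if (!all(dim(x) == dim(prompt))) {
    stop("shape mismatch between image and prompt", call. = FALSE)
  }
  x + prompt
}

# Fuse a (H, W, B, 1) stack with whatever prompt source is supplied:
# an alignment model, an agnostic prompt grid, or a raw array.
fuse_stack <- function(x, am) {
  if (inherits(am, "vps_am")) {
    return(x + am_forward(am, x)$delta)
  }
  if (inherits(am, "vps_agnostic_prompt")) {
    return(x + array(am$grid, dim(x)))
  }
  if (is.matrix(am)) return(x + array(am, dim(x)))
  stop("unsupported prompt source", call. = FALSE)
}

#' Create an input-agnostic prompt (trainable shared grid)
#'
#' The baseline prompt: one `H x W` grid of free parameters, initialized to
#' zero, added identically to every input, and trainable with the same
#' batch-statistics loss as the input-specific model.
#'
#' @param h,w Grid height and width.
#' @return An object of class `vps_agnostic_prompt` with a `$grid` matrix.
#' @export
make_agnostic_prompt <- function(h, w) {
  stopifnot(h >= 1, w >= 1)
  structure(list(grid = matrix(0, h, w), log = NULL),
            class = "vps_agnostic_prompt")
}

#' @export
print.vps_agnostic_prompt <- function(x, ...) {
  cat("<vps_agnostic_prompt>", nrow(x$grid), "x", ncol(x$grid),
      "trainable grid (", length(x$grid), "parameters )\n")
  invisible(x)
}
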