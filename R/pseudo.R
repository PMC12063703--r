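# Pseudo-label construction from the frozen source model's softmax on
# (fused) target images: per-category top-k thresholds, a global threshold,
# a binary confidence mask, and the foreground MSE noise measure.

validate_soft_prediction <- function(p, tol = 1e-5) {
  d <- dim(p)
  if (is.null(d) || length(d) != 3) {
    stop("soft prediction must be an H x W x (C+1) array", call. = FALSE)
  }
  if (min(p) < -tol || max(p) > 1 + tol) {
    stop("probabilities outside [0, 1]", call. = FALSE)
  }
  sums <- rowSums(matrix(p, d[1] * d[2], d[3]))
  if (max(abs(sums - 1)) > tol) {
    stop("per-pixel channel sums deviate from 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-category confidence thresholds from a softmax prediction
#'
#' For each foreground category `c`, collects the softmax values of channel
#' `c` at the pixels whose argmax (over all channels, background included)
#' is `c`, and sets the threshold `delta_c` to the k-th largest such value.
#' If the category claims fewer than `k` pixels the smallest claimed value
#' is used; if it claims none, `delta_c = 1` so the category yields no
#' confident pixels.
#'
#' @param p Softmax array `H x W x (C+1)`; channel 1 is background.
#' @param k Rank parameter (`k >= 1`), or when `k_mode = "fraction"` a
#'   fraction in (0, 1] of each category's claimed-pixel count.
#' @param k_mode `"rank"` (absolute) or `"fraction"`.
#' @return Numeric vector `delta` of length `C` (foreground categories).
#' @export
category_thresholds <- function(p, k, k_mode = c("rank", "fraction")) {
  k_mode <- match.arg(k_mode)
  validate_soft_prediction(p)
  if (k_mode == "rank" && (!is.finite(k) || k < 1)) {
    stop("k must be >= 1", call. = FALSE)
  }
  if (k_mode == "fraction" && (k <= 0 || k > 1)) {
    stop("fractional k must be in (0, 1]", call. = FALSE)
  }
  d <- dim(p)
  C <- d[3] - 1L
  pm <- matrix(p, d[1] * d[2], d[3])
  amax <- max.col(pm, ties.method = "first")       # 1 = background
  delta <- rep(1, C)
  for (cc in seq_len(C)) {
    vals <- pm[amax == cc + 1L, cc + 1L]
    if (length(vals) == 0) next
    kk <- if (k_mode == "fraction") max(1L, ceiling(k * length(vals)))
          else as.integer(k)
    sv <- sort(vals, decreasing = TRUE)
    delta[cc] <- if (length(sv) >= kk) sv[kk] else sv[length(sv)]
  }
  delta
}

#' Double-threshold pseudo-label denoising
#'
#' Builds a one-hot pseudo-label and confidence mask from a softmax
#' prediction. A pixel whose overall argmax is a foreground category `c`
#' receives the one-hot label `c` iff its probability passes both the
#' per-category threshold (`p_c >= delta_c`, so the k-th value itself
#' survives) and the global threshold (`p_c > lambda`, strict). All other
#' pixels -- including every background-argmax pixel, since background is
#' never a pseudo-supervision target -- get an all-zero label and mask 0.
#'
#' @param p Softmax array `H x W x (C+1)`.
#' @param k,k_mode Passed to [category_thresholds()]; ignored when `delta`
#'   is given directly.
#' @param lambda Global threshold in `[0, 1]`.
#' @param delta Optional precomputed per-category thresholds.
#' @return Object of class `vps_pseudo_bundle`: `y_hat` (`H x W x C`
#'   one-hot over foreground categories), `r` (binary `H x W` mask),
#'   `delta`, `lambda`.
#' @export
denoise_double_threshold <- function(p, k = 0.33, lambda = 0.75,
                                     k_mode = c("fraction", "rank"),
                                     delta = NULL) {
  k_mode <- match.arg(k_mode)
  validate_soft_prediction(p)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  d <- dim(p)
  C <- d[3] - 1L
  if (is.null(delta)) {
    delta <- category_thresholds(p, k, k_mode)
  } else if (length(delta) != C) {
    stop("delta must have one threshold per foreground category",
         call. = FALSE)
  }
  pm <- matrix(p, d[1] * d[2], d[3])
  amax <- max.col(pm, ties.method = "first")
  fg <- amax > 1L
  cstar <- amax - 1L                               # foreground category id
  pc <- pm[cbind(seq_len(nrow(pm)), amax)]         # prob of argmax channel
  keep <- fg & pc >= delta[pmax(cstar, 1L)] & pc > lambda
  y <- array(0, c(d[1], d[2], C))
  if (any(keep)) {
    ym <- matrix(0, d[1] * d[2], C)
    ym[cbind(which(keep), cstar[keep])] <- 1
    y <- array(ym, c(d[1], d[2], C))
  }
  r <- matrix(0L, d[1], d[2])
  r[keep] <- 1L
  structure(list(y_hat = y, r = r, delta = delta, lambda = lambda),
            class = "vps_pseudo_bundle")
}

#' @export
print.vps_pseudo_bundle <- function(x, ...) {
  cat("<vps_pseudo_bundle>", paste(dim(x$r), collapse = "x"),
      "| confident pixels:", sum(x$r),
      sprintf("(%.1f%%)", 100 * mean(x$r)), "\n")
  invisible(x)
}

#' Wrap a denoising function for the adaptation stage
#'
#' The adaptation stage accepts any function mapping a softmax prediction
#' (`H x W x (C+1)` array) to a pseudo-label bundle, so published denoising
#' schemes can be plugged in. This wrapper validates conformance on each
#' call. The built-in double-threshold denoiser is the default.
#'
#' @param g Function `p -> list(y_hat, r)`.
#' @return A validated denoiser function.
#' @examples
#' argmax_denoiser <- as_denoiser(function(p) {
#'   denoise_double_threshold(p, k = 1, k_mode = "fraction", lambda = 0)
#' })
#' @export
as_denoiser <- function(g) {
  stopifnot(is.function(g))
  function(p) {
    out <- g(p)
    d <- dim(p)
    if (is.null(out$y_hat) || is.null(out$r) ||
        !all(dim(out$y_hat)[1:2] == d[1:2]) || !all(dim(out$r) == d[1:2]) ||
        dim(out$y_hat)[3] != d[3] - 1L) {
      stop("denoiser output does not conform: need y_hat (H x W x C) ",
           "and r (H x W) matching the prediction", call. = FALSE)
    }
    nz <- rowSums(matrix(out$y_hat, d[1] * d[2], d[3] - 1L)) != 0
    if (!identical(as.integer(nz), as.integer(out$r != 0))) {
      stop("denoiser output violates mask/label consistency", call. = FALSE)
    }
    out
  }
}

default_denoiser <- function(k = 0.33, lambda = 0.75,
                             k_mode = "fraction") {
  force(k); force(lambda); force(k_mode)
  as_denoiser(function(p) {
    denoise_double_threshold(p, k = k, lambda = lambda, k_mode = k_mode)
  })
}

#' Pseudo-label noise: foreground mean squared error
#'
#' Measures pseudo-label noise against a reference annotation as the MSE
#' over the `C` foreground one-hot channels, averaged over categories and
#' pixels: `(1/C) * sum_c mean_px (y_hat_c - y_c)^2`. Zero iff the
#' pseudo-label equals the reference everywhere on foreground channels; a
#' pixel pseudo-labeled `a` whose true class is `b != a` contributes
#' `2/C` before pixel averaging.
#'
#' @param y_hat `H x W x C` one-hot array, or a `vps_pseudo_bundle`.
#' @param labels Integer `H x W` label mask (0 = background).
#' @return Scalar MSE.
#' @export
pseudo_label_mse <- function(y_hat, labels) {
  if (inherits(y_hat, "vps_pseudo_bundle")) y_hat <- y_hat$y_hat
  d <- dim(y_hat)
  if (!all(d[1:2] == dim(labels)[1:2])) {
    stop("shape mismatch between pseudo-labels and reference", call. = FALSE)
  }
  C <- d[3]
  validate_labels(labels, C)
  n <- d[1] * d[2]
  ym <- matrix(y_hat, n, C)
  gm <- matrix(0, n, C)
  lv <- as.vector(labels)
  fgpix <- lv > 0
  gm[cbind(which(fgpix), lv[fgpix])] <- 1
  mean(colMeans((ym - gm)^2))
}

#' Generate pseudo-label bundles for a stack of target images
#'
#' Applies the frozen teacher (source model, optionally with prompt fusion)
#' to each image and denoises the softmax prediction.
#'
#' @param model Frozen `vps_model` teacher.
#' @param images Target image stack.
#' @param am Optional prompt source (`vps_am` or agnostic grid); prompts
#'   are fused before prediction.
#' @param denoiser A denoiser (see [as_denoiser()]); defaults to the
#'   double-threshold scheme with `k` fraction 0.33 and `lambda` 0.75.
#' @param batch_size Images per forward pass.
#' @return List of `vps_pseudo_bundle`, one per image.
#' @export
make_pseudo_labels <- function(model, images, am = NULL,
                               denoiser = default_denoiser(),
                               batch_size = 8L) {
  x <- as_image_stack(images)
  n <- dim(x)[3]
  out <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1L, n)
    p <- predict_soft(model, x[, , ids, 1, drop = TRUE], am = am)
    if (length(ids) == 1L) dim(p) <- c(dim(p)[1], dim(p)[2], 1L, dim(p)[4])
    for (j in seq_along(ids)) {
      out[[ids[j]]] <- denoiser(array(p[, , j, ], dim(p)[c(1, 2, 4)]))
    }
  }
  out
}
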