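# Stage 2: self-training of the target model on fused target images with
# confidence-masked cross-entropy against denoised pseudo-labels. The
# teacher (frozen source model + frozen alignment model) produces the
# pseudo-labels once; only the target model is updated.

#' Initialize the target model as a copy of the source model
#'
#' Deep copy: parameters and BN running statistics are bitwise equal at
#' initialization, and later updates to the target model never touch the
#' source model.
#'
#' @param source Trained `vps_model`.
#' @return A new `vps_model`, parameter-identical to `source`.
#' @export
init_target_model <- function(source) {
  stopifnot(inherits(source, "vps_model"))
  target <- source
  target$log <- NULL
  target
}

#' Confidence-masked cross-entropy
#'
#' Per-pixel cross-entropy of a softmax prediction against a one-hot
#' pseudo-label, multiplied elementwise (Hadamard product) by the binary
#' confidence mask and averaged over the confident pixels. Masked-out
#' pixels contribute neither loss nor gradient; with no confident pixels
#' the loss is 0.
#'
#' @param pred Softmax array `H x W x (C+1)` (channel 1 = background).
#' @param bundle A `vps_pseudo_bundle` (or list with `y_hat`, `r`).
#' @return Scalar loss.
#' @export
masked_ce <- function(pred, bundle) {
  d <- dim(pred)
  C <- d[3] - 1L
  if (!all(dim(bundle$y_hat)[1:2] == d[1:2]) || dim(bundle$y_hat)[3] != C ||
      !all(dim(bundle$r) == d[1:2])) {
    stop("shape mismatch between prediction and pseudo-label bundle",
         call. = FALSE)
  }
  conf <- which(bundle$r != 0)
  if (length(conf) == 0) return(0)
  pm <- matrix(pred, d[1] * d[2], d[3])
  ym <- matrix(bundle$y_hat, d[1] * d[2], C)
  cls <- max.col(ym[conf, , drop = FALSE], ties.method = "first")
  -mean(log(pmax(pm[cbind(conf, cls + 1L)], 1e-12)))
}

# Stack a list of bundles for a batch into pixel matrices.
stack_bundles <- function(bundles, ids, d) {
  C <- dim(bundles[[ids[1]]]$y_hat)[3]
  npix <- d[1] * d[2]
  y <- matrix(0, npix * length(ids), C + 1L)
  r <- numeric(npix * length(ids))
  for (j in seq_along(ids)) {
    b <- bundles[[ids[j]]]
    rows <- ((j - 1L) * npix + 1L):(j * npix)
    y[rows, -1L] <- matrix(b$y_hat, npix, C)
    r[rows] <- as.vector(b$r)
  }
  list(y = y, r = r)
}

#' Stage 2: adapt the target model with masked self-training
#'
#' Initializes the target model as a parameter copy of the frozen source
#' model, generates pseudo-label bundles once from the fixed teacher
#' (source model applied to fused images `x + AM(x)`), then fine-tunes the
#' target model on the same fused images by minimizing confidence-masked
#' cross-entropy with Adam. The alignment model and source model are never
#' updated.
#'
#' @param source Trained, frozen `vps_model` (the teacher).
#' @param am Frozen prompt source (`vps_am`, agnostic grid, or `NULL` for
#'   raw images).
#' @param target_images Unlabeled target image stack.
#' @param denoiser Denoiser used on the teacher's softmax (see
#'   [as_denoiser()]).
#' @param epochs,batch_size,lr,weight_decay,seed Optimizer settings.
#' @param verbose Print per-epoch loss.
#' @return Adapted `vps_model`; `$log` holds per-epoch mean masked CE, and
#'   `$bundles` attribute carries the pseudo-labels that supervised it.
#' @export
adapt <- function(source, am, target_images, denoiser = default_denoiser(),
                  epochs = 2L, batch_size = 4L, lr = 1e-3, weight_decay = 0,
                  seed = 1L, verbose = FALSE) {
  x <- as_image_stack(target_images)
  n <- dim(x)[3]
  if (n == 0) stop("empty target set", call. = FALSE)
  fused <- if (is.null(am)) x else fuse_stack(x, am)
  bundles <- make_pseudo_labels(source, array(fused, dim(fused)[1:3]),
                                am = NULL, denoiser = denoiser)
  target <- init_target_model(source)
  params <- model_params(target)
  state <- adam_init(params)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  log_epoch <- numeric(epochs)
  d <- dim(fused)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      ids <- ord[start:min(start + batch_size - 1L, n)]
      xb <- fused[, , ids, , drop = FALSE]
      sb <- stack_bundles(bundles, ids, d)
      nconf <- sum(sb$r != 0)
      if (nconf == 0) { losses <- c(losses, 0); next }
      target <- set_model_params(target, params)
      fw <- forward_backbone(target, xb, training = TRUE, keep_cache = TRUE)
      target <- fw$model
      dd <- dim(fw$logits); npixb <- dd[1] * dd[2] * dd[3]
      zm <- fw$logits; dim(zm) <- c(npixb, dd[4])
      p <- softmax_mat(zm)
      conf <- sb$r != 0
      loss <- -mean(log(pmax(p[conf, , drop = FALSE][sb$y[conf, , drop = FALSE] > 0],
                             1e-12)))
      losses <- c(losses, loss)
      if (lr > 0) {
        dz <- (p - sb$y) * sb$r / nconf
        dim(dz) <- dd
        bw <- backward_backbone(target, fw$caches, dz)
        st <- adam_step(params, bw$grads, state, lr = lr,
                        weight_decay = weight_decay)
        params <- st$params; state <- st$state
      }
    }
    log_epoch[ep] <- mean(losses)
    if (verbose) message(sprintf("adapt epoch %d  masked CE %.4f", ep,
                                 log_epoch[ep]))
  }
  target <- set_model_params(target, params)
  target$log <- tibble::tibble(epoch = seq_len(epochs), loss = log_epoch)
  attr(target, "bundles") <- bundles
  target
}
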