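# Batch-normalization-constraint (BNC) objective: match the batch
# statistics of prompted target images, measured at the BN layers of the
# frozen source model, to the running statistics those layers stored while
# training on source data.

#' Extract the BN running statistics of a source model
#'
#' The running mean and (population) variance stored in each
#' batch-normalization layer summarize the feature distribution of the data
#' the model was trained on -- the source domain's fingerprint. This is a
#' read-only operation.
#'
#' @param model A `vps_model` with at least one BN layer.
#' @return Object of class `vps_bn_stats`: per-layer channel vectors of
#'   means and variances, keyed by layer position.
#' @export
extract_source_bn_stats <- function(model) {
  ids <- bn_layer_indices(model)
  if (length(ids) == 0) {
    stop("model has no batch-normalization layers", call. = FALSE)
  }
  structure(list(
    layer_ids = ids,
    mean = lapply(ids, function(i) model$layers[[i]]$rmean),
    var = lapply(ids, function(i) model$layers[[i]]$rvar)
  ), class = "vps_bn_stats")
}

#' Capture batch statistics of a frozen model on a batch
#'
#' Runs the model in inference mode (BN layers normalize by their running
#' statistics, so the stored source fingerprint stays untouched) while
#' recording the per-channel mean and population variance of the
#' pre-normalization feature maps at every BN layer, computed over the
#' batch and spatial dimensions. Model parameters and running statistics
#' are unchanged.
#'
#' @param model A frozen `vps_model`.
#' @param batch Image stack (typically fused target images).
#' @return Object of class `vps_bn_stats` holding the batch moments.
#' @export
capture_batch_stats <- function(model, batch) {
  x <- as_image_stack(batch)
  if (dim(x)[3] < 1) stop("empty batch", call. = FALSE)
  ids <- bn_layer_indices(model)
  if (length(ids) == 0) {
    stop("model has no batch-normalization layers", call. = FALSE)
  }
  fw <- forward_backbone(model, x, training = FALSE, capture = TRUE)
  structure(list(
    layer_ids = ids,
    mean = lapply(as.character(ids), function(k) fw$captured$mean[[k]]),
    var = lapply(as.character(ids), function(k) fw$captured$var[[k]])
  ), class = "vps_bn_stats")
}

#' @export
print.vps_bn_stats <- function(x, ...) {
  cat("<vps_bn_stats>", length(x$layer_ids), "BN layers; channels:",
      paste(lengths(x$mean), collapse = "/"), "\n")
  invisible(x)
}

#' Batch-normalization-constraint loss
#'
#' Sums, over BN layers, the squared deviation between captured batch
#' moments and stored source moments:
#' `sum_l agg_c[(mu_lc - mu_bar_lc)^2 + (v_lc - v_bar_lc)^2]`,
#' where `agg` averages over channels by default (`"sum"` reproduces the
#' plain squared norm; averaging keeps wide layers from dominating).
#' The loss is nonnegative and zero exactly when all statistics match.
#'
#' @param batch `vps_bn_stats` captured from a batch.
#' @param source `vps_bn_stats` extracted from the source model.
#' @param channel_agg `"mean"` (default) or `"sum"` aggregation within a layer.
#' @param layers Optional subset of layer positions to include.
#' @return Scalar loss.
#' @export
bnc_loss <- function(batch, source, channel_agg = c("mean", "sum"),
                     layers = NULL) {
  channel_agg <- match.arg(channel_agg)
  if (!identical(batch$layer_ids, source$layer_ids)) {
    stop("batch and source statistics cover different BN layers", call. = FALSE)
  }
  keep <- if (is.null(layers)) seq_along(batch$layer_ids)
          else match(layers, batch$layer_ids)
  if (anyNA(keep)) stop("unknown BN layer id in `layers`", call. = FALSE)
  total <- 0
  for (j in keep) {
    if (length(batch$mean[[j]]) != length(source$mean[[j]])) {
      stop("channel count mismatch at BN layer ", batch$layer_ids[j],
           call. = FALSE)
    }
    term <- (batch$mean[[j]] - source$mean[[j]])^2 +
      (batch$var[[j]] - source$var[[j]])^2
    total <- total + if (channel_agg == "mean") mean(term) else sum(term)
  }
  total
}

# Loss and BN-input injection gradients for a fused batch, computed from a
# captured forward pass of the frozen source model. The gradient of each
# layer term with respect to the pre-BN feature map h is
#   2*a_l*[(mu - mu_bar)/n + 2*(v - v_bar)*(h - mu)/n]
# with a_l = 1/C_l for mean aggregation, n = batch*spatial count.
bnc_terms_from_caches <- function(model, caches, channel_agg, layers = NULL) {
  ids <- bn_layer_indices(model)
  use <- if (is.null(layers)) ids else ids[ids %in% layers]
  loss <- 0
  inject <- list()
  for (i in use) {
    cc <- caches[[i]]
    l <- model$layers[[i]]
    nC <- length(l$rmean)
    a <- if (channel_agg == "mean") 1 / nC else 1
    dmu <- cc$batch_mean - l$rmean
    dv <- cc$batch_var - l$rvar
    loss <- loss + a * sum(dmu^2 + dv^2)
    n <- nrow(cc$xc_b)
    gm <- 2 * a / n * (rep(dmu, each = n) + 2 * cc$xc_b * rep(dv, each = n))
    dim(gm) <- cc$d
    inject[[as.character(i)]] <- gm
  }
  list(loss = loss, inject = inject)
}

# Stage-1 objective for one batch: returns the BNC loss and its gradients
# with respect to the prompt parameters (alignment model or agnostic grid).
stage1_batch <- function(source, am, xb, channel_agg = "mean", layers = NULL,
                         need_grads = TRUE) {
  agnostic <- inherits(am, "vps_agnostic_prompt")
  if (agnostic) {
    fused <- xb + array(am$grid, dim(xb))
    fwd_am <- NULL
  } else {
    fwd_am <- am_forward(am, xb, keep_cache = need_grads)
    fused <- xb + fwd_am$delta
  }
  fw <- forward_backbone(source, fused, training = FALSE, capture = TRUE,
                         keep_cache = need_grads, keep_xc = need_grads)
  if (!need_grads) {
    st <- capture_from_forward(source, fw)
    src <- extract_source_bn_stats(source)
    return(list(loss = bnc_loss(st, src, channel_agg, layers)))
  }
  terms <- bnc_terms_from_caches(source, fw$caches, channel_agg, layers)
  zero_top <- array(0, dim(fw$logits))
  bw <- backward_backbone(source, fw$caches, zero_top, need_dx = TRUE,
                          need_dw = FALSE, inject = terms$inject)
  dfused <- bw$dx
  if (agnostic) {
    grads <- list(grid = matrix(rowSums(matrix(dfused, ncol = dim(xb)[3])),
                                dim(xb)[1], dim(xb)[2]))
  } else {
    grads <- am_backward(am, fwd_am, dfused)
  }
  list(loss = terms$loss, grads = grads, dfused = dfused)
}

capture_from_forward <- function(model, fw) {
  ids <- bn_layer_indices(model)
  structure(list(
    layer_ids = ids,
    mean = lapply(as.character(ids), function(k) fw$captured$mean[[k]]),
    var = lapply(as.character(ids), function(k) fw$captured$var[[k]])
  ), class = "vps_bn_stats")
}

#' Re-estimate a model's BN running statistics on a dataset
#'
#' Runs forward passes in training mode, updating only the BN running
#' buffers (weights untouched). Useful after short training runs, where
#' the exponential moving average lags behind the final weights, so that
#' the stored statistics faithfully fingerprint the source domain.
#'
#' @param model A `vps_model`.
#' @param images Image stack (typically the training images).
#' @param passes Number of passes over the data.
#' @param batch_size Images per forward pass.
#' @return The model with refreshed running statistics.
#' @export
refresh_bn_stats <- function(model, images, passes = 2L, batch_size = 8L) {
  x <- as_image_stack(images)
  n <- dim(x)[3]
  if (n == 0) stop("empty dataset", call. = FALSE)
  for (p in seq_len(passes)) {
    for (start in seq(1, n, by = batch_size)) {
      ids <- start:min(start + batch_size - 1L, n)
      fw <- forward_backbone(model, x[, , ids, , drop = FALSE],
                             training = TRUE)
      model <- fw$model
    }
  }
  model
}

#' Stage 1: train the alignment model under the BNC loss
#'
#' Optimizes the prompt generator (or the agnostic grid baseline) so that
#' fused target images `x + AM(x)` reproduce, inside the frozen source
#' model's BN layers, the batch statistics stored during source training.
#' The source model is never updated -- neither parameters nor running
#' statistics.
#'
#' @param source Trained, frozen `vps_model`.
#' @param am A `vps_am` (any mode) or a `vps_agnostic_prompt`.
#' @param target_images Unlabeled target-domain image stack.
#' @param epochs,batch_size,lr,weight_decay Adam settings (stage defaults
#'   mirror the source-training convention; desk scale uses `lr = 1e-3`).
#' @param channel_agg Channel aggregation inside each layer term.
#' @param layers Optional subset of BN layer positions to constrain.
#' @param clip_norm Global gradient-norm clip applied before the Adam
#'   update (default 1). An untrained demodulated synthesis branch can
#'   produce very large prompts on smooth, spatially correlated images
#'   (demodulation assumes i.i.d. activations), so the first BNC losses
#'   are huge; clipping keeps that transient from destabilizing Adam.
#'   `NULL` disables clipping.
#' @param warm_start For `vps_am` prompts: initialize the global affine
#'   component of the prompt by a coarse grid search over the contrast
#'   gain `a` (loss evaluated on one fixed batch) before gradient
#'   training. The BNC landscape over `a` is bimodal for contrast-
#'   inverting shifts -- constant images form a high-loss barrier at
#'   `a = -1` -- so a global search is required; gradient descent from
#'   `a = 0` cannot cross it. The searched component is then refined
#'   jointly with the synthesis branch by the same loss.
#' @param warm_grid Candidate gains for the warm start.
#' @param seed Shuffling seed.
#' @param verbose Print per-epoch mean loss.
#' @return The trained prompt object; `$log` holds a tibble with columns
#'   `step`, `epoch`, `loss`.
#' @export
train_alignment <- function(source, am, target_images, epochs = 2L,
                            batch_size = 4L, lr = 1e-3, weight_decay = 0,
                            channel_agg = c("mean", "sum"), layers = NULL,
                            clip_norm = 1, warm_start = TRUE,
                            warm_grid = seq(-3, 1, by = 0.25),
                            seed = 1L, verbose = FALSE) {
  channel_agg <- match.arg(channel_agg)
  x <- as_image_stack(target_images)
  n <- dim(x)[3]
  if (n == 0) stop("empty target set", call. = FALSE)
  agnostic <- inherits(am, "vps_agnostic_prompt")
  params <- if (agnostic) list(grid = am$grid) else am_params(am)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (!agnostic && warm_start && lr > 0) {
    probe <- x[, , seq_len(min(8L, n)), , drop = FALSE]
    losses <- vapply(warm_grid, function(a) {
      am$affine <- c(a = a, b = params$affine[["b"]])
      stage1_batch(source, am, probe, channel_agg, layers,
                   need_grads = FALSE)$loss
    }, numeric(1))
    params$affine[["a"]] <- warm_grid[which.min(losses)]
    am$affine <- params$affine
  }
  state <- adam_init(params)
  steps <- 0L
  log_step <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      ids <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[, , ids, , drop = FALSE]
      if (agnostic) am$grid <- params$grid else am <- set_am_params(am, params)
      sb <- stage1_batch(source, am, xb, channel_agg, layers,
                         need_grads = lr > 0)
      steps <- steps + 1L
      log_step[[steps]] <- c(steps, ep, sb$loss)
      if (lr > 0) {
        st <- adam_step(params, clip_global_norm(sb$grads, clip_norm),
                        state, lr = lr, weight_decay = weight_decay)
        params <- st$params; state <- st$state
      }
    }
    if (verbose) {
      epoch_losses <- vapply(log_step, identity, numeric(3))
      message(sprintf("stage1 epoch %d  BNC %.5f", ep,
                      mean(epoch_losses[3, epoch_losses[2, ] == ep])))
    }
  }
  if (agnostic) am$grid <- params$grid else am <- set_am_params(am, params)
  lg <- do.call(rbind, log_step)
  am$log <- tibble::tibble(step = as.integer(lg[, 1]),
                           epoch = as.integer(lg[, 2]), loss = lg[, 3])
  am
}
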