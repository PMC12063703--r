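# BN-bearing segmentation backbones and supervised source-domain training.

.arch_registry <- new.env(parent = emptyenv())

#' Register a backbone architecture
#'
#' The package ships a `"tiny"` backbone (four 3x3 conv -> BN -> leaky-ReLU
#' blocks, widths 16/32/32/16, no downsampling, final 1x1 projection) sized
#' so a CPU trains it in minutes while keeping the batch-normalization
#' structure the alignment stage needs. Larger nets can be plugged in by
#' registering a builder.
#'
#' @param name Architecture name used in [build_backbone()].
#' @param builder `function(num_classes)` returning a list of layer specs.
#' @export
register_backbone <- function(name, builder) {
  stopifnot(is.character(name), is.function(builder))
  .arch_registry[[name]] <- builder
  invisible(name)
}

tiny_builder <- function(num_classes) {
  widths <- c(16L, 32L, 32L, 16L)
  layers <- list()
  cin <- 1L
  for (wd in widths) {
    layers <- c(layers, list(
      list(type = "conv", cin = cin, cout = wd, k = 3L, pad = 1L, stride = 1L),
      list(type = "bn", channels = wd),
      list(type = "lrelu", slope = 0.01)
    ))
    cin <- wd
  }
  c(layers, list(list(type = "conv", cin = cin, cout = num_classes + 1L,
                      k = 1L, pad = 0L, stride = 1L)))
}

.arch_registry[["tiny"]] <- tiny_builder

#' Build a segmentation backbone
#'
#' Constructs an untrained BN-bearing convolutional segmentation model with
#' `num_classes + 1` output channels (foreground classes plus an explicit
#' background channel, so per-pixel cross-entropy is well-posed everywhere).
#' Construction is deterministic given `seed`: convolution weights are
#' Kaiming-He normal, biases zero, BN running statistics start at mean 0 /
#' variance 1.
#'
#' @param arch Registered architecture name; `"tiny"` is built in.
#' @param num_classes Number of foreground classes `C` (>= 1).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `vps_model`.
#' @examples
#' m <- build_backbone("tiny", num_classes = 4, seed = 0)
#' length(bn_layer_indices(m))
#' @export
build_backbone <- function(arch = "tiny", num_classes = 4L, seed = 0L) {
  builder <- .arch_registry[[arch]]
  if (is.null(builder)) {
    stop("unknown architecture '", arch, "'; registered: ",
         paste(ls(.arch_registry), collapse = ", "), call. = FALSE)
  }
  num_classes <- as.integer(num_classes)
  if (is.na(num_classes) || num_classes < 1L) {
    stop("num_classes must be an integer >= 1", call. = FALSE)
  }
  specs <- builder(num_classes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  layers <- lapply(specs, function(sp) {
    if (sp$type == "conv") {
      sp$W <- kaiming_weight(sp$k, sp$k, sp$cin, sp$cout)
      sp$b <- numeric(sp$cout)
    } else if (sp$type == "bn") {
      sp$gamma <- rep(1, sp$channels)
      sp$beta <- rep(0, sp$channels)
      sp$rmean <- rep(0, sp$channels)
      sp$rvar <- rep(1, sp$channels)
      sp$eps <- 1e-5
      sp$momentum <- 0.1
    }
    sp
  })
  structure(list(arch = arch, num_classes = num_classes, seed = seed,
                 layers = layers, log = NULL),
            class = "vps_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.vps_model <- function(x, ...) {
  nconv <- sum(vapply(x$layers, function(l) l$type == "conv", logical(1)))
  nbn <- length(bn_layer_indices(x))
  cat("<vps_model> arch:", x$arch, "| foreground classes:", x$num_classes,
      "| conv layers:", nconv, "| BN layers:", nbn,
      "| parameters:", format(sum(lengths(model_params(x))), big.mark = ","),
      "\n")
  invisible(x)
}

#' Indices of the batch-normalization layers of a model
#' @param model A `vps_model`.
#' @return Integer vector of positions in `model$layers`.
#' @export
bn_layer_indices <- function(model) {
  which(vapply(model$layers, function(l) l$type == "bn", logical(1)))
}

# Flat named list of all trainable parameters (used by Adam and by
# bitwise-identity checks in the two-stage protocol).
#' Extract the trainable parameters and BN buffers of a model
#' @param model A `vps_model`.
#' @param buffers Include BN running statistics as well.
#' @return Named list of numeric arrays.
#' @export
model_params <- function(model, buffers = FALSE) {
  out <- list()
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      out[[paste0("L", i, ".W")]] <- l$W
      out[[paste0("L", i, ".b")]] <- l$b
    } else if (l$type == "bn") {
      out[[paste0("L", i, ".gamma")]] <- l$gamma
      out[[paste0("L", i, ".beta")]] <- l$beta
      if (buffers) {
        out[[paste0("L", i, ".rmean")]] <- l$rmean
        out[[paste0("L", i, ".rvar")]] <- l$rvar
      }
    }
  }
  out
}

set_model_params <- function(model, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- as.integer(sub("^L", "", parts[1]))
    model$layers[[i]][[parts[2]]] <- flat[[nm]]
  }
  model
}

# Forward pass through the backbone.
#  training: BN normalizes by batch stats and updates running buffers.
#  capture: record pre-BN batch moments (used by the BNC objective).
# Returns logits (H, W, B, C+1), per-layer caches, possibly-updated model,
# and captured batch statistics.
forward_backbone <- function(model, x, training = FALSE, capture = FALSE,
                             keep_cache = FALSE, keep_xc = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  captured <- if (capture) list(mean = list(), var = list()) else NULL
  h <- x
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      cc <- conv_fw(h, l$W, l$b, stride = l$stride, pad = l$pad)
      h <- cc$out
      if (keep_cache) {
        cc$out <- NULL
        caches[[i]] <- cc
      }
    } else if (l$type == "bn") {
      cc <- bn_fw(h, l$gamma, l$beta, l$rmean, l$rvar, eps = l$eps,
                  training = training, momentum = l$momentum,
                  keep_xc = keep_xc)
      h <- cc$out
      if (training) {
        model$layers[[i]]$rmean <- cc$rmean
        model$layers[[i]]$rvar <- cc$rvar
      }
      if (capture) {
        captured$mean[[as.character(i)]] <- cc$batch_mean
        captured$var[[as.character(i)]] <- cc$batch_var
      }
      if (keep_cache) {
        cc$out <- NULL
        caches[[i]] <- cc
      }
    } else if (l$type == "lrelu") {
      cc <- lrelu_fw(h, l$slope)
      h <- cc$out
      if (keep_cache) {
        cc$out <- NULL
        caches[[i]] <- cc
      }
    } else {
      stop("unknown layer type: ", l$type)
    }
  }
  list(logits = h, caches = caches, model = model, captured = captured)
}

# Backward pass; dlogits has the shape of the logits. Returns parameter
# gradients (flat named list) and optionally the input gradient.
backward_backbone <- function(model, caches, dlogits, need_dx = FALSE,
                              need_dw = TRUE, inject = NULL) {
  grads <- list()
  g <- dlogits
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      bb <- conv_bw_full(g, caches[[i]], l$W,
                         need_dx = need_dx || i > 1L, need_dw = need_dw)
      if (need_dw) {
        grads[[paste0("L", i, ".W")]] <- bb$dW
        grads[[paste0("L", i, ".b")]] <- bb$db
      }
      g <- bb$dx
    } else if (l$type == "bn") {
      if (!is.null(inject) && !is.null(inject[[as.character(i)]])) {
        # gradient of a statistics-matching loss on the pre-BN feature map
        # enters here, in addition to whatever flows down from above
        bb <- bn_bw(g, caches[[i]])
        g <- bb$dx + inject[[as.character(i)]]
      } else {
        bb <- bn_bw(g, caches[[i]])
        g <- bb$dx
      }
      if (need_dw) {
        grads[[paste0("L", i, ".gamma")]] <- bb$dgamma
        grads[[paste0("L", i, ".beta")]] <- bb$dbeta
      }
    } else if (l$type == "lrelu") {
      g <- lrelu_bw(g, caches[[i]], l$slope)
    }
  }
  list(grads = grads, dx = g)
}

validate_labels <- function(labels, num_classes) {
  if (!all(is.finite(labels))) stop("labels contain non-finite values", call. = FALSE)
  if (any(labels != round(labels))) stop("labels must be integers", call. = FALSE)
  if (min(labels) < 0 || max(labels) > num_classes) {
    stop("label values out of range [0, ", num_classes, "]", call. = FALSE)
  }
  invisible(TRUE)
}

# One-hot pixel matrix (H*W*B, C+1) from an (H, W, B) integer label array.
one_hot_pixels <- function(labels, num_classes) {
  n <- length(labels)
  y <- matrix(0, n, num_classes + 1L)
  y[cbind(seq_len(n), as.vector(labels) + 1L)] <- 1
  y
}

#' Train a segmentation model on labeled source-domain slices
#'
#' Minimizes per-pixel cross-entropy (over background + foreground channels)
#' with Adam. BN layers run in training mode, so running statistics absorb
#' the source-domain feature distribution -- these buffers are the
#' "fingerprint" that the alignment stage later matches.
#'
#' @param model A `vps_model` from [build_backbone()].
#' @param images Source images: `H x W x N` array, list of matrices, or a
#'   single matrix.
#' @param labels Integer label maps (`0` = background) of matching shape.
#' @param epochs,batch_size,lr,weight_decay Optimizer settings. The tiny
#'   backbone converges on the phantom task with `lr = 1e-3` in a handful of
#'   epochs; see [vps_config()] for the full-scale convention.
#' @param seed Seed controlling shuffling (and augmentation, if enabled).
#' @param augment Apply random horizontal flips to image/label pairs.
#' @param verbose Print per-epoch loss.
#' @return The trained `vps_model`; `model$log` holds a tibble with columns
#'   `epoch` and `loss` (mean training cross-entropy).
#' @export
train_source <- function(model, images, labels, epochs = 10L, batch_size = 4L,
                         lr = 1e-3, weight_decay = 0, seed = 1L,
                         augment = FALSE, verbose = FALSE) {
  x <- as_image_stack(images)
  if (is.list(labels)) labels <- array(unlist(labels), dim(x)[c(1, 2, 3)])
  if (length(dim(labels)) == 2) dim(labels) <- c(dim(labels), 1L)
  n <- dim(x)[3]
  if (n == 0) stop("empty dataset", call. = FALSE)
  validate_labels(labels, model$num_classes)
  stopifnot(all(dim(labels) == dim(x)[c(1, 2, 3)]))

  params <- model_params(model)
  state <- adam_init(params)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  log_epoch <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      ids <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[, , ids, , drop = FALSE]
      yb <- labels[, , ids, drop = FALSE]
      if (augment) {
        for (j in seq_along(ids)) {
          if (stats::runif(1) < 0.5) {
            xb[, , j, 1] <- xb[rev(seq_len(dim(xb)[1])), , j, 1]
            yb[, , j] <- yb[rev(seq_len(dim(yb)[1])), , j]
          }
        }
      }
      model <- set_model_params(model, params)
      fw <- forward_backbone(model, xb, training = TRUE, keep_cache = TRUE)
      model <- fw$model                      # updated BN running stats
      d <- dim(fw$logits); npix <- d[1] * d[2] * d[3]
      zm <- fw$logits; dim(zm) <- c(npix, d[4])
      p <- softmax_mat(zm)
      yoh <- one_hot_pixels(yb, model$num_classes)
      loss <- -mean(log(pmax(p[yoh > 0], 1e-12)))
      losses <- c(losses, loss)
      dz <- (p - yoh) / npix
      dim(dz) <- d
      if (lr > 0) {
        bw <- backward_backbone(model, fw$caches, dz)
        st <- adam_step(params, bw$grads, state, lr = lr,
                        weight_decay = weight_decay)
        params <- st$params; state <- st$state
      }
    }
    log_epoch[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d  CE %.4f", ep, log_epoch[ep]))
  }
  model <- set_model_params(model, params)
  model$log <- tibble::tibble(epoch = seq_len(epochs), loss = log_epoch)
  model
}

#' Per-pixel softmax prediction of a frozen model
#'
#' Runs the model in inference mode (BN layers normalize by their running
#' statistics) and returns per-pixel class probabilities.
#'
#' @param model A `vps_model`.
#' @param images Image stack (see [train_source()]).
#' @param am Optional alignment model (or agnostic prompt); when supplied,
#'   each image is fused with its visual prompt before prediction.
#' @return Array `H x W x N x (C+1)` of probabilities summing to 1 per pixel.
#' @export
predict_soft <- function(model, images, am = NULL) {
  x <- as_image_stack(images)
  if (!is.null(am)) x <- fuse_stack(x, am)
  fw <- forward_backbone(model, x, training = FALSE)
  d <- dim(fw$logits)
  zm <- fw$logits; dim(zm) <- c(d[1] * d[2] * d[3], d[4])
  p <- softmax_mat(zm)
  dim(p) <- d
  p
}

#' Hard segmentation (per-pixel argmax) of a model
#' @inheritParams predict_soft
#' @return Integer array `H x W x N`, values in `0..C`.
#' @export
predict_labels <- function(model, images, am = NULL) {
  p <- predict_soft(model, images, am = am)
  d <- dim(p)
  pm <- p; dim(pm) <- c(d[1] * d[2] * d[3], d[4])
  lab <- max.col(pm, ties.method = "first") - 1L
  array(lab, d[1:3])
}
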