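# Synthetic cross-modality phantom benchmark: paired two-domain 2-D
# segmentation data with identical label geometry per slice and
# modality-like intensity shift (near-inverted class intensity tables,
# different noise and multiplicative bias fields), standing in for CT/MRI
# cross-modality pairs so the whole pipeline is testable at desk scale.

#' Specify a synthetic two-domain phantom dataset
#'
#' Both domains share the label geometry of every slice; only the intensity
#' rendering differs. Domain A uses an increasing class intensity table,
#' domain B a (slightly perturbed) decreasing one -- cross-modality shifts
#' are dominated by tissue-intensity remapping, and a near-inversion
#' survives per-slice normalization (which cancels any affine remap but not
#' a reordering), so a model trained on A degrades substantially on B.
#'
#' @param image_size Slice height/width (square), default 64.
#' @param n_classes Foreground classes `C`, default 4.
#' @param n_slices Slices per domain.
#' @param seed Master seed; every random choice derives from it.
#' @param domain_a,domain_b Per-domain rendering parameters: list with
#'   `intensities` (length `C + 1`, background first), `noise_sd`
#'   (additive Gaussian, in pre-normalization intensity units), and
#'   `bias_amp` (amplitude of the smooth multiplicative bias field).
#' @return Object of class `vps_phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L, n_classes = 4L, n_slices = 200L,
                         seed = 0L,
                         domain_a = list(
                           intensities = seq(0.15, 0.95,
                                             length.out = n_classes + 1L),
                           noise_sd = 0.04, bias_amp = 0.10),
                         domain_b = list(
                           intensities = 0.97 - seq(0.12, 0.85,
                                                    length.out = n_classes + 1L),
                           noise_sd = 0.06, bias_amp = 0.20)) {
  stopifnot(image_size >= 16L, n_classes >= 1L, n_slices >= 1L,
            length(domain_a$intensities) == n_classes + 1L,
            length(domain_b$intensities) == n_classes + 1L)
  structure(list(image_size = as.integer(image_size),
                 n_classes = as.integer(n_classes),
                 n_slices = as.integer(n_slices),
                 seed = as.integer(seed),
                 domain_a = domain_a, domain_b = domain_b),
            class = "vps_phantom_spec")
}

#' @export
print.vps_phantom_spec <- function(x, ...) {
  cat("<vps_phantom_spec>", x$n_slices, "slices,",
      paste0(x$image_size, "x", x$image_size), "px,", x$n_classes,
      "foreground classes, seed", x$seed, "\n")
  invisible(x)
}

# Deterministic sub-seed below 2^31 for (seed, stream, index).
derive_seed <- function(seed, stream, index) {
  as.integer((as.double(seed) * 7919 + stream * 104729 +
                as.double(index) * 15485863) %% 2147483629)
}

#' Generate the shared label geometry of one slice
#'
#' Places up to `C` mutually disjoint smooth blobs (random ellipses with
#' low-order boundary jitter) on background. Each class is present with
#' probability 0.9 (organs are absent from some slices of a scan), so every
#' class appears in well over 80% of slices. Deterministic in
#' `(spec$seed, index)`.
#'
#' @param spec A `vps_phantom_spec`.
#' @param index Slice index (1-based).
#' @return Integer label matrix, values in `0..C`.
#' @export
generate_anatomy <- function(spec, index) {
  stopifnot(inherits(spec, "vps_phantom_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, 1L, index))
  s <- spec$image_size
  lab <- matrix(0L, s, s)
  gx <- matrix(rep(seq_len(s), each = s) / s, s, s)   # column coord
  gy <- matrix(rep(seq_len(s), times = s) / s, s, s)  # row coord
  for (cc in seq_len(spec$n_classes)) {
    if (stats::runif(1) > 0.9) next
    placed <- FALSE
    for (try in seq_len(60L)) {
      cx <- stats::runif(1, 0.18, 0.82)
      cy <- stats::runif(1, 0.18, 0.82)
      ra <- stats::runif(1, 0.07, 0.15)
      rb <- stats::runif(1, 0.07, 0.15)
      phi <- stats::runif(1, 0, pi)
      a1 <- stats::runif(1, 0, 0.12); p1 <- stats::runif(1, 0, 2 * pi)
      a2 <- stats::runif(1, 0, 0.08); p2 <- stats::runif(1, 0, 2 * pi)
      u <- (gx - cx) * cos(phi) + (gy - cy) * sin(phi)
      v <- -(gx - cx) * sin(phi) + (gy - cy) * cos(phi)
      rho <- sqrt((u / ra)^2 + (v / rb)^2)
      t <- atan2(v, u)
      inside <- rho <= 1 + a1 * sin(2 * t + p1) + a2 * sin(3 * t + p2)
      if (!any(inside & lab != 0L)) {
        lab[inside] <- cc
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", spec$n_classes,
           " disjoint blobs after bounded retries (slice ", index, ")",
           call. = FALSE)
    }
  }
  lab
}

# Smooth random field in [-1, 1]: bilinear upsampling of a coarse grid.
smooth_field <- function(s, coarse = 5L) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  pos <- seq(1, coarse, length.out = s)
  i0 <- pmin(floor(pos), coarse - 1L); fi <- pos - i0
  f <- outer(seq_len(s), seq_len(s), function(r, c) {
    r0 <- i0[r]; c0 <- i0[c]; fr <- fi[r]; fc <- fi[c]
    g[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      g[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
      g[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
      g[cbind(r0 + 1L, c0 + 1L)] * fr * fc
  })
  f / max(abs(f))
}

#' Render one slice in one domain
#'
#' Per-class base intensity, times a smooth multiplicative bias field,
#' plus additive Gaussian noise, then z-scored to zero mean / unit
#' variance.
#'
#' @param mask Integer label matrix from [generate_anatomy()].
#' @param domain Domain parameter list (see [phantom_spec()]).
#' @param seed Seed for the noise and bias field.
#' @param normalize Z-score the slice (default TRUE).
#' @return Numeric matrix of intensities.
#' @export
render_domain <- function(mask, domain, seed = 0L, normalize = TRUE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  s <- nrow(mask)
  img <- matrix(domain$intensities[mask + 1L], s, s)
  if (domain$bias_amp > 0) {
    img <- img * (1 + domain$bias_amp * smooth_field(s))
  }
  if (domain$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(s * s, sd = domain$noise_sd), s, s)
  }
  if (normalize) {
    sd0 <- stats::sd(as.vector(img)) * sqrt((s * s - 1) / (s * s))
    img <- (img - mean(img)) / max(sd0, 1e-12)
  }
  img
}

#' Generate the full two-domain phantom dataset in memory
#'
#' @param spec A `vps_phantom_spec`.
#' @return Object of class `vps_phantom`: `labels` (`H x W x N` integer),
#'   `images_a`, `images_b` (`H x W x N` numeric, z-scored per slice), and
#'   the spec.
#' @export
phantom_dataset <- function(spec) {
  stopifnot(inherits(spec, "vps_phantom_spec"))
  s <- spec$image_size; n <- spec$n_slices
  labels <- array(0L, c(s, s, n))
  a <- array(0, c(s, s, n))
  b <- array(0, c(s, s, n))
  for (i in seq_len(n)) {
    m <- generate_anatomy(spec, i)
    labels[, , i] <- m
    a[, , i] <- render_domain(m, spec$domain_a, derive_seed(spec$seed, 2L, i))
    b[, , i] <- render_domain(m, spec$domain_b, derive_seed(spec$seed, 3L, i))
  }
  structure(list(labels = labels, images_a = a, images_b = b, spec = spec),
            class = "vps_phantom")
}

#' @export
print.vps_phantom <- function(x, ...) {
  print(x$spec)
  invisible(x)
}
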