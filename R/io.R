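# Readers/writers for the formats the pipeline touches: 16-bit grayscale
# PNG images, 8-bit label PNGs, NIfTI volumes (sliced along the last axis,
# z-scored per volume), YAML configs/manifests, and RDS checkpoints.

# ---- low-level PNG helpers ----------------------------------------------
# png::readPNG reads 16-bit grayscale, but png::writePNG emits 8-bit only,
# so images are written by a minimal 16-bit encoder. memCompress's "gzip"
# type yields a zlib stream, which is exactly what an IDAT chunk holds;
# only the chunk CRC32 is computed here (table-driven, unsigned 32-bit
# semantics via R's bitwNNN functions).

.crc_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    cc <- n
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) != 0L) {
        bitwXor(bitwShiftR(cc, 1L), -306674912L)  # 0xEDB88320 as signed
      } else {
        bitwShiftR(cc, 1L)
      }
    }
    tab[n + 1L] <- cc
  }
  tab
})

crc32_raw <- function(bytes) {
  cc <- -1L
  for (b in as.integer(bytes)) {
    cc <- bitwXor(bitwShiftR(cc, 8L),
                  .crc_table[bitwAnd(bitwXor(cc, b), 255L) + 1L])
  }
  cc <- bitwXor(cc, -1L)
  u <- if (cc < 0) as.double(cc) + 4294967296 else as.double(cc)
  be32(u)                                   # big-endian for PNG chunks
}

zlib_stream <- function(bytes) {
  memCompress(bytes, type = "gzip")
}

be32 <- function(x) {
  x <- as.double(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(be32(length(data)), body, crc32_raw(body))
}

#' Write a 16-bit grayscale PNG
#'
#' @param img Numeric matrix with values in `[0, 1]` (quantized to 16 bits).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_png16 <- function(img, path) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (min(img) < 0 || max(img) > 1) stop("values must be in [0, 1]",
                                         call. = FALSE)
  v <- round(img * 65535)
  h <- nrow(img); w <- ncol(img)
  # scanlines: filter byte 0 + big-endian uint16 per pixel, row by row
  hi <- as.raw(t(v) %/% 256)
  lo <- as.raw(t(v) %% 256)
  px <- as.raw(rbind(hi, lo))              # interleave hi/lo per pixel
  dim(px) <- NULL
  rows <- matrix(px, nrow = 2L * w)
  raw_data <- as.raw(rbind(matrix(as.raw(0), 1L, h), rows))  # filter byte 0
  dim(raw_data) <- NULL
  ihdr <- c(be32(w), be32(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_stream(raw_data)),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

#' Write an integer label mask as an 8-bit PNG
#'
#' Class indices are stored directly as 8-bit gray levels, so the round
#' trip through [read_label_png()] is exact for up to 255 classes.
#'
#' @param labels Integer matrix, values in `0..255`.
#' @param path Output file.
#' @export
write_label_png <- function(labels, path) {
  stopifnot(all(labels == round(labels)), min(labels) >= 0,
            max(labels) <= 255)
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Read an integer label mask from an 8-bit PNG
#' @param path PNG file written by [write_label_png()].
#' @return Integer matrix of class indices.
#' @export
read_label_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  m <- round(v * 255)
  storage.mode(m) <- "integer"
  m
}

zscore <- function(x) {
  n <- length(x)
  sd0 <- stats::sd(as.vector(x)) * sqrt((n - 1) / n)
  (x - mean(x)) / max(sd0, 1e-12)
}

#' Read an image stack from PNG slices or a NIfTI volume
#'
#' PNG: each file is one slice, min-max stored in `[0, 1]`; each slice is
#' z-scored on read (z-scoring is invariant to the affine storage map).
#' NIfTI: the volume is sliced along the last axis and z-scored *per
#' volume*, following the convention that normalization statistics come
#' from the whole scan.
#'
#' @param path Directory of `.png` slices, or a `.nii`/`.nii.gz` file.
#' @param format `"png"` or `"nifti"` (guessed from `path` by default).
#' @return Numeric `H x W x N` array of normalized slices.
#' @export
read_images <- function(path, format = c("auto", "png", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "png"
  }
  if (format == "nifti") {
    if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
    vol <- RNifti::readNifti(path)
    vol <- zscore(array(as.vector(vol), dim(vol)))     # per volume
    if (length(dim(vol)) == 2) dim(vol) <- c(dim(vol), 1L)
    return(vol)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG slices under ", path, call. = FALSE)
  slices <- lapply(files, function(f) {
    v <- png::readPNG(f)
    if (length(dim(v)) == 3) v <- v[, , 1]
    zscore(v)
  })
  array(unlist(slices), c(dim(slices[[1]]), length(slices)))
}

#' Write a phantom dataset to disk
#'
#' Writes one image and one label file per slice and domain
#' (`domain_A/images/slice_0001.png`, ... for `format = "png"`; one
#' NIfTI volume per domain otherwise) plus a `manifest.yaml` recording the
#' spec and per-file CRC32 checksums. Label files are shared geometry:
#' identical across domains.
#'
#' @param spec A `vps_phantom_spec` (or a `vps_phantom` already generated).
#' @param out_dir Output directory (created if needed).
#' @param format `"png"` or `"nifti"`.
#' @return `out_dir`, invisibly.
#' @export
make_dataset <- function(spec, out_dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  ph <- if (inherits(spec, "vps_phantom")) spec else phantom_dataset(spec)
  spec <- ph$spec
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if (format == "png") {
    for (dom in c("A", "B")) {
      imdir <- file.path(out_dir, paste0("domain_", dom), "images")
      lbdir <- file.path(out_dir, paste0("domain_", dom), "labels")
      dir.create(imdir, recursive = TRUE, showWarnings = FALSE)
      dir.create(lbdir, recursive = TRUE, showWarnings = FALSE)
      imgs <- if (dom == "A") ph$images_a else ph$images_b
      for (i in seq_len(spec$n_slices)) {
        sl <- imgs[, , i]
        sl <- (sl - min(sl)) / max(max(sl) - min(sl), 1e-12)
        f1 <- file.path(imdir, sprintf("slice_%04d.png", i))
        write_png16(sl, f1)
        f2 <- file.path(lbdir, sprintf("slice_%04d.png", i))
        write_label_png(ph$labels[, , i], f2)
        files <- c(files, f1, f2)
      }
    }
  } else {
    for (dom in c("A", "B")) {
      imgs <- if (dom == "A") ph$images_a else ph$images_b
      f1 <- file.path(out_dir, paste0("domain_", dom, ".nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(imgs), f1)
      f2 <- file.path(out_dir, paste0("domain_", dom, "_labels.nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(ph$labels + 0), f2)
      files <- c(files, f1, f2)
    }
  }
  sums <- vapply(files, function(f) {
    paste(format(as.integer(crc32_raw(readBin(f, "raw",
                                              file.info(f)$size)))),
          collapse = ".")
  }, character(1))
  manifest <- list(
    spec = list(image_size = spec$image_size, n_classes = spec$n_classes,
                n_slices = spec$n_slices, seed = spec$seed,
                domain_a = spec$domain_a, domain_b = spec$domain_b),
    format = format,
    checksums = as.list(stats::setNames(sums,
                                        sub(paste0("^", out_dir, "/?"), "",
                                            files)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

# ---- checkpoints and configs --------------------------------------------

#' Save / load a model or alignment-model checkpoint
#'
#' Checkpoints are RDS files holding the full object (parameters, BN
#' running statistics, architecture name and class count).
#'
#' @param object A `vps_model`, `vps_am`, or `vps_agnostic_prompt`.
#' @param path File path.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, c("vps_model", "vps_am",
                               "vps_agnostic_prompt")))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("missing checkpoint: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!inherits(obj, c("vps_model", "vps_am", "vps_agnostic_prompt"))) {
    stop("not a recognized checkpoint: ", path, call. = FALSE)
  }
  obj
}

#' Default run configuration
#'
#' `scale = "desk"` are the settings used throughout the package's tests
#' and examples (tiny backbone, 64x64 phantoms, Adam lr 1e-3).
#' `scale = "full"` records the full-scale convention for real
#' cross-modality data: batch 4, Adam with learning rate 3e-5 and weight
#' decay 3e-5, inputs resized to 256x256 by bilinear interpolation
#' (images; labels nearest-neighbour), DeepLab-class backbone slot.
#'
#' @param scale `"desk"` or `"full"`.
#' @return Nested configuration list.
#' @export
vps_config <- function(scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(
      backbone = list(arch = "deeplabv3-resnet50", num_classes = 4L,
                      epochs = 100L, batch_size = 4L, lr = 3e-5,
                      weight_decay = 3e-5, seed = 0L,
                      augment = TRUE,
                      resize = list(size = c(256L, 256L),
                                    image_interp = "bilinear",
                                    label_interp = "nearest")),
      prompt = list(blocks = 5L, code_dim = 1024L, widths = 16L,
                    eps = 1e-8, mode = "specific"),
      bnc = list(channel_agg = "mean", layers = NULL, epochs = 2L,
                 batch_size = 4L, lr = 3e-5),
      denoise = list(k = 0.33, k_mode = "fraction", lambda = 0.75),
      adapt = list(epochs = 2L, batch_size = 4L, lr = 3e-5,
                   weight_decay = 3e-5),
      seed = 0L
    )
  } else {
    list(
      backbone = list(arch = "tiny", num_classes = 4L, epochs = 8L,
                      batch_size = 4L, lr = 1e-3, weight_decay = 0,
                      seed = 0L, augment = FALSE),
      prompt = list(blocks = 5L, code_dim = 1024L, widths = 16L,
                    eps = 1e-8, mode = "specific"),
      bnc = list(channel_agg = "mean", layers = NULL, epochs = 2L,
                 batch_size = 4L, lr = 1e-3),
      denoise = list(k = 0.33, k_mode = "fraction", lambda = 0.75),
      adapt = list(epochs = 2L, batch_size = 4L, lr = 1e-3,
                   weight_decay = 0),
      seed = 0L
    )
  }
}

#' @rdname vps_config
#' @param config Configuration list.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname vps_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("missing config: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
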