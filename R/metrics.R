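# Segmentation evaluation: per-class Dice overlap and average surface
# distance (ASD). Surface pixels are foreground pixels 4-connected to
# background (or to the image border); distances are Euclidean between
# pixel centers, scaled by the physical pixel spacing.

#' Dice coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty (perfect agreement on absence).
#'
#' @param pred,gt Logical/0-1 matrices of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch", call. = FALSE)
  a <- pred != 0; b <- gt != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Surface (boundary) pixel coordinates of a binary mask: foreground pixels
# with at least one 4-neighbour outside the mask (image border counts).
surface_pixels <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)]
  nb <- pad[1:d[1], 2:(d[2] + 1L)] & pad[3:(d[1] + 2L), 2:(d[2] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2]] & pad[2:(d[1] + 1L), 3:(d[2] + 2L)]
  which(core & !nb, arr.ind = TRUE)
}

#' Average surface distance between two binary masks
#'
#' Symmetric mean of the two directed average nearest-neighbour distances
#' between the masks' surface pixel sets, in physical units (`spacing` per
#' pixel). Undefined (returns `NA`) if either mask is empty -- an absent
#' structure has no boundary, and reporting 0 would overstate agreement.
#'
#' @param pred,gt Binary matrices of identical shape.
#' @param spacing Physical pixel size, length 1 or 2 (row, column).
#' @return Scalar `>= 0`, or `NA_real_` if either mask is empty.
#' @export
average_surface_distance <- function(pred, gt, spacing = 1) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (sum(pred != 0) == 0 || sum(gt != 0) == 0) return(NA_real_)
  sa <- surface_pixels(pred)
  sb <- surface_pixels(gt)
  da <- directed_mean_dist(sa, sb, spacing)
  db <- directed_mean_dist(sb, sa, spacing)
  (da + db) / 2
}

directed_mean_dist <- function(from, to, spacing) {
  dy <- outer(from[, 1] * spacing[1], to[, 1] * spacing[1], "-")
  dx <- outer(from[, 2] * spacing[2], to[, 2] * spacing[2], "-")
  d2 <- dy * dy + dx * dx
  mean(sqrt(apply(d2, 1, min)))
}

#' Evaluate a segmentation model on labeled slices
#'
#' Predicts hard labels (optionally after prompt fusion) and reports
#' per-class Dice and ASD, averaged over the slices in which the class
#' occurs in the reference, plus foreground means.
#'
#' @param model A `vps_model`.
#' @param images `H x W x N` image stack.
#' @param labels Integer `H x W x N` reference masks.
#' @param am Optional prompt source fused before prediction.
#' @param spacing Physical pixel size.
#' @param asd Compute average surface distance as well (slower; set
#'   `FALSE` for Dice-only sweeps).
#' @return A tibble with one row per foreground class and a `"mean"` row:
#'   columns `class`, `dice`, `asd`.
#' @export
evaluate_segmentation <- function(model, images, labels, am = NULL,
                                  spacing = 1, asd = TRUE) {
  x <- as_image_stack(images)
  if (length(dim(labels)) == 2) dim(labels) <- c(dim(labels), 1L)
  stopifnot(all(dim(labels) == dim(x)[1:3]))
  pred <- predict_labels(model, array(x, dim(x)[1:3]), am = am)
  C <- model$num_classes
  n <- dim(x)[3]
  dice <- matrix(NA_real_, n, C)
  asd_mat <- matrix(NA_real_, n, C)
  for (i in seq_len(n)) {
    for (cc in seq_len(C)) {
      gt <- labels[, , i] == cc
      if (!any(gt)) next                   # class absent from this slice
      pr <- pred[, , i] == cc
      dice[i, cc] <- dice_coefficient(pr, gt)
      if (asd) asd_mat[i, cc] <- average_surface_distance(pr, gt, spacing)
    }
  }
  per_class <- tibble::tibble(
    class = as.character(seq_len(C)),
    dice = colMeans(dice, na.rm = TRUE),
    asd = colMeans(asd_mat, na.rm = TRUE)
  )
  per_class$asd[is.nan(per_class$asd)] <- NA_real_
  per_class$dice[is.nan(per_class$dice)] <- NA_real_
  rbind(per_class,
        tibble::tibble(class = "mean",
                       dice = mean(per_class$dice, na.rm = TRUE),
                       asd = mean(per_class$asd, na.rm = TRUE)))
}

#' Mean foreground Dice of a model on labeled slices
#' @inheritParams evaluate_segmentation
#' @return Scalar mean Dice over foreground classes.
#' @export
mean_dice <- function(model, images, labels, am = NULL) {
  ev <- evaluate_segmentation(model, images, labels, am = am, asd = FALSE)
  ev$dice[ev$class == "mean"]
}
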