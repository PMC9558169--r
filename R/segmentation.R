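#' @title Root segmentation: classical baseline and evaluation
#' @name segmentation
#' @description
#' Extracting roots from the cluttered soil background is the gating step of
#' the pipeline. Two segmenters are provided: a classical
#' brightness-threshold baseline ([threshold_segment()]), and a small
#' trainable encoder-decoder with atrous spatial pyramid pooling and a
#' sub-pixel (pixel-shuffle) decoder ([train_seg_model()],
#' [predict_mask()]). Masks are binary matrices with a `provenance`
#' attribute (`"classical"`, `"model"`, `"manual"` or `"truth"`).
NULL

root_mask <- function(mask, provenance) {
  mask <- as_binary_mask(mask)
  attr(mask, "provenance") <- provenance
  mask
}

#' Mask provenance
#' @param mask a binary mask produced by a segmenter.
#' @export
mask_provenance <- function(mask) attr(mask, "provenance")

grayscale <- function(image) {
  if (length(dim(image)) == 3L) (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  else image
}

#' Classical threshold segmentation of a root frame
#'
#' Deterministic baseline: the local mean brightness (large box kernel) is
#' subtracted to flatten uneven background, pixels brighter than the local
#' mean by more than `thr_offset` are kept, the result is cleaned by
#' morphological opening, and components smaller than `min_area_px` are
#' dropped. Bright roots against dark soil segment well; senescent (dark
#' brown) roots and bright mineral grains are its known failure modes — the
#' motivation for the trainable segmenter.
#'
#' @param image RGB array or grayscale matrix, values in `[0, 1]`.
#' @param flatten_kernel_px side of the local-mean kernel (odd).
#' @param thr_offset brightness excess over local mean required for
#'   foreground.
#' @param open_size diameter (px) of the opening brush; 0 disables.
#' @param min_area_px components smaller than this are removed.
#' @return binary mask with provenance `"classical"`.
#' @export
threshold_segment <- function(image, flatten_kernel_px = 41,
                              thr_offset = 0.12, open_size = 3,
                              min_area_px = 20) {
  if (length(image) == 0L) stop("empty image")
  g <- grayscale(image)
  k <- flatten_kernel_px + (flatten_kernel_px %% 2L == 0L)
  bg <- EBImage::filter2(g, matrix(1 / (k * k), k, k), boundary = "replicate")
  m <- (g - bg > thr_offset) + 0L
  if (open_size > 0 && sum(m) > 0) {
    sz <- open_size + (open_size %% 2L == 0L)
    m <- (EBImage::opening(m, EBImage::makeBrush(sz, "disc")) > 0) + 0L
  }
  if (min_area_px > 0 && sum(m) > 0) {
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area_px)
    m <- (matrix(lab, nrow(m), ncol(m)) %in% keep) + 0L
    dim(m) <- dim(g)
  }
  root_mask(m, "classical")
}

#' Segmentation quality scores
#'
#' Intersection-over-union, Dice, precision and recall of a predicted mask
#' against a reference. Two empty masks count as perfect agreement (all
#' scores 1).
#'
#' @param mask,reference binary masks of identical shape.
#' @return data.frame with `iou`, `dice`, `precision`, `recall`.
#' @export
evaluate_masks <- function(mask, reference) {
  mask <- as_binary_mask(mask); reference <- as_binary_mask(reference)
  if (!identical(dim(mask), dim(reference)))
    stop("mask shapes differ: ", paste(dim(mask), collapse = "x"), " vs ",
         paste(dim(reference), collapse = "x"))
  tp <- sum(mask == 1L & reference == 1L)
  fp <- sum(mask == 1L & reference == 0L)
  fn <- sum(mask == 0L & reference == 1L)
  if (tp + fp + fn == 0L)
    return(data.frame(iou = 1, dice = 1, precision = 1, recall = 1))
  iou <- tp / (tp + fp + fn)
  data.frame(
    iou = iou,
    dice = 2 * iou / (1 + iou),
    precision = if (tp + fp == 0L) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0L) 0 else tp / (tp + fn)
  )
}

#' Trait agreement between two sets of masks
#'
#' Reproduces, on any paired mask sets, the agreement analysis used to
#' validate automatic against manual segmentation: traits (RL, AD, RSA, RV)
#' are measured on both sets frame by frame and the per-trait coefficient of
#' determination (R^2 of the linear fit auto ~ reference) is reported.
#'
#' @param masks_auto,masks_ref lists of paired binary masks (>= 3 pairs).
#' @param calibration a [calibrate()] result.
#' @param prune_len_mm passed to [skeletonize_mask()].
#' @return list with `r2` (named vector over RL_cm, AD_mm, RSA_cm2, RV_cm3)
#'   and `traits` (long data.frame of both measurements).
#' @export
compare_trait_agreement <- function(masks_auto, masks_ref, calibration,
                                    prune_len_mm = 0.5) {
  if (length(masks_auto) != length(masks_ref))
    stop("mask lists must be paired")
  if (length(masks_auto) < 3L)
    stop("need at least 3 mask pairs for a stable R^2")
  one <- function(m) measure_traits(
    skeletonize_mask(m, calibration, prune_len_mm), calibration)
  ta <- do.call(rbind, lapply(masks_auto, one))
  tr <- do.call(rbind, lapply(masks_ref, one))
  traits <- c("RL_cm", "AD_mm", "RSA_cm2", "RV_cm3")
  r2 <- vapply(traits, function(tn) {
    a <- ta[[tn]]; b <- tr[[tn]]
    if (isTRUE(all.equal(a, b))) return(1)
    if (sd(b) == 0 || sd(a) == 0) return(NA_real_)
    summary(lm(a ~ b))$r.squared
  }, numeric(1))
  ta$set <- "auto"; tr$set <- "reference"
  ta$frame <- seq_along(masks_auto); tr$frame <- seq_along(masks_ref)
  list(r2 = r2, traits = rbind(ta, tr))
}
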