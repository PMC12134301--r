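#' Segment a kV image with the trained generator
#'
#' Runs the generator and binarises its prediction at `threshold` times the
#' output-range maximum (the generator output is bounded in \[0, 1\], so the
#' default 10% threshold is an absolute 0.1). Thresholding against the output
#' range, rather than each image's own maximum, means an all-noise prediction
#' can yield an empty mask instead of a spurious one; empty masks are allowed
#' here and flagged downstream.
#'
#' @param model a `model_artifact`.
#' @param kv a [projection_image()] or matrix, normalised like the training
#'   inputs.
#' @param threshold binarisation fraction of the output range (default 0.10).
#' @return Logical matrix (`seg_mask`).
#' @export
segment <- function(model, kv, threshold = 0.10) {
  pred <- predict_generator(model, list(kv))[[1]]
  binarise_prediction(pred, threshold)
}

#' @rdname segment
#' @param pred a raw generator prediction in \[0, 1\].
#' @export
binarise_prediction <- function(pred, threshold = 0.10) {
  pred >= threshold * 1.0
}

#' Keep only the largest 8-connected component of a mask
#'
#' Components are labelled with 8-connectivity; all but the largest (by pixel
#' count) are removed, mirroring the rule that when multiple unconnected
#' regions are detected the centroid of the largest region is used. Ties are
#' broken in favour of the component containing the smallest row-major pixel
#' index. An empty mask is returned unchanged with attribute `empty = TRUE`.
#'
#' @param mask logical matrix.
#' @return Logical matrix, with attributes `n_components` and `empty`.
#' @export
largest_component <- function(mask) {
  if (!is.logical(mask)) mask <- mask != 0
  if (!any(mask)) {
    attr(mask, "n_components") <- 0L
    attr(mask, "empty") <- TRUE
    return(mask)
  }
  lab <- .cpp_label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  # labels are assigned in row-major scan order, so which.max's first-maximum
  # rule implements the documented tie-break
  keep <- which.max(sizes)
  out <- lab == keep
  attr(out, "n_components") <- length(sizes)
  attr(out, "empty") <- FALSE
  out
}

#' Centroid of a binary mask
#'
#' Arithmetic mean of the member pixel coordinates, pixel-centre convention,
#' returned as `c(u, v)` = (column, row).
#'
#' @param mask logical matrix; must be nonempty.
#' @return Numeric `c(u, v)` in pixels.
#' @export
mask_centroid <- function(mask) {
  if (!is.logical(mask)) mask <- mask != 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("cannot compute the centroid of an empty mask")
  c(u = mean(idx[, 2]), v = mean(idx[, 1]))
}

#' Track the prostate across an arc of kV images
#'
#' Applies the inference workflow to each image: generator segmentation,
#' binarisation, largest-component selection, centroid extraction; compares
#' against the ground-truth masks and reports per-image errors in isocentre
#' mm (u error as AP/LAT, v error as SI), Dice coefficient and mean surface
#' distance. Images with an empty prediction are flagged (`dropped = TRUE`)
#' and carry `NA` metrics; summaries exclude them.
#'
#' @param model a `model_artifact`.
#' @param kv_images list of normalised kV-like images.
#' @param gt_masks list of logical ground-truth masks, aligned by angle.
#' @param geom a [beam_geometry()].
#' @param angles numeric vector of gantry angles; defaults to the images'
#'   `angle` fields.
#' @param threshold binarisation fraction (default 0.10).
#' @return Data frame of tracking records (one row per image).
#' @export
track_arc <- function(model, kv_images, gt_masks, geom, angles = NULL,
                      threshold = 0.10) {
  stopifnot(length(kv_images) == length(gt_masks))
  if (is.null(angles))
    angles <- vapply(kv_images, function(im)
      if (inherits(im, "projection_image")) im$angle else NA_real_, 0)
  preds <- predict_generator(model, kv_images)
  pitch_iso <- iso_pixel_mm(geom)
  rows <- lapply(seq_along(preds), function(i) {
    seg <- largest_component(binarise_prediction(preds[[i]], threshold))
    gm <- gt_masks[[i]]
    if (!is.logical(gm)) gm <- proj_values(gm) != 0
    gt_c <- mask_centroid(gm)
    if (attr(seg, "empty")) {
      return(data.frame(angle = angles[i], pred_u = NA_real_, pred_v = NA_real_,
                        gt_u = gt_c[1], gt_v = gt_c[2],
                        err_aplat_mm = NA_real_, err_si_mm = NA_real_,
                        dsc = NA_real_, msd_mm = NA_real_,
                        n_components = attr(seg, "n_components"),
                        dropped = TRUE))
    }
    pc <- mask_centroid(seg)
    data.frame(angle = angles[i], pred_u = pc[1], pred_v = pc[2],
               gt_u = gt_c[1], gt_v = gt_c[2],
               err_aplat_mm = pixel_to_isocentre_mm(pc[1] - gt_c[1], geom),
               err_si_mm = pixel_to_isocentre_mm(pc[2] - gt_c[2], geom),
               dsc = dice(seg, gm),
               msd_mm = mean_surface_distance(seg, gm, pitch_iso),
               n_components = attr(seg, "n_components"),
               dropped = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
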