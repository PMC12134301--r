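#' Construct a masked-style test set (markers embedded, then removed)
#'
#' Emulates the ground-truth pathway for patients with implanted fiducial
#' markers: markers are embedded in the attenuation volume, kV-like images
#' are forward-projected, the marker footprints are masked out by harmonic
#' inpainting, and Poisson noise is applied after interpolation. The
#' ground-truth masks come from the marker-free contour projections.
#'
#' @param ct planning [voxel_volume()] (without markers).
#' @param contour prostate [binary_volume()].
#' @param markers list of 3D mm marker positions.
#' @param geom a [beam_geometry()].
#' @param angles gantry angles, degrees.
#' @param marker_radius mm.
#' @param marker_attenuation 1/mm.
#' @param photons_at_max Poisson photon budget at the image maximum
#'   (`NULL` disables noise).
#' @param mask_eps contour binarisation path length, mm.
#' @param step projector ray step, mm.
#' @return `list(kv = list of projection_image, gt = list of logical masks,
#'   angles =)`. kV images are raw line integrals (normalise before
#'   inference).
#' @export
make_masked_testset <- function(ct, contour, markers, geom, angles,
                                marker_radius = 0.6, marker_attenuation = 2.0,
                                photons_at_max = 1e4, mask_eps = 0.1,
                                step = NULL) {
  ct_m <- embed_markers(ct, markers, marker_radius, marker_attenuation)
  # rasterised marker support: half a voxel diagonal plus the trilinear
  # interpolation tail, ~1.5 voxels in total
  pad <- max(ct$spacing) * 1.5
  kv <- vector("list", length(angles))
  gt <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    img <- forward_project(ct_m, geom, angles[i], step = step, kind = "kv")
    fp <- marker_footprint(markers, geom, angles[i], marker_radius,
                           voxel_pad = pad)
    img <- inpaint_regions(img, fp)
    if (!is.null(photons_at_max)) img <- add_poisson_noise(img, photons_at_max)
    kv[[i]] <- img
    gt[[i]] <- project_contour_mask(contour, geom, angles[i], mask_eps, step)
  }
  list(kv = kv, gt = gt, angles = angles)
}

#' Construct a markerless-style test set (known couch shift)
#'
#' Emulates the ground-truth pathway for patients without markers: clean
#' kV-like images are shifted in the detector frame by the projection of a
#' known 3D couch shift (via the cone-beam shift mapping at each angle), and
#' the ground-truth masks are the contour projections shifted the same way
#' (the ground truth is the average prostate location implied by the rigid
#' registration shift).
#'
#' @inheritParams make_masked_testset
#' @param shift3d `c(x, y, z)` mm couch shift.
#' @param photons_at_max Poisson photon budget (`NULL` disables noise).
#' @return `list(kv, gt, angles, shift2d)`; `shift2d` is the per-angle
#'   detector-plane shift (mm) applied.
#' @export
make_markerless_testset <- function(ct, contour, geom, angles, shift3d,
                                    photons_at_max = NULL, mask_eps = 0.1,
                                    step = NULL) {
  kv <- vector("list", length(angles))
  gt <- vector("list", length(angles))
  s2 <- matrix(0, length(angles), 2, dimnames = list(NULL, c("u", "v")))
  for (i in seq_along(angles)) {
    uv <- project_shift(shift3d, angles[i], geom)
    s2[i, ] <- uv
    img <- forward_project(ct, geom, angles[i], step = step, kind = "kv")
    img <- shift_image(img, uv)
    if (!is.null(photons_at_max)) img <- add_poisson_noise(img, photons_at_max)
    kv[[i]] <- img
    gm <- project_contour_mask(contour, geom, angles[i], mask_eps, step)
    gm_s <- shift_image(gm * 1, uv, pitch = geom$detector_pitch) > 0.5
    gt[[i]] <- gm_s
  }
  list(kv = kv, gt = gt, angles = angles, shift2d = s2)
}

#' Project a contour volume into a binary detector mask
#'
#' @param contour a [binary_volume()].
#' @param geom a [beam_geometry()].
#' @param angle degrees.
#' @param mask_eps path-length threshold, mm.
#' @param step projector ray step, mm.
#' @return Logical matrix (`nv x nu`).
#' @export
project_contour_mask <- function(contour, geom, angle, mask_eps = 0.1, step = NULL) {
  p <- forward_project(contour, geom, angle, step = step, kind = "mask")
  p$values > mask_eps
}
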