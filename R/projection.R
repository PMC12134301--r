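#' Construct a projection image
#'
#' A 2D scalar grid produced by (or emulating) the kV imager: rows index the
#' detector v axis (superior-inferior), columns the u axis (transverse).
#'
#' @param values numeric matrix (`nv x nu`), finite; non-negative for
#'   `anatomy`/`mask` kinds.
#' @param pitch detector pixel pitch, mm.
#' @param angle gantry angle, degrees.
#' @param kind one of `"anatomy"`, `"mask"`, `"kv"`.
#' @return Object of class `projection_image`.
#' @export
projection_image <- function(values, pitch, angle, kind = c("anatomy", "mask", "kv")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("projection values must be finite")
  if (kind %in% c("anatomy", "mask") && any(values < 0))
    stop(sprintf("%s projections must be non-negative", kind))
  structure(list(values = values, pitch = as.numeric(pitch),
                 angle = as.numeric(angle), kind = kind),
            class = "projection_image")
}

#' @exportS3Method base::print
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image:%s> %dx%d px @ %g mm, angle %g deg, range [%.4g, %.4g]\n",
              x$kind, nrow(x$values), ncol(x$values), x$pitch, x$angle,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Forward-project a volume into a DRR
#'
#' Computes a digitally reconstructed radiograph: each detector pixel holds
#' the line integral of attenuation (units: attenuation x mm) along the ray
#' from the point source through that pixel centre, evaluated by uniform-step
#' trilinear sampling with step size at most half the minimum voxel spacing.
#' Rays that miss the volume yield 0.
#'
#' @param volume a [voxel_volume()].
#' @param geom a [beam_geometry()].
#' @param angle gantry angle, degrees.
#' @param step sampling step along the ray, mm; default `min(spacing)/2`.
#' @param kind stored [projection_image()] kind.
#' @return A [projection_image()].
#' @export
forward_project <- function(volume, geom, angle, step = NULL, kind = "anatomy") {
  stopifnot(inherits(volume, "voxel_volume"), inherits(geom, "beam_geometry"))
  if (is.null(step)) step <- min(volume$spacing) / 2
  if (step <= 0) stop("step must be positive")
  ext <- sqrt(sum((abs(volume$origin) + dim(volume$values) * volume$spacing)^2))
  if (ext >= geom$sad)
    stop("volume does not fit between the source and the isocentre")
  img <- .cpp_forward_project(volume$values, volume$spacing, volume$origin,
                              geom$sad, geom$sid,
                              geom$detector_shape[1], geom$detector_shape[2],
                              geom$detector_pitch, angle, step)
  projection_image(img, geom$detector_pitch, angle %% 360, kind = kind)
}

#' Generate a full treatment arc of DRRs
#'
#' Forward-projects a volume at every `angle_step` degrees over a full 360
#' degree gantry rotation, yielding `360 / angle_step` images at angles
#' `0, angle_step, ..., 360 - angle_step` (a 1 degree step gives the standard
#' set of 360 images per volume).
#'
#' @inheritParams forward_project
#' @param angle_step arc step, degrees; must divide 360.
#' @param offset optional constant angular offset, degrees, added to every
#'   angle (useful for held-out arcs interleaved with a training arc).
#' @return List of [projection_image()]s.
#' @export
generate_arc <- function(volume, geom, angle_step = 1, step = NULL,
                         kind = "anatomy", offset = 0) {
  if (angle_step <= 0 || (360 %% angle_step) != 0)
    stop("angle_step must be a positive divisor of 360")
  angles <- seq(0, 360 - angle_step, by = angle_step) + offset
  lapply(angles, function(a) forward_project(volume, geom, a, step = step, kind = kind))
}

#' Min-max normalise a set of projections to [0, 1]
#'
#' Network inputs are normalised jointly over an image *set* (not per image)
#' so inter-angle intensity relationships are preserved. The range used is
#' returned (or reused, at inference time) via `range`.
#'
#' @param images list of [projection_image()]s or matrices.
#' @param range optional `c(lo, hi)` to reuse a previously computed range.
#' @return `list(images = , range = c(lo, hi))` with values clipped to [0, 1].
#' @export
normalize_projections <- function(images, range = NULL) {
  mats <- lapply(images, proj_values)
  if (is.null(range)) {
    range <- c(min(vapply(mats, min, 0)), max(vapply(mats, max, 0)))
    if (diff(range) == 0) range[2] <- range[1] + 1
  }
  scaled <- lapply(seq_along(images), function(i) {
    m <- pmin(pmax((mats[[i]] - range[1]) / (range[2] - range[1]), 0), 1)
    replace_values(images[[i]], m)
  })
  list(images = scaled, range = range)
}

proj_values <- function(x) if (inherits(x, "projection_image")) x$values else x

replace_values <- function(x, m) {
  if (inherits(x, "projection_image")) {
    x$values <- m
    x
  } else m
}
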