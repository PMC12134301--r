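#' Rotational cone-beam geometry
#'
#' Describes the source-detector assembly of a linac on-board kV imager:
#' source-axis distance SAD (source to isocentre, mm), source-imager distance
#' SID (source to detector plane, mm), detector grid and pixel pitch. The
#' gantry angle theta rotates the assembly in the axial (x-z) plane about the
#' patient superior-inferior axis; at theta = 0 the source lies on the +x
#' axis. The geometric magnification between the isocentre plane and detector
#' is M = SID/SAD (1.5 for the standard SAD 1000 mm / SID 1500 mm setup).
#'
#' @param sad source-axis (isocentre) distance, mm.
#' @param sid source-imager distance, mm; must satisfy `sid >= sad > 0`.
#' @param detector_shape integer length-2, detector pixels as `c(nu, nv)`
#'   (u = transverse/lateral columns, v = superior-inferior rows).
#' @param detector_pitch detector pixel size, mm per pixel. The default
#'   0.39 mm corresponds to a 0.26 mm pixel rescaled to the isocentre plane at
#'   magnification 1.5.
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(sad = 1000, sid = 1500,
                          detector_shape = c(512L, 512L),
                          detector_pitch = 0.39) {
  sad <- as.numeric(sad); sid <- as.numeric(sid)
  detector_shape <- as.integer(detector_shape)
  detector_pitch <- as.numeric(detector_pitch)
  if (!(sad > 0 && sid >= sad)) stop("geometry invariant violated: need SID >= SAD > 0")
  if (detector_pitch <= 0) stop("geometry invariant violated: detector_pitch must be > 0")
  if (length(detector_shape) != 2L || any(detector_shape < 1L))
    stop("detector_shape must be two positive pixel counts c(nu, nv)")
  structure(list(sad = sad, sid = sid, detector_shape = detector_shape,
                 detector_pitch = detector_pitch),
            class = "beam_geometry")
}

#' @exportS3Method base::print
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> SAD %g mm, SID %g mm (M = %.3g), detector %dx%d px @ %g mm\n",
              x$sad, x$sid, x$sid / x$sad, x$detector_shape[1], x$detector_shape[2],
              x$detector_pitch))
  invisible(x)
}

#' Map a 3D shift into the 2D detector frame
#'
#' Projects a rigid 3D patient/couch shift `(x, y, z)` mm (x lateral, y
#' superior-inferior, z anterior-posterior) into the detector coordinates
#' `(u, v)` mm at gantry angle theta:
#' \deqn{(u, v) = \frac{SID}{SAD - (x\cos\theta + z\sin\theta)}
#'   \,(x\sin\theta - z\cos\theta,\; y)}
#' The returned shift is in the detector plane (magnified); rescale with
#' [pixel_to_isocentre_mm()] to express it at the isocentre. Motion along the
#' beam axis produces no detector displacement.
#'
#' @param shift numeric length-3, mm.
#' @param angle gantry angle theta, degrees.
#' @param geom a [beam_geometry()].
#' @return Named numeric `c(u =, v =)`, mm in the detector plane.
#' @export
project_shift <- function(shift, angle, geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  shift <- as.numeric(shift)
  if (length(shift) != 3L || any(!is.finite(shift))) stop("shift must be 3 finite mm values")
  t <- angle * pi / 180
  along <- shift[1] * cos(t) + shift[3] * sin(t)
  if (abs(along) >= geom$sad)
    stop("shift places the point at or behind the x-ray source")
  f <- geom$sid / (geom$sad - along)
  c(u = f * (shift[1] * sin(t) - shift[3] * cos(t)), v = f * shift[2])
}

#' Rescale a detector-plane measurement to the isocentre plane
#'
#' Multiplies a detector measurement in pixels by the pixel pitch and divides
#' by the magnification SID/SAD, giving mm at the isocentre. With the standard
#' ratio 1.5 and a 0.39 mm detector pixel this yields the 0.26 mm isocentre
#' pixel used to report tracking errors in patient coordinates.
#'
#' @param value_px measurement in detector pixels (may be fractional/vector).
#' @param geom a [beam_geometry()].
#' @return mm at the isocentre plane.
#' @export
pixel_to_isocentre_mm <- function(value_px, geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  value_px * geom$detector_pitch * geom$sad / geom$sid
}

# isocentre-plane pixel size, mm
iso_pixel_mm <- function(geom) geom$detector_pitch * geom$sad / geom$sid
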