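#' Harmonic (Laplace/Dirichlet) inpainting of masked image regions
#'
#' Replaces the pixels under `mask` by the solution of the discrete Laplace
#' equation with Dirichlet boundary values taken from the adjacent unmasked
#' pixels: each filled pixel equals the mean of its 4-neighbours, i.e. values
#' are smoothly interpolated inwards from the surrounding pixels. This is the
#' standard approach for masking out fiducial markers in radiographs without
#' leaving a visible footprint. Pixels outside the mask are untouched.
#'
#' The sparse symmetric positive-definite system is solved directly
#' (Cholesky, via the Matrix package); the residual is verified against
#' `tol * max(|image|)`.
#'
#' @param image a [projection_image()] or numeric matrix.
#' @param mask logical matrix of the same shape; must not touch the image
#'   border (the boundary condition would be undefined).
#' @param tol relative residual tolerance of the solve.
#' @return Same type as `image`, with masked pixels filled.
#' @export
inpaint_regions <- function(image, mask, tol = 1e-6) {
  vals <- proj_values(image)
  if (!is.logical(mask)) mask <- mask != 0
  if (!identical(dim(vals), dim(mask))) stop("mask shape must match the image")
  if (!any(mask)) return(image)
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)]))
    stop("mask touches the image border; Dirichlet boundary condition undefined")
  filled <- solve_dirichlet(vals, mask, tol)
  replace_values(image, filled)
}

# Solve the discrete Laplace equation on masked pixels of a 2D/3D array.
# For every masked cell: degree * u_i - sum(masked neighbours) = sum(boundary
# values); degree = number of in-grid neighbours (all masked cells are
# interior here, so degree = 4 in 2D, 6 in 3D).
solve_dirichlet <- function(vals, mask, tol = 1e-6) {
  dm <- dim(vals)
  nd <- length(dm)
  idx <- which(mask)
  n <- length(idx)
  id_of <- array(0L, dm)
  id_of[idx] <- seq_len(n)
  # offsets of axis-aligned neighbours in linear index units
  strides <- cumprod(c(1, dm[-nd]))
  offs <- c(strides, -strides)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  b <- numeric(n)
  deg <- rep(2 * nd, n)
  ar <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nd)) {
    for (sgn in c(-1L, 1L)) {
      # neighbour along axis k; mask never touches the border, so always in-grid
      nb <- idx + sgn * strides[k]
      inm <- mask[nb]
      ii <- c(ii, seq_len(n)[inm])
      jj <- c(jj, id_of[nb[inm]])
      xx <- c(xx, rep(-1, sum(inm)))
      b[!inm] <- b[!inm] + vals[nb[!inm]]
    }
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                            x = c(deg, xx), dims = c(n, n))
  u <- as.numeric(Matrix::solve(A, b))
  res <- max(abs(A %*% u - b))
  scale <- max(abs(vals), 1e-12)
  if (res > tol * scale)
    stop(sprintf("Dirichlet solve residual %.3g exceeds tolerance", res))
  out <- vals
  out[idx] <- u
  out
}

#' Apply Poisson (photon-counting) noise to a projection image
#'
#' Rescales the image so its maximum corresponds to `photons_at_max` expected
#' photon counts, draws Poisson counts per pixel, and scales back:
#' `p -> Poisson(p / max * photons_at_max) * max / photons_at_max`. Relative
#' noise therefore shrinks as the photon budget grows; zero pixels stay zero.
#'
#' @param image non-negative [projection_image()] or matrix.
#' @param photons_at_max expected photon count at the image maximum (> 0).
#' @return Same type as `image`, with noise applied.
#' @export
add_poisson_noise <- function(image, photons_at_max = 1e4) {
  vals <- proj_values(image)
  if (any(vals < 0)) stop("image must be non-negative for Poisson noise")
  if (photons_at_max <= 0) stop("photons_at_max must be > 0")
  mx <- max(vals)
  if (mx == 0) return(image)
  counts <- stats::rpois(length(vals), vals / mx * photons_at_max)
  noisy <- matrix(counts * mx / photons_at_max, nrow(vals), ncol(vals))
  replace_values(image, noisy)
}

#' Shift a 2D image by a detector-frame displacement
#'
#' Translates the image by `shift = c(u, v)` mm in detector coordinates
#' (converted to pixels via the pitch), with bilinear interpolation and zero
#' fill. Used to impose a known couch shift on kV-like images when building
#' the markerless-style ground truth.
#'
#' @param image a [projection_image()] or matrix.
#' @param shift `c(u, v)` mm at the detector plane (u = columns, v = rows).
#' @param pitch mm per pixel; taken from the image when available.
#' @return Shifted image of the same type.
#' @export
shift_image <- function(image, shift, pitch = NULL) {
  vals <- proj_values(image)
  if (is.null(pitch))
    pitch <- if (inherits(image, "projection_image")) image$pitch else 1
  shift <- as.numeric(shift)
  if (length(shift) != 2L || any(!is.finite(shift))) stop("shift must be c(u, v) mm")
  px <- shift / pitch
  if (any(abs(px) >= dim(vals)[2:1]))
    stop("shift exceeds the image extent")
  out <- .cpp_shift_image(vals, px[1], px[2])
  replace_values(image, out)
}

#' Mask out 3D marker regions by harmonic infill
#'
#' 3D analogue of [inpaint_regions()]: voxels within `radius` of a marker
#' centre are replaced by the solution of the 3D discrete Laplace equation
#' (6-neighbour stencil) with Dirichlet boundary values from the surrounding
#' voxels, removing the markers from the planning volume without disturbing
#' any other voxel.
#'
#' @param volume a [voxel_volume()].
#' @param markers list of 3D mm points.
#' @param radius mm; the masked region is all voxels with centres within
#'   `radius` of any marker (at minimum the voxel containing the centre).
#' @param tol relative residual tolerance of the solve.
#' @return A [voxel_volume()] with markers removed.
#' @export
mask_markers_3d <- function(volume, markers, radius = 0.6, tol = 1e-6) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (length(markers) == 0) return(volume)
  mask <- marker_voxel_mask(volume, markers, radius)
  dm <- dim(volume$values)
  border <- array(FALSE, dm)
  border[c(1, dm[1]), , ] <- TRUE; border[, c(1, dm[2]), ] <- TRUE
  border[, , c(1, dm[3])] <- TRUE
  if (any(mask & border))
    stop("marker region touches the volume boundary; Dirichlet condition undefined")
  out <- solve_dirichlet(volume$values, mask, tol)
  voxel_volume(out, volume$spacing, volume$origin, nonneg = FALSE)
}

# boolean voxel mask covering spheres around marker centres (plus the voxel
# holding each centre, mirroring embed_markers)
marker_voxel_mask <- function(volume, markers, radius) {
  dm <- dim(volume$values)
  lo <- volume$origin
  hi <- lo + (dm - 1) * volume$spacing
  mask <- array(FALSE, dm)
  for (m in markers) {
    m <- as.numeric(m)
    if (any(m < lo) || any(m > hi)) stop("marker outside the volume grid")
    i0 <- pmax(1L, floor((m - radius - lo) / volume$spacing) + 1L)
    i1 <- pmin(dm, ceiling((m + radius - lo) / volume$spacing) + 1L)
    ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
    cx <- lo[1] + (ix - 1) * volume$spacing[1]
    cy <- lo[2] + (iy - 1) * volume$spacing[2]
    cz <- lo[3] + (iz - 1) * volume$spacing[3]
    d2 <- outer(outer((cx - m[1])^2, (cy - m[2])^2, `+`), (cz - m[3])^2, `+`)
    mask[ix, iy, iz] <- mask[ix, iy, iz] | (d2 <= radius^2)
    idx <- pmin(pmax(round((m - lo) / volume$spacing) + 1L, 1L), dm)
    mask[idx[1], idx[2], idx[3]] <- TRUE
  }
  mask
}

#' 2D marker footprint in a projection
#'
#' Projects marker spheres through the beam geometry at a given angle and
#' returns the pixel mask of their footprints, dilated by one pixel, for use
#' with [inpaint_regions()]. With the phantom, marker geometry is known
#' exactly, so no image-based marker detection is needed.
#'
#' @param markers list of 3D mm points.
#' @param geom a [beam_geometry()].
#' @param angle gantry angle, degrees.
#' @param radius marker radius, mm.
#' @param dilate extra pixels of dilation around the projected disc.
#' @param voxel_pad extra mm added to the radius before projection. When the
#'   marker has been embedded into a voxel grid, its rasterised support
#'   extends up to half a voxel diagonal beyond the sphere; pass
#'   `max(spacing) * sqrt(3) / 2` to cover it (done automatically by
#'   [make_masked_testset()]).
#' @return Logical matrix (`nv x nu`).
#' @export
marker_footprint <- function(markers, geom, angle, radius = 0.6, dilate = 1L,
                             voxel_pad = 0) {
  nu <- geom$detector_shape[1]; nv <- geom$detector_shape[2]
  mask <- matrix(FALSE, nv, nu)
  for (m in markers) {
    uv <- project_shift(as.numeric(m), angle, geom)  # detector-plane mm
    mag <- geom$sid / geom$sad
    r_det <- (radius + voxel_pad) * mag  # projected radius at the detector
    cu <- uv[1] / geom$detector_pitch + (nu + 1) / 2
    cv <- uv[2] / geom$detector_pitch + (nv + 1) / 2
    r_px <- r_det / geom$detector_pitch + dilate
    iu <- seq_len(nu); iv <- seq_len(nv)
    d2 <- outer((iv - cv)^2, (iu - cu)^2, `+`)
    mask <- mask | (d2 <= max(r_px, 1)^2)
  }
  mask
}
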