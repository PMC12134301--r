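#' Specify a synthetic digital-pelvis phantom
#'
#' The phantom emulates the planning data the tracking pipeline consumes: a
#' pelvis-like attenuation volume (soft-tissue body ellipsoid, higher-attenuation
#' bone structures, an ellipsoidal prostate) plus the matching binary prostate
#' contour and, optionally, implanted high-attenuation fiducial markers. All
#' geometry is known analytically, so downstream stages can be verified against
#' ground truth.
#'
#' Attenuations are linear attenuation coefficients in consistent 1/mm units
#' (the projector only needs line integrals, so no Hounsfield calibration is
#' involved). The invariants `marker > bone > soft > 0` are enforced. The
#' default prostate attenuation is deliberately elevated well above soft
#' tissue so that the prostate is radiographically visible in the synthetic
#' projections: the phantom exists to verify the pipeline's mechanics at desk
#' scale, and a clearly learnable target keeps short training schedules
#' meaningful. Real kV images have far lower soft-tissue contrast; see the
#' package vignette for what this does and does not demonstrate.
#'
#' @param grid_shape integer length-3, voxels per axis (x, y, z).
#' @param voxel_spacing numeric length-3, mm per voxel per axis.
#' @param prostate_center,prostate_semiaxes mm, centre and semi-axes of the
#'   prostate ellipsoid (isocentre frame).
#' @param body_semiaxes mm, semi-axes of the body ellipsoid (centred on the
#'   isocentre).
#' @param bone_descriptors list of `list(center=, semiaxes=, attenuation=)`
#'   ellipsoids standing in for femoral heads / sacrum.
#' @param tissue_attenuations named list with entries `soft`, `prostate`,
#'   `bone` (default for bones without their own value) and `marker` (1/mm).
#' @param marker_positions list of 3D mm points (possibly empty); must lie
#'   inside the prostate ellipsoid.
#' @param marker_radius mm, radius of the spherical marker model.
#' @param texture_sd relative SD of the seeded Gaussian soft-tissue texture,
#'   as a fraction of the soft-tissue attenuation (clipped at zero).
#' @return A validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         voxel_spacing = c(4, 4, 4),
                         prostate_center = c(5, 8, -6),
                         prostate_semiaxes = c(20, 15, 18),
                         body_semiaxes = c(85, 90, 75),
                         bone_descriptors = default_bones(),
                         tissue_attenuations = list(soft = 0.020,
                                                    prostate = 0.045,
                                                    bone = 0.060,
                                                    marker = 2.0),
                         marker_positions = list(),
                         marker_radius = 0.6,
                         texture_sd = 0.02) {
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         voxel_spacing = as.numeric(voxel_spacing),
                         prostate_center = as.numeric(prostate_center),
                         prostate_semiaxes = as.numeric(prostate_semiaxes),
                         body_semiaxes = as.numeric(body_semiaxes),
                         bone_descriptors = bone_descriptors,
                         tissue_attenuations = tissue_attenuations,
                         marker_positions = marker_positions,
                         marker_radius = as.numeric(marker_radius),
                         texture_sd = as.numeric(texture_sd)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @export
default_bones <- function() {
  list(list(center = c(-65, 0, 5), semiaxes = c(16, 45, 20), attenuation = 0.060),
       list(center = c(65, 0, 5), semiaxes = c(16, 45, 20), attenuation = 0.060),
       list(center = c(0, 0, 48), semiaxes = c(18, 60, 14), attenuation = 0.055))
}

inside_ellipsoid <- function(p, center, semiaxes) {
  sum(((p - center) / semiaxes)^2) < 1
}

validate_phantom_spec <- function(spec) {
  mu <- spec$tissue_attenuations
  for (nm in c("soft", "prostate", "bone", "marker"))
    if (is.null(mu[[nm]])) stop(sprintf("tissue_attenuations$%s missing", nm))
  if (any(unlist(mu) < 0)) stop("invariant violated: all attenuations must be >= 0")
  if (!(mu$marker > mu$bone && mu$bone > mu$soft && mu$soft > 0))
    stop("invariant violated: marker > bone > soft-tissue attenuation > 0 required")
  if (any(spec$voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  if (any(spec$grid_shape < 2L)) stop("grid_shape must be at least 2 per axis")
  # prostate strictly inside body: check surface points sampled over directions
  dirs <- fibonacci_sphere(200L)
  surf <- sweep(sweep(dirs, 2, spec$prostate_semiaxes, `*`), 2,
                spec$prostate_center, `+`)
  q <- rowSums(sweep(surf, 2, spec$body_semiaxes, `/`)^2)
  if (any(q >= 1))
    stop("invariant violated: prostate ellipsoid must lie strictly inside the body ellipsoid")
  for (m in spec$marker_positions)
    if (!inside_ellipsoid(as.numeric(m), spec$prostate_center, spec$prostate_semiaxes))
      stop("invariant violated: markers must lie inside the prostate ellipsoid")
  invisible(spec)
}

# evenly distributed unit directions (Fibonacci lattice on the sphere)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a phantom volume pair from a specification
#'
#' Builds the attenuation volume and the binary prostate contour on a shared
#' grid centred on the isocentre. The contour is exactly the set of voxels
#' whose centres lie inside the prostate ellipsoid. Attenuation is assigned by
#' tissue class (air outside the body, soft tissue inside, bone ellipsoids,
#' prostate), then mild seeded Gaussian texture is added to body soft tissue so
#' that flat regions are not trivially memorable. Markers are *not* embedded
#' here; see [embed_markers()].
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed controlling the texture noise (bit-identical
#'   volumes for equal seeds).
#' @return `list(ct = voxel_volume, contour = binary_volume, markers = list)`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  dm <- spec$grid_shape
  sp <- spec$voxel_spacing
  origin <- -(dm - 1) / 2 * sp
  xs <- origin[1] + (seq_len(dm[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(dm[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(dm[3]) - 1) * sp[3]
  # squared normalized coordinates, broadcast over the grid
  quad <- function(center, semi) {
    qx <- ((xs - center[1]) / semi[1])^2
    qy <- ((ys - center[2]) / semi[2])^2
    qz <- ((zs - center[3]) / semi[3])^2
    outer(outer(qx, qy, `+`), qz, `+`)
  }
  mu <- spec$tissue_attenuations
  body <- quad(c(0, 0, 0), spec$body_semiaxes) < 1
  vals <- array(0, dm)
  vals[body] <- mu$soft
  for (b in spec$bone_descriptors) {
    att <- if (is.null(b$attenuation)) mu$bone else b$attenuation
    inb <- quad(as.numeric(b$center), as.numeric(b$semiaxes)) < 1
    vals[inb] <- pmax(vals[inb], att)
  }
  pro <- quad(spec$prostate_center, spec$prostate_semiaxes) < 1
  vals[pro] <- mu$prostate
  if (spec$texture_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
    noise <- array(stats::rnorm(prod(dm), sd = spec$texture_sd * mu$soft), dm)
    soft_only <- body & !pro & vals <= mu$soft
    vals[soft_only] <- pmax(vals[soft_only] + noise[soft_only], 0)
  }
  ct <- voxel_volume(vals, sp, origin)
  contour <- binary_volume(array(as.double(pro), dm), sp, origin)
  list(ct = ct, contour = contour, markers = spec$marker_positions)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Embed spherical fiducial markers into a volume
#'
#' Voxels whose centres lie within `radius` of a marker centre are raised to
#' the marker attenuation (`max(existing, attenuation)`); all other voxels are
#' untouched, so the operation is idempotent. Markers are modelled as spheres;
#' the masking/inpainting logic downstream is orientation-agnostic.
#'
#' @param ct a [voxel_volume()].
#' @param markers list of 3D mm points (isocentre frame); must lie inside the
#'   grid.
#' @param radius sphere radius, mm.
#' @param attenuation marker linear attenuation, 1/mm.
#' @return A new [voxel_volume()] with markers embedded.
#' @export
embed_markers <- function(ct, markers, radius = 0.6, attenuation = 2.0) {
  stopifnot(inherits(ct, "voxel_volume"), radius > 0, attenuation >= 0)
  if (length(markers) == 0) return(ct)
  dm <- dim(ct$values)
  lo <- ct$origin
  hi <- ct$origin + (dm - 1) * ct$spacing
  vals <- ct$values
  for (m in markers) {
    m <- as.numeric(m)
    if (any(m < lo) || any(m > hi))
      stop("marker outside the volume grid")
    # bounding index window around the sphere
    i0 <- pmax(1L, floor((m - radius - lo) / ct$spacing) + 1L)
    i1 <- pmin(dm, ceiling((m + radius - lo) / ct$spacing) + 1L)
    ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
    cx <- lo[1] + (ix - 1) * ct$spacing[1]
    cy <- lo[2] + (iy - 1) * ct$spacing[2]
    cz <- lo[3] + (iz - 1) * ct$spacing[3]
    d2 <- outer(outer((cx - m[1])^2, (cy - m[2])^2, `+`), (cz - m[3])^2, `+`)
    sub <- vals[ix, iy, iz, drop = FALSE]
    sel <- d2 <= radius^2
    sub[sel] <- pmax(sub[sel], attenuation)
    vals[ix, iy, iz] <- sub
  }
  # guarantee at least the voxel containing each centre is set, even for
  # radii below half the voxel spacing
  for (m in markers) {
    m <- as.numeric(m)
    idx <- pmin(pmax(round((m - lo) / ct$spacing) + 1L, 1L), dm)
    vals[idx[1], idx[2], idx[3]] <- max(vals[idx[1], idx[2], idx[3]], attenuation)
  }
  voxel_volume(vals, ct$spacing, ct$origin)
}
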