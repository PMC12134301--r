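#' Rigid transforms and motion augmentation
#'
#' A `rigid_transform` holds a 3D translation (mm) and rotation (degrees,
#' applied about the isocentre in x -> y -> z axis order). Training-set
#' augmentation samples transforms uniformly per component, emulating
#' treatment setup error and whole-patient motion of up to `max_shift` mm and
#' `max_rot` degrees.
#'
#' @param translation numeric length-3, mm.
#' @param rotation numeric length-3, degrees.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0)) {
  translation <- as.numeric(translation); rotation <- as.numeric(rotation)
  if (length(translation) != 3L || length(rotation) != 3L ||
      any(!is.finite(c(translation, rotation))))
    stop("translation and rotation must be 3 finite components each")
  structure(list(translation = translation, rotation = rotation),
            class = "rigid_transform")
}

is_identity_transform <- function(t)
  all(t$translation == 0) && all(t$rotation == 0)

#' @rdname rigid_transform
#' @param max_shift maximum absolute translation per component, mm
#'   (default 10, the standard augmentation limit).
#' @param max_rot maximum absolute rotation per component, degrees (default 10).
#' @export
sample_transform <- function(max_shift = 10, max_rot = 10) {
  if (max_shift < 0 || max_rot < 0) stop("limits must be >= 0")
  rigid_transform(stats::runif(3, -max_shift, max_shift),
                  stats::runif(3, -max_rot, max_rot))
}

# rotation matrix, x -> y -> z order, degrees; the y rotation is oriented so
# that rotating a volume by +phi about the SI axis shifts its projections to
# gantry angle theta - phi
rotation_matrix <- function(rotation) {
  r <- rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, -sy), c(0, 1, 0), c(sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Resample a volume under a rigid transform
#'
#' Moves the anatomy by the rigid map `p -> R p + t` (rotation about the
#' isocentre, then translation): the output voxel at physical position `p`
#' takes the input value at `R^-1 (p - t)` by trilinear interpolation, with
#' zero (air) fill outside the grid. Grid metadata is unchanged. The identity
#' transform returns the volume bit-exactly.
#'
#' @param volume a [voxel_volume()].
#' @param t a [rigid_transform()].
#' @return A [voxel_volume()] on the same grid.
#' @export
apply_rigid_transform <- function(volume, t) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(t, "rigid_transform"))
  if (is_identity_transform(t)) return(volume)
  R <- rotation_matrix(t$rotation)
  out <- .cpp_rigid_resample(volume$values, volume$spacing, volume$origin,
                             t(R), t$translation)
  voxel_volume(array(out, dim(volume$values)), volume$spacing, volume$origin,
               nonneg = FALSE)
}

#' Build the paired cGAN training set
#'
#' For each of `n_augment` sampled rigid transforms, applies the *same*
#' transform to the planning volume and the prostate contour, then
#' forward-projects both over a full arc. Each anatomy DRR is paired with the
#' contour projection of the same transformed geometry at the same angle,
#' giving `n_augment * 360 / angle_step` pairs (100 augmentations at a 1
#' degree step yield the standard 36,000 pairs). Anatomy images are min-max
#' normalised to [0, 1] jointly over the whole set; mask projections are
#' binarised where the projected contour path length exceeds `mask_eps` mm.
#'
#' @param ct planning [voxel_volume()].
#' @param contour prostate [binary_volume()] on the same grid.
#' @param geom a [beam_geometry()].
#' @param n_augment number of sampled transforms (the identity is *not*
#'   included automatically).
#' @param max_shift,max_rot augmentation limits (mm, degrees).
#' @param angle_step arc step in degrees (must divide 360).
#' @param seed integer seed; the transform sequence is reproducible.
#' @param out_dir if non-`NULL`, pair pixel data are streamed to float32
#'   binary shards (one per augmentation) in this directory instead of being
#'   held in memory; the manifest then records shard paths.
#' @param mask_eps projected path length (mm) above which a mask pixel is 1.
#' @param step projector ray step, mm (default `min(spacing)/2`).
#' @return A `training_manifest`: list with `pairs` (in-memory mode; each a
#'   list `x`, `y`, `angle`, `transform_id`), or `shards` (disk mode),
#'   plus `meta` (data frame of angle/transform per pair), `transforms`,
#'   `geom`, `seed`, `norm_range`, `n_pairs`, `mask_eps`.
#' @export
build_training_set <- function(ct, contour, geom, n_augment = 100,
                               max_shift = 10, max_rot = 10, angle_step = 1,
                               seed = 1L, out_dir = NULL, mask_eps = 0.1,
                               step = NULL) {
  stopifnot(inherits(ct, "voxel_volume"), inherits(contour, "binary_volume"),
            inherits(geom, "beam_geometry"))
  if (!same_grid(ct, contour)) stop("ct and contour grids are not co-registered")
  if (360 %% angle_step != 0) stop("angle_step must divide 360")
  if (n_augment < 1) stop("n_augment must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  transforms <- lapply(seq_len(n_augment), function(i)
    sample_transform(max_shift, max_rot))

  angles <- seq(0, 360 - angle_step, by = angle_step)
  n_per <- length(angles)
  disk <- !is.null(out_dir)
  if (disk) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- if (!disk) vector("list", n_augment * n_per)
  shards <- if (disk) character(n_augment)
  # pass 1 computes the global anatomy range on the fly; raw shards are
  # written unnormalised and rescaled on load (range recorded in manifest)
  rng_lo <- Inf; rng_hi <- -Inf
  nu <- geom$detector_shape[1]; nv <- geom$detector_shape[2]
  for (a in seq_len(n_augment)) {
    tct <- apply_rigid_transform(ct, transforms[[a]])
    tmask <- apply_rigid_transform(contour, transforms[[a]])
    con <- NULL
    if (disk) {
      shards[a] <- file.path(out_dir, sprintf("shard_%04d.bin", a))
      con <- file(shards[a], "wb")
    }
    for (i in seq_along(angles)) {
      x <- forward_project(tct, geom, angles[i], step = step)$values
      ypath <- .cpp_forward_project(tmask$values, tmask$spacing, tmask$origin,
                                    geom$sad, geom$sid, nu, nv,
                                    geom$detector_pitch, angles[i],
                                    if (is.null(step)) min(tmask$spacing) / 2 else step)
      y <- (ypath > mask_eps) * 1
      rng_lo <- min(rng_lo, min(x)); rng_hi <- max(rng_hi, max(x))
      if (disk) {
        writeBin(as.numeric(x), con, size = 4L)
        writeBin(as.numeric(y), con, size = 4L)
      } else {
        pairs[[(a - 1) * n_per + i]] <-
          list(x = x, y = y, angle = angles[i], transform_id = a)
      }
    }
    if (disk) close(con)
  }
  if (rng_hi <= rng_lo) rng_hi <- rng_lo + 1
  norm_range <- c(rng_lo, rng_hi)
  if (!disk) {
    for (i in seq_along(pairs))
      pairs[[i]]$x <- (pairs[[i]]$x - rng_lo) / (rng_hi - rng_lo)
  }
  meta <- data.frame(pair = seq_len(n_augment * n_per),
                     transform_id = rep(seq_len(n_augment), each = n_per),
                     angle = rep(angles, n_augment))
  structure(list(pairs = if (!disk) pairs,
                 shards = if (disk) shards,
                 meta = meta,
                 transforms = transforms, geom = geom, seed = as.integer(seed),
                 norm_range = norm_range, n_pairs = nrow(meta),
                 angle_step = angle_step, mask_eps = mask_eps,
                 image_shape = c(nv, nu)),
            class = "training_manifest")
}

#' @exportS3Method base::print
print.training_manifest <- function(x, ...) {
  cat(sprintf("<training_manifest> %d pairs (%d transforms x %d angles), %dx%d px, %s\n",
              x$n_pairs, length(x$transforms), 360 %/% x$angle_step,
              x$image_shape[1], x$image_shape[2],
              if (is.null(x$shards)) "in memory" else "on disk"))
  invisible(x)
}

#' Load pairs from a training manifest
#'
#' Returns the requested pairs regardless of storage mode, with anatomy
#' images normalised by the manifest's recorded range.
#'
#' @param manifest a `training_manifest`.
#' @param indices pair indices (rows of `manifest$meta`).
#' @return List of `list(x, y, angle, transform_id)`.
#' @export
load_pairs <- function(manifest, indices) {
  stopifnot(inherits(manifest, "training_manifest"))
  if (is.null(manifest$shards)) return(manifest$pairs[indices])
  nv <- manifest$image_shape[1]; nu <- manifest$image_shape[2]
  npx <- nv * nu
  n_per <- 360 %/% manifest$angle_step
  rl <- manifest$norm_range[1]; rh <- manifest$norm_range[2]
  lapply(indices, function(i) {
    a <- (i - 1) %/% n_per + 1
    k <- (i - 1) %% n_per
    con <- file(manifest$shards[a], "rb")
    on.exit(close(con))
    seek(con, where = k * 2 * npx * 4)
    x <- matrix(readBin(con, "numeric", npx, size = 4L), nv, nu)
    y <- matrix(readBin(con, "numeric", npx, size = 4L), nv, nu)
    list(x = (x - rl) / (rh - rl), y = y,
         angle = manifest$meta$angle[i], transform_id = a)
  })
}
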