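#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D scalar grid of linear attenuation values with
#' physical metadata: per-axis voxel spacing (mm) and the position of the
#' centre of voxel `[1,1,1]` relative to the machine isocentre (mm). Array
#' axes follow the patient coordinate convention used throughout the package:
#' axis 1 = x (lateral), axis 2 = y (superior-inferior), axis 3 = z
#' (anterior-posterior), with the isocentre at coordinate (0,0,0).
#'
#' @param values 3D numeric array of attenuation values (1/mm). Must be finite.
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin numeric length-3, mm offset of the centre of voxel `[1,1,1]`
#'   from the isocentre. Default centres the grid on the isocentre.
#' @param nonneg if `TRUE` (default), negative values are rejected; attenuation
#'   volumes are physically non-negative.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = NULL, nonneg = TRUE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("`values` must be finite")
  if (nonneg && any(values < 0)) stop("attenuation values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive mm values")
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite mm values")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' Construct a binary volume (e.g. a prostate contour)
#'
#' Shares grid metadata with [voxel_volume()] but holds values in {0, 1}.
#'
#' @param values 3D array of 0/1 (or logical) values.
#' @inheritParams voxel_volume
#' @param require_nonempty error if no voxel is set (a contour volume must
#'   contain at least one voxel).
#' @return An object of class `binary_volume` (also inherits `voxel_volume`).
#' @export
binary_volume <- function(values, spacing, origin = NULL, require_nonempty = TRUE) {
  if (is.logical(values)) {
    dm <- dim(values)
    values <- array(as.double(values), dm)
  }
  if (!all(values %in% c(0, 1))) stop("binary volume values must be 0 or 1")
  if (require_nonempty && sum(values) == 0) stop("binary volume is empty")
  v <- voxel_volume(values, spacing, origin)
  class(v) <- c("binary_volume", class(v))
  v
}

#' @exportS3Method base::print
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(round(x$origin, 2)), collapse = ", ")))
  invisible(x)
}

# physical coordinates (mm, isocentre frame) of voxel centres along one axis
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$values)[axis]) - 1) * vol$spacing[axis]
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Read / write volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 files with voxel spacing in `pixdim` and the
#' isocentre-frame origin encoded in the sform/qform translation, so a
#' write-read round trip preserves values, spacing and origin.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [voxel_volume()] (a [binary_volume()] when
#'   `binary = TRUE`); `write_volume` returns `path` invisibly.
#' @param binary interpret the file as a 0/1 contour volume.
#' @export
read_volume <- function(path, binary = FALSE) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("expected a 3D volume, got %dD data in %s", length(dim(img)), path))
  xf <- RNifti::xform(img)
  spacing <- abs(c(xf[1, 1], xf[2, 2], xf[3, 3]))
  origin <- xf[1:3, 4]
  vals <- array(as.double(img), dim(img))
  if (binary) binary_volume(vals, spacing, origin, require_nonempty = FALSE)
  else voxel_volume(vals, spacing, origin)
}

#' @rdname read_volume
#' @param volume a [voxel_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  xf <- diag(c(volume$spacing, 1))
  xf[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing  # must precede the xform assignment
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
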