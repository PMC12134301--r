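#' Dice similarity coefficient between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Errors if both masks are empty (the
#' coefficient is undefined); disjoint nonempty masks give 0.
#'
#' @param a,b logical matrices of the same shape.
#' @return Fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("Dice undefined: both masks are empty")
  2 * sum(a & b) / (na + nb)
}

as_mask <- function(m) {
  if (inherits(m, "projection_image")) m <- m$values
  if (!is.logical(m)) m <- m != 0
  m
}

# boundary pixels: members with at least one non-member 4-neighbour
mask_boundary <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  m & !interior
}

#' Symmetric mean surface distance between two masks
#'
#' Boundaries are the member pixels with a non-member 4-neighbour; the MSD is
#' the average of the two directed mean nearest-neighbour distances between
#' the boundaries, with Euclidean pixel distances scaled by `pitch_iso` (mm
#' per pixel at the isocentre plane). Symmetric by construction:
#' `MSD(a, b) == MSD(b, a)`.
#'
#' @param a,b nonempty logical matrices of the same shape.
#' @param pitch_iso isocentre-plane pixel size, mm (1 = distances in pixels).
#' @return MSD in mm.
#' @export
mean_surface_distance <- function(a, b, pitch_iso = 1) {
  a <- as_mask(a); b <- as_mask(b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  if (!any(a) || !any(b)) stop("mean surface distance undefined for an empty mask")
  pa <- which(mask_boundary(a), arr.ind = TRUE)
  pb <- which(mask_boundary(b), arr.ind = TRUE)
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2
  dab <- mean(sqrt(apply(d2, 1, min)))
  dba <- mean(sqrt(apply(d2, 2, min)))
  (dab + dba) / 2 * pitch_iso
}

#' Summarise tracking records
#'
#' Per direction (AP/LAT, SI): mean, sample SD, MAD and linearly interpolated
#' 5th/95th percentiles of the centroid error; DSC and MSD are summarised
#' likewise. MAD here is the mean absolute deviation of the centroid error,
#' `mean(|error|)`. Flagged (dropped) records are excluded and counted.
#'
#' @param records data frame from [track_arc()].
#' @return A `metrics_summary`: list with `aplat`, `si`, `dsc`, `msd` stat
#'   vectors plus `n` and `n_dropped`.
#' @export
summarize_tracking <- function(records) {
  ok <- records[!records$dropped, , drop = FALSE]
  if (nrow(ok) == 0) stop("no unflagged records to summarise")
  stat_block <- function(x, mad = FALSE) {
    s <- c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
           p5 = unname(stats::quantile(x, 0.05)),
           p95 = unname(stats::quantile(x, 0.95)))
    if (mad) s <- c(s, mad = mean(abs(x)))
    s
  }
  structure(list(aplat = stat_block(ok$err_aplat_mm, mad = TRUE),
                 si = stat_block(ok$err_si_mm, mad = TRUE),
                 dsc = stat_block(ok$dsc),
                 msd = stat_block(ok$msd_mm),
                 n = nrow(ok), n_dropped = sum(records$dropped)),
            class = "metrics_summary")
}

#' @exportS3Method base::print
print.metrics_summary <- function(x, ...) {
  cat(sprintf("<metrics_summary> n = %d (%d dropped)\n", x$n, x$n_dropped))
  cat(sprintf("  AP/LAT error: %.2f +/- %.2f mm (MAD %.2f; p5 %.2f, p95 %.2f)\n",
              x$aplat["mean"], x$aplat["sd"], x$aplat["mad"],
              x$aplat["p5"], x$aplat["p95"]))
  cat(sprintf("  SI error:     %.2f +/- %.2f mm (MAD %.2f; p5 %.2f, p95 %.2f)\n",
              x$si["mean"], x$si["sd"], x$si["mad"], x$si["p5"], x$si["p95"]))
  cat(sprintf("  DSC: %.3f +/- %.3f (p5 %.3f, p95 %.3f)\n",
              x$dsc["mean"], x$dsc["sd"], x$dsc["p5"], x$dsc["p95"]))
  cat(sprintf("  MSD: %.2f +/- %.2f mm (p5 %.2f, p95 %.2f)\n",
              x$msd["mean"], x$msd["sd"], x$msd["p5"], x$msd["p95"]))
  invisible(x)
}

#' Pearson correlation between two series
#'
#' Thin wrapper over [stats::cor()] with the degenerate cases rejected
#' explicitly (length < 3 or zero variance).
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return Sample Pearson r in \[-1, 1\].
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Pearson correlation undefined for zero-variance series")
  stats::cor(a, b)
}

#' Bland-Altman agreement between observed motion and tracking error
#'
#' Standard Bland-Altman construction on the paired series: differences
#' `d = error - motion` analysed against the pairwise averages; bias is the
#' mean difference and the limits of agreement are `bias +/- 1.96 SD(d)`.
#'
#' @param motion,error numeric vectors (mm) of equal length >= 3.
#' @return `list(bias, loa_low, loa_high, mean_vals, diffs)`.
#' @export
bland_altman <- function(motion, error) {
  if (length(motion) != length(error)) stop("series lengths differ")
  if (length(motion) < 3) stop("need at least 3 observations")
  d <- error - motion
  avg <- (error + motion) / 2
  bias <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       mean_vals = avg, diffs = d)
}

#' Per-imager-angle statistics
#'
#' Bins tracking records by gantry angle and reports the per-bin mean and
#' 5th/95th percentiles of the AP/LAT error, SI error and DSC. Bins with no
#' samples are reported with `NA` (the number of samples per angle can vary).
#'
#' @param records data frame from [track_arc()].
#' @param bin_deg bin width, degrees (must divide 360).
#' @return Data frame with one row per bin.
#' @export
per_angle_stats <- function(records, bin_deg = 10) {
  if (360 %% bin_deg != 0) stop("bin_deg must divide 360")
  ok <- records[!records$dropped, , drop = FALSE]
  starts <- seq(0, 360 - bin_deg, by = bin_deg)
  bin_of <- (floor((ok$angle %% 360) / bin_deg) * bin_deg)
  one <- function(s) {
    sel <- ok[bin_of == s, , drop = FALSE]
    if (nrow(sel) == 0)
      return(data.frame(angle_lo = s, angle_hi = s + bin_deg, n = 0L,
                        aplat_mean = NA_real_, aplat_p5 = NA_real_, aplat_p95 = NA_real_,
                        si_mean = NA_real_, si_p5 = NA_real_, si_p95 = NA_real_,
                        dsc_mean = NA_real_, dsc_p5 = NA_real_, dsc_p95 = NA_real_))
    q <- function(x, p) unname(stats::quantile(x, p))
    data.frame(angle_lo = s, angle_hi = s + bin_deg, n = nrow(sel),
               aplat_mean = mean(sel$err_aplat_mm),
               aplat_p5 = q(sel$err_aplat_mm, 0.05),
               aplat_p95 = q(sel$err_aplat_mm, 0.95),
               si_mean = mean(sel$err_si_mm),
               si_p5 = q(sel$err_si_mm, 0.05), si_p95 = q(sel$err_si_mm, 0.95),
               dsc_mean = mean(sel$dsc),
               dsc_p5 = q(sel$dsc, 0.05), dsc_p95 = q(sel$dsc, 0.95))
  }
  out <- do.call(rbind, lapply(starts, one))
  rownames(out) <- NULL
  out
}
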