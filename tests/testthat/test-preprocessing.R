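test_that("harmonic inpainting restores constants and linear ramps exactly", {
  img <- matrix(3.7, 20, 20)
  mask <- matrix(FALSE, 20, 20)
  mask[8:12, 9:14] <- TRUE
  expect_equal(inpaint_regions(img, mask), img, tolerance = 1e-9)

  ramp <- outer(seq_len(20), seq_len(20), function(i, j) 0.5 * i - 0.2 * j + 3)
  out <- inpaint_regions(ramp, mask)
  expect_equal(out, ramp, tolerance = 1e-7)
  # pixels outside the mask untouched, bit-identical
  expect_identical(out[!mask], ramp[!mask])
})

test_that("inpainted pixels satisfy the discrete mean-value property and maximum principle", {
  set.seed(9)
  img <- matrix(runif(30 * 30), 30, 30)
  mask <- matrix(FALSE, 30, 30)
  mask[10:18, 12:20] <- TRUE
  mask[5:7, 5:6] <- TRUE
  out <- inpaint_regions(img, mask)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    nb <- c(out[i - 1, j], out[i + 1, j], out[i, j - 1], out[i, j + 1])
    expect_equal(out[i, j], mean(nb), tolerance = 1e-6)
  }
  # maximum principle: filled values lie within the range of boundary values
  boundary_vals <- c()
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      if (!mask[i + d[1], j + d[2]])
        boundary_vals <- c(boundary_vals, img[i + d[1], j + d[2]])
    }
  }
  expect_true(all(out[mask] >= min(boundary_vals) - 1e-9))
  expect_true(all(out[mask] <= max(boundary_vals) + 1e-9))
})

test_that("inpainting is idempotent and rejects border masks", {
  set.seed(3)
  img <- matrix(runif(16 * 16), 16, 16)
  mask <- matrix(FALSE, 16, 16)
  mask[6:9, 7:11] <- TRUE
  once <- inpaint_regions(img, mask)
  twice <- inpaint_regions(once, mask)
  expect_equal(once, twice, tolerance = 1e-9)

  bad <- matrix(FALSE, 16, 16)
  bad[1, 5] <- TRUE
  expect_error(inpaint_regions(img, bad), "border")
})

test_that("Poisson noise has the correct mean and variance scaling", {
  set.seed(21)
  img <- matrix(c(0, 2, 5, 10), 2, 2)
  n <- 10000
  draws <- replicate(n, add_poisson_noise(img, photons_at_max = 100))
  expect_true(all(draws[1, 1, ] == 0))  # zero pixels stay zero
  m <- mean(draws[2, 2, ])  # the value-10 pixel
  se <- sd(draws[2, 2, ]) / sqrt(n)
  expect_lt(abs(m - 10), 3 * se)
  # variance ~ value * max / photons: doubling photons halves the variance
  d2 <- replicate(n, add_poisson_noise(img, photons_at_max = 200))
  expect_equal(var(d2[2, 2, ]) / var(draws[2, 2, ]), 0.5, tolerance = 0.1)
  expect_error(add_poisson_noise(matrix(-1, 2, 2)), "non-negative")
})

test_that("image shifts behave exactly for integer pixel displacements", {
  set.seed(4)
  img <- matrix(runif(12 * 12), 12, 12)
  expect_equal(shift_image(img, c(0, 0), pitch = 1), img)
  sh <- shift_image(img, c(3, -2), pitch = 1)  # +3 px in u, -2 px in v
  expect_equal(sh[1:10, 4:12], img[3:12, 1:9], tolerance = 1e-12)
  expect_true(all(sh[, 1:3] == 0))
  # centroid of a shifted mask moves by exactly the applied shift
  m <- matrix(0, 12, 12)
  m[5:7, 5:7] <- 1
  msh <- shift_image(m, c(2, 1), pitch = 1)
  expect_equal(unname(mask_centroid(msh > 0.5) - mask_centroid(m > 0.5)), c(2, 1))
})

test_that("3D marker masking restores a locally linear background", {
  # affine attenuation field is harmonic: infill must restore it
  dm <- c(16L, 16L, 16L)
  sp <- c(2, 2, 2)
  origin <- -(dm - 1) / 2 * sp
  xs <- origin[1] + (seq_len(dm[1]) - 1) * sp[1]
  field <- outer(outer(0.01 * xs, 0.002 * xs, `+`), 0.005 * xs, `+`) + 2
  vol <- voxel_volume(field, sp, origin)
  mk <- list(c(0, 0, 0), c(-6, 4, 2))
  withmk <- embed_markers(vol, mk, radius = 2.5, attenuation = 10)
  expect_gt(max(abs(withmk$values - vol$values)), 1)
  restored <- mask_markers_3d(withmk, mk, radius = 2.5)
  expect_equal(restored$values, vol$values, tolerance = 1e-6)
  # constant volume unchanged; unmasked voxels bit-identical
  cst <- voxel_volume(array(1, dm), sp, origin)
  cwm <- embed_markers(cst, mk, radius = 2.5, attenuation = 10)
  back <- mask_markers_3d(cwm, mk, radius = 2.5)
  expect_equal(back$values, cst$values, tolerance = 1e-9)
  mask <- kvtrack:::marker_voxel_mask(vol, mk, 2.5)
  expect_identical(back$values[!mask], cst$values[!mask])
})

test_that("marker footprints are removed from DRRs end to end", {
  # fine voxel grid: the rasterised marker footprint must stay small relative
  # to the surrounding anatomy for harmonic infill to be a faithful
  # restoration (the premise of marker masking in kV practice)
  spec <- phantom_spec(grid_shape = c(192L, 192L, 192L),
                       voxel_spacing = c(1, 1, 1),
                       marker_positions = list(c(5, 8, -6), c(-2, 2, -10)))
  ph <- generate_phantom(spec, seed = 13)
  geom <- beam_geometry(detector_shape = c(64L, 64L), detector_pitch = 2)
  clean <- forward_project(ph$ct, geom, 40)
  withmk <- forward_project(embed_markers(ph$ct, ph$markers, 0.6, 2.0), geom, 40)
  pad <- max(ph$ct$spacing) * 1.5
  fp <- marker_footprint(ph$markers, geom, 40, 0.6, voxel_pad = pad)
  resid <- withmk$values - clean$values
  expect_gt(max(resid[fp]), 0.5)        # markers clearly visible before masking
  expect_lt(max(abs(resid[!fp])), 1e-6) # and fully covered by the footprint
  inp <- inpaint_regions(withmk, fp)
  # after inpainting, no pixel in the footprint deviates from the marker-free
  # DRR by more than 5% of the local dynamic range (clean-image range over
  # the neighbourhood window around the footprints)
  idx <- which(fp, arr.ind = TRUE)
  r <- ceiling(sqrt(sum(fp) / pi / 2))
  win <- matrix(FALSE, nrow(fp), ncol(fp))
  win[max(1, min(idx[, 1]) - 3 * r):min(nrow(fp), max(idx[, 1]) + 3 * r),
      max(1, min(idx[, 2]) - 3 * r):min(ncol(fp), max(idx[, 2]) + 3 * r)] <- TRUE
  local_range <- diff(range(clean$values[win]))
  expect_lt(max(abs(inp$values[fp] - clean$values[fp])), 0.05 * local_range)
})
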