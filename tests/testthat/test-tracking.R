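# an "oracle generator": a model_artifact-shaped object is not needed for
# these workflow tests; we drive the mask-processing stages directly and,
# for track_arc, inject predictions through a stub generator model built from
# a trained-network API bypass (predictions equal the ground truth masks,
# optionally shifted), which isolates the geometry of the workflow from
# network quality.

stub_tracking <- function(gt_masks, preds, geom, angles, threshold = 0.10) {
  # replicate track_arc's per-image workflow on given prediction images
  pitch_iso <- kvtrack:::iso_pixel_mm(geom)
  rows <- lapply(seq_along(preds), function(i) {
    seg <- largest_component(binarise_prediction(preds[[i]], threshold))
    gm <- gt_masks[[i]]
    gt_c <- mask_centroid(gm)
    pc <- mask_centroid(seg)
    data.frame(angle = angles[i],
               err_aplat_mm = pixel_to_isocentre_mm(pc[1] - gt_c[1], geom),
               err_si_mm = pixel_to_isocentre_mm(pc[2] - gt_c[2], geom),
               dsc = dice(seg, gm),
               msd_mm = mean_surface_distance(seg, gm, pitch_iso),
               dropped = FALSE)
  })
  do.call(rbind, rows)
}

test_that("binarisation uses an absolute fraction of the output range", {
  pred <- matrix(0, 6, 6)
  pred[3:4, 3:4] <- c(0.05, 0.11, 0.2, 0.4)
  expect_equal(sum(binarise_prediction(pred, 0.10)), 3)
  # monotone: higher threshold gives a subset
  m1 <- binarise_prediction(pred, 0.1)
  m2 <- binarise_prediction(pred, 0.2)
  expect_true(all(m1[m2]))
  expect_true(sum(m2) <= sum(m1))
  # all-zero prediction yields an empty mask
  expect_false(any(binarise_prediction(matrix(0, 4, 4), 0.1)))
})

test_that("largest_component keeps the biggest 8-connected region with a stable tie-break", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:6] <- TRUE          # 10 px
  m[7:8, 2:3] <- TRUE          # 4 px (diagonal-separated from the first)
  out <- largest_component(m)
  expect_equal(sum(out), 10)
  expect_true(all(out[2:3, 2:6]))
  expect_equal(attr(out, "n_components"), 2L)

  # single component unchanged; diagonal touching counts as connected
  d <- matrix(FALSE, 5, 5)
  d[1, 1] <- TRUE; d[2, 2] <- TRUE
  od <- largest_component(d)
  expect_equal(attr(od, "n_components"), 1L)
  expect_equal(sum(od), 2)

  # equal sizes: the component containing the smallest row-major index wins
  t2 <- matrix(FALSE, 8, 8)
  t2[5, 6:7] <- TRUE   # row-major index of (5,6): (5-1)*8+6 = 38
  t2[6, 1:2] <- TRUE   # row-major index of (6,1): (6-1)*8+1 = 41
  ot <- largest_component(t2)
  expect_true(all(ot[5, 6:7]))
  expect_false(any(ot[6, ]))

  e <- largest_component(matrix(FALSE, 4, 4))
  expect_true(attr(e, "empty"))
  expect_equal(attr(e, "n_components"), 0L)
})

test_that("centroids are coordinate means with the documented conventions", {
  m <- matrix(FALSE, 9, 9)
  m[3:5, 6:8] <- TRUE  # rows 3-5, cols 6-8
  expect_equal(unname(mask_centroid(m)), c(7, 4))  # (u=col, v=row)
  s <- matrix(FALSE, 4, 4); s[2, 3] <- TRUE
  expect_equal(unname(mask_centroid(s)), c(3, 2))
  # L-shaped pentomino matches exhaustive enumeration
  l <- matrix(FALSE, 6, 6)
  l[2:5, 2] <- TRUE; l[5, 3] <- TRUE
  idx <- which(l, arr.ind = TRUE)
  expect_equal(unname(mask_centroid(l)), c(mean(idx[, 2]), mean(idx[, 1])))
  expect_error(mask_centroid(matrix(FALSE, 3, 3)), "empty")
})

test_that("oracle predictions track perfectly; shifted predictions show the exact offset", {
  ph <- tiny_phantom()
  geom <- test_geom()
  angles <- c(0, 90, 180, 270)
  gt <- lapply(angles, function(a) project_contour_mask(ph$contour, geom, a))
  # oracle: predictions equal ground truth
  rec0 <- stub_tracking(gt, lapply(gt, function(m) m * 1), geom, angles)
  expect_true(all(rec0$err_aplat_mm == 0))
  expect_true(all(rec0$err_si_mm == 0))
  expect_true(all(rec0$dsc == 1))
  expect_true(all(rec0$msd_mm == 0))
  # predictions shifted 3 px in +u: AP/LAT error = 3 * pitch * SAD/SID, SI 0
  sh <- lapply(gt, function(m) shift_image(m * 1, c(3, 0), pitch = 1))
  rec3 <- stub_tracking(gt, sh, geom, angles)
  expect_equal(rec3$err_aplat_mm, rep(3 * geom$detector_pitch / 1.5, 4),
               tolerance = 1e-9)
  expect_equal(rec3$err_si_mm, rep(0, 4), tolerance = 1e-9)
  # with pitch 0.39 and ratio 1.5 a 3 px offset is 0.78 mm
  g2 <- beam_geometry(detector_pitch = 0.39, detector_shape = c(64L, 64L))
  expect_equal(pixel_to_isocentre_mm(3, g2), 0.78)
})

test_that("centroid displacement of a translated phantom matches the shift mapping", {
  ph <- tiny_phantom()
  geom <- test_geom()
  shift <- c(5, -7, 4)
  moved <- apply_rigid_transform(ph$contour, rigid_transform(translation = shift))
  for (a in c(0, 30, 135, 220, 315)) {
    m0 <- project_contour_mask(ph$contour, geom, a)
    m1 <- forward_project(voxel_volume(moved$values, moved$spacing, moved$origin,
                                       nonneg = FALSE), geom, a)$values > 0.1
    dc_px <- mask_centroid(m1) - mask_centroid(m0)
    pred_px <- project_shift(shift, a, geom) / geom$detector_pitch
    expect_lt(max(abs(dc_px - pred_px)), 1)
  }
})

test_that("track_arc flags empty predictions and reports one record per image", {
  ph <- tiny_phantom()
  geom <- test_geom()
  angles <- c(0, 90)
  gt <- lapply(angles, function(a) project_contour_mask(ph$contour, geom, a))
  kv <- lapply(angles, function(a) forward_project(ph$ct, geom, a))
  kvn <- normalize_projections(kv)$images
  # an untrained generator: records exist for every image; any empty
  # predictions carry NA metrics and the dropped flag
  nets <- build_networks(network_config(image_size = 64L, base_channels = 2L,
                                        generator_depth = 2L), seed = 1)
  model <- structure(list(G = nets$G, ncfg = nets$cfg,
                          norm_range = c(0, 1)), class = "model_artifact")
  rec <- track_arc(model, kvn, gt, geom, angles = angles)
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$dropped %in% c(TRUE, FALSE)))
  expect_true(all(is.na(rec$dsc[rec$dropped])))
  expect_true(all(!is.na(rec$gt_u)))
})
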