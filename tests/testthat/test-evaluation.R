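test_that("dice matches hand-counted and degenerate cases", {
  a <- matrix(FALSE, 8, 8); a[2:3, 2:3] <- TRUE
  b <- matrix(FALSE, 8, 8); b[2:3, 3:4] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)  # 2*2/(4+4)
  d <- matrix(FALSE, 8, 8); d[6:7, 6:7] <- TRUE
  expect_equal(dice(a, d), 0)
  expect_equal(dice(a, matrix(FALSE, 8, 8)), 0)  # one empty mask: no overlap
  expect_error(dice(matrix(FALSE, 8, 8), matrix(FALSE, 8, 8)), "empty")
  expect_error(dice(a, matrix(TRUE, 4, 4)), "shape")
})

test_that("mean surface distance matches simple exact cases and is symmetric", {
  a <- matrix(FALSE, 10, 10); a[5, 3] <- TRUE
  b <- matrix(FALSE, 10, 10); b[5, 7] <- TRUE
  expect_equal(mean_surface_distance(a, b, 1), 4)
  expect_equal(mean_surface_distance(a, b, 0.26), 4 * 0.26)
  expect_equal(mean_surface_distance(a, a, 1), 0)
  c2 <- matrix(FALSE, 10, 10); c2[2:4, 2:4] <- TRUE
  d2 <- matrix(FALSE, 10, 10); d2[6:9, 3:8] <- TRUE
  expect_equal(mean_surface_distance(c2, d2, 1), mean_surface_distance(d2, c2, 1))
  expect_error(mean_surface_distance(a, matrix(FALSE, 10, 10), 1), "empty")
})

test_that("dice, MSD and centroid agree with brute-force oracles on random masks", {
  set.seed(77)
  for (k in 1:100) {
    a <- random_blob_mask()
    b <- random_blob_mask()
    expect_identical(dice(a, b), oracle_dice(a, b))
    expect_lt(abs(mean_surface_distance(a, b, 1) - oracle_msd(a, b, 1)), 1e-9)
    idx <- which(a, arr.ind = TRUE)
    expect_equal(unname(mask_centroid(a)), c(mean(idx[, 2]), mean(idx[, 1])))
  }
})

test_that("tracking summaries compute mean, SD, MAD and percentiles correctly", {
  rec <- data.frame(angle = c(0, 45, 90, 135, 180),
                    err_aplat_mm = c(-2, -1, 0, 1, 2),
                    err_si_mm = rep(0.5, 5),
                    dsc = c(0.9, 0.92, 0.94, 0.96, 0.98),
                    msd_mm = rep(1, 5), dropped = FALSE)
  s <- summarize_tracking(rec)
  expect_equal(unname(s$aplat["mean"]), 0)
  expect_equal(unname(s$aplat["mad"]), 1.2)  # mean(|{-2,-1,0,1,2}|)
  expect_equal(unname(s$aplat["sd"]), sd(c(-2, -1, 0, 1, 2)))
  expect_equal(unname(s$si["mean"]), 0.5)
  expect_equal(unname(s$si["sd"]), 0)
  expect_equal(unname(s$si["p5"]), 0.5)
  expect_equal(unname(s$si["p95"]), 0.5)
  expect_equal(unname(s$aplat["p5"]), unname(quantile(c(-2, -1, 0, 1, 2), 0.05)))
  expect_equal(s$n, 5)
  # permutation invariance
  s2 <- summarize_tracking(rec[sample(5), ])
  expect_equal(s2$aplat, s$aplat)
  # flagged records are excluded and counted
  rec2 <- rbind(rec, data.frame(angle = 225, err_aplat_mm = NA, err_si_mm = NA,
                                dsc = NA, msd_mm = NA, dropped = TRUE))
  s3 <- summarize_tracking(rec2)
  expect_equal(s3$n, 5)
  expect_equal(s3$n_dropped, 1)
  expect_equal(s3$aplat, s$aplat)
  expect_error(summarize_tracking(rec2[rec2$dropped, ]), "no unflagged")
})

test_that("pearson wraps the sample correlation with explicit degenerate errors", {
  set.seed(12)
  a <- rnorm(50)
  expect_equal(pearson(a, a), 1)
  expect_equal(pearson(a, -a), -1)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(abs(pearson(x, y)), 0.05)
  expect_error(pearson(a, a[1:10]), "length")
  expect_error(pearson(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("Bland-Altman bias and limits follow the standard construction", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  bak <- bland_altman(x, x + 2)
  expect_equal(bak$bias, 2)
  expect_equal(bak$loa_low, 2)
  expect_equal(bak$loa_high, 2)
  # hand-computed 5-point example
  m <- c(0.0, 1.0, -1.0, 2.0, 0.5)
  e <- c(0.4, 0.8, -1.5, 2.9, 0.2)
  d <- e - m
  ba <- bland_altman(m, e)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$mean_vals, (m + e) / 2)
  expect_error(bland_altman(x, x[1:3]), "length")
})

test_that("per-angle tables bin records and report empty bins", {
  rec <- data.frame(angle = c(5, 7, 95, 100, 340),
                    err_aplat_mm = c(1, 2, 3, 4, 5),
                    err_si_mm = c(-1, -2, -3, -4, -5),
                    dsc = c(0.9, 0.8, 0.7, 0.6, 0.5),
                    msd_mm = 1, dropped = FALSE)
  tab <- per_angle_stats(rec, bin_deg = 10)
  expect_equal(nrow(tab), 36)
  expect_equal(tab$n[tab$angle_lo == 0], 2)
  expect_equal(tab$aplat_mean[tab$angle_lo == 0], 1.5)
  expect_equal(tab$n[tab$angle_lo == 20], 0)
  expect_true(is.na(tab$dsc_mean[tab$angle_lo == 20]))
  # single-angle records populate a single bin
  one <- per_angle_stats(rec[1:2, ], bin_deg = 45)
  expect_equal(sum(one$n > 0), 1)
  # homogeneous errors: per-bin means equal the global mean
  set.seed(3)
  big <- data.frame(angle = rep(seq(0, 350, by = 10), each = 20),
                    err_aplat_mm = 2, err_si_mm = -1, dsc = 0.9, msd_mm = 1,
                    dropped = FALSE)
  tb <- per_angle_stats(big, bin_deg = 10)
  expect_true(all(abs(tb$aplat_mean - 2) < 1e-12))
  expect_error(per_angle_stats(rec, bin_deg = 7), "divide")
})
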