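test_that("network configs validate their invariants", {
  expect_error(network_config(image_size = 8, generator_depth = 4), "2\\^")
  expect_error(network_config(image_size = 48), "power of two")
  expect_error(network_config(lambda = -1), "lambda")
  expect_error(train_config(epochs = 0), "positive")
  expect_equal(network_config()$lambda, 100)
  expect_equal(train_config()$epochs, 20L)
  expect_equal(train_config()$batch_size, 4L)
  expect_equal(train_config()$learning_rate, 2e-4)
})

test_that("generator and discriminator honour their shape contracts", {
  for (sz in c(32L, 64L)) {
    cfg <- network_config(image_size = sz, base_channels = 4L,
                          generator_depth = 3L)
    nets <- build_networks(cfg, seed = 2)
    x <- array(runif(sz * sz), c(sz, sz, 1))
    g <- kvtrack:::.cpp_unet_predict(nets$G, x, cfg$base_channels,
                                     cfg$generator_depth, 1L)
    expect_equal(dim(g), dim(x))                 # same-shape output
    expect_true(all(g > 0 & g < 1))              # sigmoid-bounded
    s <- kvtrack:::.cpp_disc_predict(nets$D, x[, , 1], x[, , 1],
                                     cfg$base_channels,
                                     cfg$discriminator_patch_levels, 1L)
    expect_lt(nrow(s), sz)                       # patch grid smaller than input
    expect_true(all(s > 0 & s < 1))
  }
  # identical seeds give identical initial parameters
  a <- build_networks(network_config(), seed = 4)
  b <- build_networks(network_config(), seed = 4)
  expect_identical(a$G, b$G)
  expect_identical(a$D, b$D)
  expect_false(identical(build_networks(network_config(), seed = 5)$G, a$G))
})

test_that("objective closed forms match the adversarial + L1 definition", {
  y <- matrix(runif(16), 4, 4)
  o <- cgan_objective(matrix(0.5, 3, 3), matrix(0.5, 3, 3), y, y, lambda = 100)
  expect_equal(o$loss_D, 2 * log(2))
  expect_equal(o$adv_G, log(2))
  expect_equal(o$l1, 0)
  expect_equal(o$loss_G, log(2))
  # lambda weighting of a known L1 gap
  g <- y + 0.25
  o2 <- cgan_objective(matrix(0.9), matrix(0.2), y, g, lambda = 100)
  expect_equal(o2$l1, 0.25)
  expect_equal(o2$loss_G, -log(0.2) + 25)
  expect_equal(o2$loss_D, -(log(0.9) + log(0.8)))
  # clamped at scores of exactly 0/1 rather than infinite
  o3 <- cgan_objective(matrix(1), matrix(0), y, g, lambda = 0)
  expect_true(is.finite(o3$loss_D) && is.finite(o3$loss_G))
  expect_error(cgan_objective(matrix(0.5), matrix(0.5), y, matrix(0, 2, 2)), "shape")
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- network_config(image_size = 8L, base_channels = 2L,
                        generator_depth = 2L, discriminator_patch_levels = 2L,
                        lambda = 3)
  nets <- build_networks(cfg, seed = 3)
  set.seed(14)
  n <- 2
  x <- array(runif(8 * 8 * n), c(8, 8, n))
  y <- array(runif(8 * 8 * n), c(8, 8, n))
  res <- kvtrack:::.cpp_cgan_batch_grads(nets$G, nets$D, x, y, cfg$lambda,
                                         cfg$base_channels, cfg$generator_depth,
                                         cfg$discriminator_patch_levels, 1L)
  lossG <- function(G, D) {
    tot <- 0
    for (s in 1:n) {
      g <- kvtrack:::.cpp_unet_predict(G, x[, , s, drop = FALSE],
                                       cfg$base_channels, cfg$generator_depth, 1L)[, , 1]
      sf <- kvtrack:::.cpp_disc_predict(D, x[, , s], g, cfg$base_channels,
                                        cfg$discriminator_patch_levels, 1L)
      tot <- tot + cgan_objective(matrix(0.5), sf, y[, , s], g, cfg$lambda)$loss_G
    }
    tot / n
  }
  lossD <- function(G, D) {
    tot <- 0
    for (s in 1:n) {
      g <- kvtrack:::.cpp_unet_predict(G, x[, , s, drop = FALSE],
                                       cfg$base_channels, cfg$generator_depth, 1L)[, , 1]
      sr <- kvtrack:::.cpp_disc_predict(D, x[, , s], y[, , s], cfg$base_channels,
                                        cfg$discriminator_patch_levels, 1L)
      sf <- kvtrack:::.cpp_disc_predict(D, x[, , s], g, cfg$base_channels,
                                        cfg$discriminator_patch_levels, 1L)
      tot <- tot + cgan_objective(sr, sf, y[, , s], g, cfg$lambda)$loss_D
    }
    tot / n
  }
  # reported batch losses agree with the R-side objective on the same scores
  expect_equal(res$loss_d, lossD(nets$G, nets$D), tolerance = 1e-10)
  expect_equal(res$loss_g, lossG(nets$G, nets$D), tolerance = 1e-10)
  h <- 1e-5
  check_net <- function(params, grads, loss, which) {
    errs <- c()
    for (r in 1:15) {
      li <- sample(seq_along(params), 1)
      if (length(params[[li]]) == 0) next
      ei <- sample(length(params[[li]]), 1)
      up <- params; up[[li]][ei] <- up[[li]][ei] + h
      dn <- params; dn[[li]][ei] <- dn[[li]][ei] - h
      num <- if (which == "G") (loss(up, nets$D) - loss(dn, nets$D)) / (2 * h)
             else (loss(nets$G, up) - loss(nets$G, dn)) / (2 * h)
      ana <- grads[[li]][ei]
      errs <- c(errs, abs(num - ana) / max(abs(num), abs(ana), 1e-6))
    }
    errs
  }
  expect_lt(max(check_net(nets$G, res$g_grads, lossG, "G")), 1e-4)
  expect_lt(max(check_net(nets$D, res$d_grads, lossD, "D")), 1e-4)
})

test_that("with a dominant L1 weight the generator update is pure L1 regression", {
  cfg <- network_config(image_size = 16L, base_channels = 2L,
                        generator_depth = 3L, discriminator_patch_levels = 2L)
  nets <- build_networks(cfg, seed = 8)
  set.seed(15)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.2), c(16, 16, 2))
  res <- kvtrack:::.cpp_cgan_batch_grads(nets$G, nets$D, x, y, 1e6,
                                         cfg$base_channels, cfg$generator_depth,
                                         cfg$discriminator_patch_levels, 1L)
  ref <- kvtrack:::.cpp_unet_l1_grads(nets$G, x, y, cfg$base_channels,
                                      cfg$generator_depth, 1L)
  a <- unlist(res$g_grads)
  b <- unlist(ref)
  cosine <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosine, 0.99)
})

test_that("training reduces the reconstruction error and is seed-deterministic", {
  ph <- tiny_phantom()
  geom <- test_geom()
  man <- build_training_set(ph$ct, ph$contour, geom, n_augment = 1,
                            angle_step = 45, seed = 2)
  ncfg <- network_config(image_size = 64L, base_channels = 4L,
                         generator_depth = 3L)
  tcfg <- train_config(epochs = 5L, batch_size = 4L, learning_rate = 1e-3,
                       seed = 6L)
  m1 <- train_patient_model(man, ncfg, tcfg)
  expect_equal(nrow(m1$history), 5)
  expect_true(all(is.finite(as.matrix(m1$history))))
  expect_lt(m1$history$l1[5], m1$history$l1[1])
  m2 <- train_patient_model(man, ncfg, tcfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$G, m2$G)
})
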