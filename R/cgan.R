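#' Network configuration for the conditional GAN
#'
#' The generator is a UNet (4x4 stride-2 encoder/decoder with skip
#' connections, sigmoid output bounded in \[0, 1\]); the discriminator is a
#' PatchGAN that scores overlapping patches of an (input, mask) pair.
#' Channel widths double per level from `base_channels`, capped at
#' `8 * base_channels`, following the conventions of the pix2pix model
#' family. Parameters are initialised from a zero-mean normal.
#'
#' @param image_size square input size in pixels; must be a power of two and
#'   at least `2^generator_depth`. 512 for full-scale runs; 64 is the working
#'   size for desk-scale experiments.
#' @param base_channels first-level channel count.
#' @param generator_depth number of down/up levels in the UNet.
#' @param discriminator_patch_levels number of discriminator conv layers
#'   (the first `levels - 1` have stride 2; the patch grid is strictly
#'   smaller than the input).
#' @param lambda weight of the L1 reconstruction term in the generator loss
#'   (default 100).
#' @param init_sd SD of the normal weight initialiser (default 0.02); when
#'   `init = "he"` weights are instead drawn with the fan-in-scaled SD
#'   `sqrt(2 / fan_in)`.
#' @param normalization `"instance"` (non-affine instance normalisation on
#'   inner layers) or `"none"`.
#' @param init `"normal"` (fixed-SD zero-mean normal) or `"he"`
#'   (fan-in-scaled).
#' @return An object of class `network_config`.
#' @export
network_config <- function(image_size = 64L, base_channels = 16L,
                           generator_depth = 4L,
                           discriminator_patch_levels = 3L,
                           lambda = 100, init_sd = 0.02,
                           normalization = c("instance", "none"),
                           init = c("normal", "he")) {
  normalization <- match.arg(normalization)
  init <- match.arg(init)
  image_size <- as.integer(image_size)
  if (image_size < 2^generator_depth)
    stop("image_size must be at least 2^generator_depth")
  if (bitwAnd(image_size, image_size - 1L) != 0L)
    stop("image_size must be a power of two")
  if (lambda < 0) stop("lambda must be >= 0")
  if (discriminator_patch_levels < 2L) stop("need at least 2 discriminator levels")
  structure(list(image_size = image_size,
                 base_channels = as.integer(base_channels),
                 generator_depth = as.integer(generator_depth),
                 discriminator_patch_levels = as.integer(discriminator_patch_levels),
                 lambda = as.numeric(lambda), init_sd = as.numeric(init_sd),
                 normalization = normalization, init = init),
            class = "network_config")
}

#' Training configuration
#'
#' Defaults follow the standard patient-specific recipe: 20 epochs, batch
#' size 4, learning rate 0.0002, Adam with GAN-standard moments (0.5, 0.999).
#'
#' @param epochs,batch_size,learning_rate positive training hyperparameters.
#' @param beta1,beta2 Adam moment decay rates.
#' @param seed integer seed for initialisation and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 4L, learning_rate = 2e-4,
                         beta1 = 0.5, beta2 = 0.999, seed = 1L) {
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop("epochs, batch_size and learning_rate must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = as.numeric(learning_rate),
                 beta1 = beta1, beta2 = beta2, seed = as.integer(seed)),
            class = "train_config")
}

#' Build generator and discriminator parameter sets
#'
#' Draws all weights from a zero-mean normal with SD `cfg$init_sd` (biases
#' zero) using R's RNG, so equal seeds give identical initial parameters.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed.
#' @return `list(G =, D =, cfg =)`; `G`/`D` are flat lists of weight matrices
#'   and bias vectors in layer order.
#' @export
build_networks <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  shapes <- .cpp_gan_shapes(cfg$base_channels, cfg$generator_depth,
                            cfg$discriminator_patch_levels, use_norm_flag(cfg))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  init <- function(sh) {
    params <- vector("list", 2L * length(sh))
    for (i in seq_along(sh)) {
      dmw <- sh[[i]]$w
      sd <- if (identical(cfg$init, "he")) sqrt(2 / sh[[i]]$fan_in) else cfg$init_sd
      params[[2 * i - 1]] <- matrix(stats::rnorm(prod(dmw), sd = sd),
                                    dmw[1], dmw[2])
      params[[2 * i]] <- numeric(sh[[i]]$b)
    }
    params
  }
  list(G = init(shapes$g), D = init(shapes$d), cfg = cfg)
}

#' Conditional GAN objective (closed form on given scores)
#'
#' Evaluates the adversarial + L1 objective on discriminator patch scores and
#' a generated image:
#' \deqn{loss_D = -(\overline{\log d_{real}} + \overline{\log(1 - d_{fake})})}
#' \deqn{loss_G = -\overline{\log d_{fake}} + \lambda\,\overline{|y - G(x)|}}
#' (non-saturating generator form of the min-max adversarial objective;
#' expectations are means over patches/pixels). Scores at exactly 0 or 1 are
#' clamped at `1e-7`.
#'
#' @param d_real,d_fake patch-score matrices/vectors in (0, 1).
#' @param y target mask image.
#' @param g_x generated image, same shape as `y`.
#' @param lambda L1 weight (default 100).
#' @return `list(loss_D, loss_G, adv_G, l1)`.
#' @export
cgan_objective <- function(d_real, d_fake, y, g_x, lambda = 100) {
  if (!identical(dim(y), dim(g_x))) stop("y and g_x must share a shape")
  eps <- 1e-7
  dr <- pmin(pmax(as.numeric(d_real), eps), 1 - eps)
  df <- pmin(pmax(as.numeric(d_fake), eps), 1 - eps)
  loss_d <- -(mean(log(dr)) + mean(log(1 - df)))
  l1 <- mean(abs(y - g_x))
  adv <- -mean(log(df))
  list(loss_D = loss_d, loss_G = adv + lambda * l1, adv_G = adv, l1 = l1)
}

# one Adam update over a flat parameter list; state holds m/v lists and step t
adam_update <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  if (is.null(state)) {
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0), t = 0L)
  }
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / c1) / (sqrt(state$v[[i]] / c2) + eps)
  }
  list(params = params, state = state)
}

pairs_to_cube <- function(pairs, field) {
  n <- length(pairs)
  d <- dim(pairs[[1]][[field]])
  arr <- array(0, c(d[1], d[2], n))
  for (i in seq_len(n)) arr[, , i] <- pairs[[i]][[field]]
  arr
}

#' Train a patient-specific conditional GAN
#'
#' Alternates discriminator and generator Adam updates per mini-batch over
#' the paired training set, recording per-epoch mean losses (discriminator
#' loss, generator loss, and the L1 term). Deterministic for a fixed seed
#' under single-threaded numerics.
#'
#' @param manifest a `training_manifest` from [build_training_set()]; pair
#'   images must match `ncfg$image_size`.
#' @param ncfg a [network_config()].
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return A `model_artifact`: `list(G, D, history, ncfg, tcfg, norm_range,
#'   seed)`; `history` has one row per epoch.
#' @export
train_patient_model <- function(manifest, ncfg, tcfg, verbose = FALSE) {
  stopifnot(inherits(manifest, "training_manifest"),
            inherits(ncfg, "network_config"), inherits(tcfg, "train_config"))
  if (manifest$n_pairs < 1) stop("manifest holds no training pairs")
  if (!all(manifest$image_shape == ncfg$image_size))
    stop("pair image shape does not match network image_size")
  nets <- build_networks(ncfg, seed = tcfg$seed)
  gpar <- nets$G
  dpar <- nets$D
  gstate <- dstate <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old), add = TRUE)
  set.seed(tcfg$seed + 1L)
  history <- data.frame(epoch = integer(0), loss_D = numeric(0),
                        loss_G = numeric(0), l1 = numeric(0))
  n <- manifest$n_pairs
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
    ld <- lg <- l1s <- 0
    for (bi in seq_along(batches)) {
      pairs <- load_pairs(manifest, batches[[bi]])
      x <- pairs_to_cube(pairs, "x")
      y <- pairs_to_cube(pairs, "y")
      res <- .cpp_cgan_batch_grads(gpar, dpar, x, y, ncfg$lambda,
                                   ncfg$base_channels, ncfg$generator_depth,
                                   ncfg$discriminator_patch_levels,
                                   use_norm_flag(ncfg))
      if (!all(is.finite(c(res$loss_d, res$loss_g, res$l1))))
        stop(sprintf("non-finite loss in epoch %d, batch %d (pairs %s)",
                     ep, bi, paste(batches[[bi]], collapse = ",")))
      du <- adam_update(dpar, res$d_grads, dstate, tcfg$learning_rate,
                        tcfg$beta1, tcfg$beta2)
      dpar <- du$params; dstate <- du$state
      gu <- adam_update(gpar, res$g_grads, gstate, tcfg$learning_rate,
                        tcfg$beta1, tcfg$beta2)
      gpar <- gu$params; gstate <- gu$state
      ld <- ld + res$loss_d; lg <- lg + res$loss_g; l1s <- l1s + res$l1
    }
    nb <- length(batches)
    history <- rbind(history, data.frame(epoch = ep, loss_D = ld / nb,
                                         loss_G = lg / nb, l1 = l1s / nb))
    if (verbose)
      message(sprintf("epoch %d/%d: loss_D %.4f loss_G %.4f L1 %.4f",
                      ep, tcfg$epochs, ld / nb, lg / nb, l1s / nb))
  }
  structure(list(G = gpar, D = dpar, history = history, ncfg = ncfg,
                 tcfg = tcfg, norm_range = manifest$norm_range,
                 seed = tcfg$seed),
            class = "model_artifact")
}

#' @exportS3Method base::print
print.model_artifact <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<model_artifact> %d epochs (final loss_D %.3f, loss_G %.3f, L1 %.4f), image %d px\n",
              nrow(x$history), last$loss_D, last$loss_G, last$l1,
              x$ncfg$image_size))
  invisible(x)
}

#' Run the generator on kV-like images
#'
#' @param model a `model_artifact` (or `list(G, ncfg)`).
#' @param images list of [projection_image()]s or matrices, already
#'   normalised like the training inputs (see [normalize_projections()] with
#'   `model$norm_range`).
#' @return List of prediction matrices in \[0, 1\].
#' @export
predict_generator <- function(model, images) {
  mats <- lapply(images, proj_values)
  d <- dim(mats[[1]])
  x <- array(unlist(mats), c(d[1], d[2], length(mats)))
  out <- .cpp_unet_predict(model$G, x, model$ncfg$base_channels,
                           model$ncfg$generator_depth,
                           use_norm_flag(model$ncfg))
  lapply(seq_len(dim(out)[3]), function(i) out[, , i])
}

# 1 when the config asks for instance normalisation, 0 otherwise
use_norm_flag <- function(cfg) {
  if (is.null(cfg$normalization) || identical(cfg$normalization, "instance")) 1L else 0L
}
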