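#' Default end-to-end run configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]. The defaults
#' describe a desk-scale run: a 64x64 detector, a coarse digital-pelvis
#' phantom, an 8-angle training arc with a handful of rigid augmentations and
#' a short training schedule. Full-scale values (512 px detector, 1 degree
#' arc, 100 augmentations, 20 epochs) can be set field by field or via a YAML
#' file.
#'
#' @param ... named overrides of the default fields.
#' @return A named list (class `run_config`).
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    phantom = list(),                    # phantom_spec() overrides
    geometry = list(sad = 1000, sid = 1500, detector_shape = c(64L, 64L),
                    detector_pitch = 2),
    augmentation = list(n_augment = 8L, max_shift = 10, max_rot = 10,
                        angle_step = 45),
    network = list(image_size = 64L, base_channels = 16L, generator_depth = 4L,
                   discriminator_patch_levels = 3L, lambda = 100),
    training = list(epochs = 10L, batch_size = 4L, learning_rate = 1e-3),
    test_set = list(mode = "markerless", angle_offset = 22.5,
                    shift3d = c(0, 0, 0), photons_at_max = NULL,
                    markers = list(), marker_radius = 0.6,
                    marker_attenuation = 2.0),
    threshold = 0.10
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys override [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  do.call(run_config, yaml::read_yaml(path))
}

stage_log <- function(stage, ...) {
  message(sprintf("[kvtrack] %s: %s", stage, sprintf(...)))
}

#' Run the end-to-end tracking pipeline
#'
#' Executes the full workflow on the synthetic phantom: phantom generation,
#' paired training-set construction, conditional-GAN training, test-set
#' construction (masked or markerless mode), tracking over the held-out arc,
#' and evaluation. Every stage logs its parameters; the output directory (if
#' given) receives the resolved configuration, the phantom volumes (NIfTI),
#' tracking records (CSV), the per-angle table (CSV) and the metrics summary
#' (JSON), making the artifact tree self-describing and reproducible.
#'
#' @param cfg a `run_config` (or YAML path).
#' @param verbose print per-epoch training losses.
#' @return `list(summary, records, per_angle, model, manifest, phantom,
#'   geom)` invisibly.
#' @export
run_pipeline <- function(cfg = run_config(), verbose = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  seed <- as.integer(cfg$seed)
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage_log("phantom", "seed %d", seed)
  spec <- do.call(phantom_spec, cfg$phantom)
  ph <- generate_phantom(spec, seed = seed)
  geom <- do.call(beam_geometry, cfg$geometry)

  stage_log("training-set", "%d augmentations, %g deg step, limits %g mm / %g deg",
            cfg$augmentation$n_augment, cfg$augmentation$angle_step,
            cfg$augmentation$max_shift, cfg$augmentation$max_rot)
  manifest <- build_training_set(ph$ct, ph$contour, geom,
                                 n_augment = cfg$augmentation$n_augment,
                                 max_shift = cfg$augmentation$max_shift,
                                 max_rot = cfg$augmentation$max_rot,
                                 angle_step = cfg$augmentation$angle_step,
                                 seed = seed)

  ncfg <- do.call(network_config, cfg$network)
  tcfg <- do.call(train_config, c(cfg$training, list(seed = seed)))
  stage_log("train", "%d pairs, %d epochs, batch %d, lr %g",
            manifest$n_pairs, tcfg$epochs, tcfg$batch_size, tcfg$learning_rate)
  model <- train_patient_model(manifest, ncfg, tcfg, verbose = verbose)

  ts <- cfg$test_set
  test_angles <- seq(0, 360 - cfg$augmentation$angle_step,
                     by = cfg$augmentation$angle_step) + ts$angle_offset
  stage_log("test-set", "mode %s, %d angles (offset %g deg)",
            ts$mode, length(test_angles), ts$angle_offset)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed + 2L)
  test <- if (identical(ts$mode, "masked")) {
    make_masked_testset(ph$ct, ph$contour, ts$markers, geom, test_angles,
                        marker_radius = ts$marker_radius,
                        marker_attenuation = ts$marker_attenuation,
                        photons_at_max = ts$photons_at_max)
  } else {
    make_markerless_testset(ph$ct, ph$contour, geom, test_angles,
                            shift3d = ts$shift3d,
                            photons_at_max = ts$photons_at_max)
  }
  kv_norm <- normalize_projections(test$kv, range = manifest$norm_range)$images

  stage_log("track", "threshold %g", cfg$threshold)
  records <- track_arc(model, kv_norm, test$gt, geom, angles = test_angles,
                       threshold = cfg$threshold)
  summary <- summarize_tracking(records)
  per_angle <- per_angle_stats(records, bin_deg = cfg$augmentation$angle_step)
  stage_log("evaluate", "mean DSC %.3f, AP/LAT MAD %.2f mm, SI MAD %.2f mm (%d dropped)",
            summary$dsc["mean"], summary$aplat["mad"], summary$si["mad"],
            summary$n_dropped)

  if (!is.null(out)) {
    cfg_out <- unclass(cfg)
    cfg_out$out_dir <- NULL
    jsonlite::write_json(cfg_out, file.path(out, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_volume(ph$ct, file.path(out, "phantom_ct.nii.gz"))
    write_volume(ph$contour, file.path(out, "phantom_contour.nii.gz"))
    jsonlite::write_json(ph$markers, file.path(out, "markers.json"), digits = NA)
    utils::write.csv(records, file.path(out, "records.csv"), row.names = FALSE)
    utils::write.csv(per_angle, file.path(out, "per_angle.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, n = summary$n, n_dropped = summary$n_dropped,
           aplat = as.list(summary$aplat), si = as.list(summary$si),
           dsc = as.list(summary$dsc), msd = as.list(summary$msd),
           training_history = model$history),
      file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    saveRDS(model, file.path(out, "model.rds"))
    stage_log("output", "artifact tree written to %s", out)
  }
  invisible(list(summary = summary, records = records, per_angle = per_angle,
                 model = model, manifest = manifest, phantom = ph, geom = geom))
}
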