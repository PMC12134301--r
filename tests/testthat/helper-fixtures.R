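# Shared fixtures: a coarse digital-pelvis phantom and a small test geometry.
# Built once per test run; individual tests treat them as read-only.

tiny_spec <- function(...) {
  args <- list(grid_shape = c(32L, 32L, 32L), voxel_spacing = c(6, 6, 6),
               prostate_center = c(5, 8, -6), prostate_semiaxes = c(20, 15, 18),
               body_semiaxes = c(85, 90, 75))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

test_geom <- function(...) {
  beam_geometry(sad = 1000, sid = 1500, detector_shape = c(64L, 64L),
                detector_pitch = 6, ...)
}

fixture_env <- new.env()

tiny_phantom <- function() {
  if (is.null(fixture_env$ph)) fixture_env$ph <- generate_phantom(tiny_spec(), seed = 11)
  fixture_env$ph
}

# smooth blob phantom (no bone edges) for interpolation-tolerance properties
smooth_phantom <- function() {
  if (is.null(fixture_env$smooth)) {
    dm <- c(32L, 32L, 32L)
    sp <- c(6, 6, 6)
    origin <- -(dm - 1) / 2 * sp
    ax <- origin[1] + (seq_len(dm[1]) - 1) * sp[1]
    g <- function(x, s) exp(-x^2 / (2 * s^2))
    vals <- outer(outer(g(ax, 40), g(ax, 50), `*`), g(ax, 35), `*`) * 0.02
    fixture_env$smooth <- voxel_volume(vals, sp, origin)
  }
  fixture_env$smooth
}
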