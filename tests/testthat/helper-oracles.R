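# Independent oracles, written without reference to the package internals:
# a plain-R trilinear sampler and fine-step ray integrator, plus brute-force
# mask metrics used to cross-check dice / MSD / centroids.

oracle_trilinear <- function(vol, pt) {
  f <- (pt - vol$origin) / vol$spacing
  dm <- dim(vol$values)
  if (any(f < 0) || any(f > dm - 1)) return(0)
  i0 <- pmin(pmax(floor(f), 0), dm - 2)
  d <- f - i0
  i0 <- i0 + 1
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, d, 1 - d))
    v <- v + w * vol$values[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  v
}

# dense midpoint integration along the source->pixel ray
oracle_ray_integral <- function(vol, geom, angle, iu, iv, nstep = 4000) {
  t <- angle * pi / 180
  es <- c(cos(t), 0, sin(t))
  eu <- c(sin(t), 0, -cos(t))
  src <- geom$sad * es
  nu <- geom$detector_shape[1]; nv <- geom$detector_shape[2]
  u <- (iu - (nu + 1) / 2) * geom$detector_pitch
  v <- (iv - (nv + 1) / 2) * geom$detector_pitch
  det <- src - geom$sid * es + u * eu + c(0, v, 0)
  dir <- det - src
  L <- sqrt(sum(dir^2))
  dir <- dir / L
  h <- L / nstep
  s <- (seq_len(nstep) - 0.5) * h
  sum(vapply(s, function(si) oracle_trilinear(vol, src + si * dir), 0)) * h
}

oracle_dice <- function(a, b) {
  inter <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    if (a[i, j] && b[i, j]) inter <- inter + 1
  2 * inter / (sum(a) + sum(b))
}

oracle_boundary <- function(m) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (!m[i, j]) next
    nb <- c(if (i > 1) m[i - 1, j] else FALSE,
            if (i < nrow(m)) m[i + 1, j] else FALSE,
            if (j > 1) m[i, j - 1] else FALSE,
            if (j < ncol(m)) m[i, j + 1] else FALSE)
    if (!all(nb)) out[i, j] <- TRUE
  }
  out
}

oracle_msd <- function(a, b, pitch = 1) {
  pa <- which(oracle_boundary(a), arr.ind = TRUE)
  pb <- which(oracle_boundary(b), arr.ind = TRUE)
  dmin <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      min(sqrt((p[i, 1] - q[, 1])^2 + (p[i, 2] - q[, 2])^2)), 0)
  }
  (mean(dmin(pa, pb)) + mean(dmin(pb, pa))) / 2 * pitch
}

random_blob_mask <- function(nr = 32, nc = 32) {
  # random ellipse-ish mask, occasionally empty-free by construction
  cx <- runif(1, 8, nc - 8); cy <- runif(1, 8, nr - 8)
  rx <- runif(1, 2, 6); ry <- runif(1, 2, 6)
  th <- runif(1, 0, pi)
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    x <- (j - cx) * cos(th) + (i - cy) * sin(th)
    y <- -(j - cx) * sin(th) + (i - cy) * cos(th)
    m[i, j] <- (x / rx)^2 + (y / ry)^2 <= 1
  }
  m
}
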