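# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# the mean-profile phantom voxelised at the default build spacing, with its
# segmented model and extracted mesh; reused across test files
fixture_phantom <- function(spacing = 0.25) {
  key <- paste0("ph_", spacing)
  if (is.null(.fixture_env[[key]])) {
    ph <- build_phantom(phantom_params(), spacing = spacing)
    model <- segment(ph$volume)
    mesh <- extract_surface(model)
    .fixture_env[[key]] <- list(phantom = ph, model = model, mesh = mesh)
  }
  .fixture_env[[key]]
}

# a solid voxel ball as a binary model
fixture_ball <- function(radius = 10, spacing = 0.25, margin = 2) {
  n <- ceiling(2 * (radius + margin) / spacing)
  ax <- (seq_len(n) - 0.5) * spacing - (radius + margin)
  X <- array(ax, rep(n, 3))
  Y <- array(rep(ax, each = n), rep(n, 3))
  Z <- array(rep(ax, each = n * n), rep(n, 3))
  mask <- X^2 + Y^2 + Z^2 <= radius^2
  binary_model(mask, rep(spacing, 3),
               origin = rep(-(radius + margin) + spacing / 2, 3),
               threshold_used = 0.5)
}

# rotation matrix about an arbitrary axis
rot3 <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# apply a rigid motion jointly to mesh, baseline and landmarks
transform_all <- function(mesh, bl, lmk, R = diag(3), t = c(0, 0, 0)) {
  mesh2 <- transform_mesh(mesh, R, t)
  bl2 <- baseline(point = drop(R %*% bl$point) + t,
                  direction = drop(R %*% bl$direction),
                  lateral = drop(R %*% bl$lateral))
  lmk2 <- landmark_set(
    drop(R %*% lmk$sigmoid_notch_lowest) + t,
    drop(R %*% lmk$ramus_lowest) + t,
    drop(R %*% lmk$condylion) + t,
    drop(R %*% lmk$baseline_lowest) + t,
    lmk$head_reference_level)
  attr(lmk2, "head_fraction") <- attr(lmk, "head_fraction")
  list(mesh = mesh2, bl = bl2, lmk = lmk2)
}

# independent brute-force slab extent: plain loop over vertices, no reuse of
# package internals
brute_extent <- function(vertices, point, u, dirn, level, slab) {
  lo <- Inf; hi <- -Inf
  for (i in seq_len(nrow(vertices))) {
    p <- vertices[i, ] - point
    if (abs(sum(p * u) - level) <= slab / 2) {
      s <- sum(p * dirn)
      if (s < lo) lo <- s
      if (s > hi) hi <- s
    }
  }
  if (is.finite(lo)) hi - lo else NA_real_
}

# independent brute-force Otsu: direct between-class-variance evaluation
# over the same 255 candidate bin boundaries
brute_otsu <- function(v, bins = 256L) {
  rng <- range(v)
  bw <- diff(rng) / bins
  best <- -Inf; best_thr <- NA
  for (k in 1:(bins - 1)) {
    thr <- rng[1] + k * bw
    lo <- v[v < thr]; hi <- v[v >= thr]
    if (!length(lo) || !length(hi)) next
    # class means computed from binned values, as the histogram method sees them
    centers <- rng[1] + (floor(pmin(pmax((v - rng[1]) / bw, 0), bins - 1)) + 0.5) * bw
    m0 <- mean(centers[v < thr]); m1 <- mean(centers[v >= thr])
    sb <- length(lo) * length(hi) * (m0 - m1)^2
    if (sb > best + 1e-9) { best <- sb; best_thr <- thr }
  }
  best_thr
}
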