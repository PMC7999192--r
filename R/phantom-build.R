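# Constructive-solid geometry of the condyle-ramus phantom.
#
# The phantom lives in the baseline frame: x mediolateral, y anteroposterior
# measured from the posterior baseline plane (anterior positive), z
# craniocaudal along the baseline (cranial positive).  It is the union of
# four primitives: a ramus body slab with a coned lower end, a condylar neck
# column whose posterior border is inset from the baseline at the notch level
# and nearly tangent again under the head, a thin coronoid plate carrying the
# sigmoid notch and the anterior ridge, and an ellipsoidal condylar head
# tangent to the baseline plane.  Structural shape constants are fixed
# ratios of the named parameters, so uniform scaling of all lengths scales
# the solid exactly.

# fixed shape ratios (dimensionless); anchors shown are the values they
# produce at the default FBCT mean profile
.shape <- list(
  beta_frac  = 1.9 / 21.27,    # posterior neck inset at basal level / L_basal
  gamma_frac = 0.28 / 12.07,   # head posterior clearance at top level / L_top
  vlow_frac  = 8.0 / 21.27,    # bottom apex position / L_basal
  cb_frac    = 4.5 / 10.26,    # body-top clearance below notch / neck_height
  an_frac    = 10.3 / 13.18,   # neck anterior at basal level / L_middle
  vpl0_frac  = 7.2 / 13.18,    # plate posterior edge / L_middle (overlaps
                               # the neck at every level: no plate-neck moat)
  kappa0     = 0.35 * 13.18,   # notch parabola curvature * L_middle (1/mm)
  k_bottom   = 0.08            # slope of the coned lower end
)

# Derived geometry of the constructive solid for one parameter set.
phantom_geometry <- function(p, head_fraction = 0.15) {
  f <- head_fraction
  H <- p$ramus_height; hn <- p$neck_height
  Lb <- p$neck_basal_length; Lt <- p$neck_top_length; Lm <- p$neck_middle_length
  head_height <- hn / (1 - f)
  U_n <- H - head_height            # sigmoid-notch (basal) level
  U_t <- U_n + hn                   # condylar-head reference (top) level
  U_mid <- U_n + hn / 2
  if (U_n <= 0) stop_condylometry("neck height too large for ramus height")

  beta <- .shape$beta_frac * Lb     # posterior neck inset at basal level
  gamma <- .shape$gamma_frac * Lt   # head posterior clearance at top level
  V_rf <- beta + Lb                 # ridge front face (anterior basal extreme)
  V_ta <- gamma + Lt                # head anterior extreme at top level

  # condylar head: p = 4 superellipsoid tangent to the baseline plane, top
  # at z = H, spanning [gamma, gamma + L_top] anteroposteriorly at the top
  # level; the quartic profile keeps the head's sides steep near the
  # reference level, as a condylar head is wider than it is tall
  V_c <- gamma + Lt / 2
  a_V <- V_c
  s_t <- (Lt / 2) / a_V
  q <- (max(0, 1 - s_t^4))^(1 / 4)
  d_t <- f / (1 - f) * hn
  if (q >= 1) stop_condylometry("degenerate head solve")
  a_U <- d_t / (1 - q)
  U_c <- H - a_U
  a_x <- p$head_width / 2

  A_mid <- Lm
  A_n <- .shape$an_frac * Lm
  c_a <- (A_mid - A_n) / (U_mid - U_n)^2
  c_b <- .shape$cb_frac * hn
  U_b <- U_n - c_b
  U_neck_top <- U_c
  kappa <- .shape$kappa0 / Lm
  scale <- Lb / 21.27

  V_notch_angle <- tan(p$notch_angle * pi / 180) * U_n
  V_notch <- max(V_notch_angle, A_mid + 0.15 * (Lm / 13.18))
  U_r <- U_n + p$notch_depth

  list(H = H, hn = hn, U_n = U_n, U_t = U_t, U_mid = U_mid, U_b = U_b,
       U_r = U_r, U_c = U_c, U_neck_top = U_neck_top,
       beta = beta, gamma = gamma, V_rf = V_rf, V_ta = V_ta,
       V_c = V_c, a_V = a_V, a_U = a_U, a_x = a_x,
       A_mid = A_mid, A_n = A_n, c_a = c_a, c_b = c_b,
       V_low = .shape$vlow_frac * Lb, V_pl0 = .shape$vpl0_frac * Lm,
       kappa = kappa, V_notch = V_notch,
       head_bottom = U_c - a_U, head_fraction = f, scale = scale,
       W_n = p$neck_basal_width, W_h = p$head_width, t_p = p$notch_thickness,
       k_b = .shape$k_bottom)
}

# posterior border of the neck column as a function of z
.neck_posterior <- function(z, g) {
  P <- numeric(length(z))
  lo <- z <= g$U_n
  P[lo] <- g$beta * pmax(0, z[lo] - g$U_b) / (g$U_n - g$U_b)
  mid <- z > g$U_n & z <= g$U_mid
  P[mid] <- g$beta * (g$U_mid - z[mid]) / (g$U_mid - g$U_n)
  hi <- z > g$U_mid
  P[hi] <- g$V_c * (z[hi] - g$U_mid) / (g$U_c - g$U_mid)
  P
}

# anterior border of the neck column; constant below the basal level so the
# posterior column keeps its full depth down to the ramus body
.neck_anterior <- function(z, g) g$A_mid - g$c_a * (pmax(z, g$U_n) - g$U_mid)^2

# vectorised membership test for the analytic solid
phantom_inside <- function(x, y, z, g) {
  body <- y >= 0 & y <= g$V_rf & abs(x) <= g$W_n / 2 & z <= g$U_b &
    z >= g$k_b * sqrt((y - g$V_low)^2 + x^2)
  neck <- z >= g$U_b & z <= g$U_neck_top & abs(x) <= g$W_n / 2 &
    y >= .neck_posterior(z, g) & y <= .neck_anterior(z, g)
  plate <- abs(x) <= g$t_p / 2 & y >= g$V_pl0 & y <= g$V_rf &
    z >= g$U_b - g$c_b &
    z <= pmin(g$U_n + g$kappa * (y - g$V_notch)^2, g$U_r)
  head <- (x / g$a_x)^4 + ((y - g$V_c) / g$a_V)^4 + ((z - g$U_c) / g$a_U)^4 <= 1
  body | neck | plate | head
}

# one erosion step; conn = 6 or 26
.erode_once <- function(m, conn = 6L) {
  d <- dim(m)
  pad_shift <- function(m, dx, dy, dz) {
    out <- array(FALSE, d)
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
    out
  }
  offs <- if (conn == 6L) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    o <- o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ]
    lapply(seq_len(nrow(o)), function(i) as.integer(o[i, ]))
  }
  out <- m
  for (off in offs) out <- out & pad_shift(m, off[1], off[2], off[3])
  out
}

# approximate Euclidean erosion by radius k voxels (alternating 6/26 steps)
erode_mask <- function(m, k) {
  if (k < 1) return(m)
  for (i in seq_len(k)) m <- .erode_once(m, if (i %% 3 == 0) 26L else 6L)
  m
}

#' Build a condyle phantom volume with known ground truth
#'
#' Voxelises the constructive condyle-ramus solid for one parameter set and
#' attaches the analytically known ground truth: the 11 morphometric
#' measurements, the landmark positions and the posterior baseline.  Ground
#' truth comes from the constructive geometry, not from the voxelisation;
#' [phantom_truth_numeric()] provides an independent numerical extreme-point
#' oracle on the implicit surface for cross-checking.
#'
#' The volume contains three tissue classes: a cortical shell of
#' `cortical_thickness` (approximated by morphological erosion of the bone
#' solid), trabecular interior and soft-tissue background, so its histogram
#' has exactly three modes before any blurring.
#'
#' @param params a [phantom_params()] object.
#' @param spacing isotropic build spacing in mm; must not exceed half the
#'   notch plate thickness so the thinnest structure spans at least two
#'   voxels.  Default 0.25 mm, finer than either simulated modality.
#' @param margin soft-tissue margin around the bone (mm).
#' @return A list with elements `volume` (a [density_volume()]) and `truth`
#'   (a `ground_truth` object with `params`, `true_measurements`,
#'   `landmarks` and `baseline_true`).
#' @export
#' @examples
#' \donttest{
#' ph <- build_phantom(phantom_params(), spacing = 0.5)
#' ph$truth$true_measurements[["thickness_sigmoid_notch"]]
#' }
build_phantom <- function(params, spacing = 0.25, margin = 3) {
  validate_phantom_params(params)
  if (spacing > params$notch_thickness / 2)
    stop_condylometry(sprintf(
      "spacing %.3g mm too coarse: the %.3g mm notch plate must span >= 2 voxels",
      spacing, params$notch_thickness))
  g <- phantom_geometry(params)
  margin <- max(margin, 3 * spacing)

  # x grid symmetric about the sagittal midplane (odd voxel count, centre
  # voxel at x = 0) so that mirroring a volume is an exact reflection
  n_half <- ceiling((g$W_h / 2 + margin) / spacing)
  xs <- (-n_half:n_half) * spacing
  lo <- c(xs[1] - spacing / 2, -margin, -margin)
  hi <- c(xs[length(xs)] + spacing / 2, g$V_rf + margin, g$H + margin)
  n <- c(length(xs), ceiling((hi[2:3] - lo[2:3]) / spacing))
  origin <- c(xs[1], lo[2:3] + spacing / 2)
  ys <- origin[2] + (seq_len(n[2]) - 1) * spacing
  zs <- origin[3] + (seq_len(n[3]) - 1) * spacing

  X <- array(xs, n)
  Y <- array(rep(ys, each = n[1]), n)
  Z <- array(rep(zs, each = n[1] * n[2]), n)
  inside <- phantom_inside(X, Y, Z, g)
  rm(X, Y, Z)

  k <- round(params$cortical_thickness / spacing)
  interior <- erode_mask(inside, k)

  vox <- array(params$density_soft, n)
  vox[inside] <- params$density_cortical
  vox[interior] <- params$density_trabecular

  vol <- density_volume(vox, spacing = rep(spacing, 3), origin = origin)
  truth <- phantom_truth(params, g)
  list(volume = vol, truth = truth)
}

# Analytic ground truth from the constructive geometry.
phantom_truth <- function(params, g = phantom_geometry(params)) {
  m <- c(
    length_neck_basal = params$neck_basal_length,
    length_neck_top = params$neck_top_length,
    distance_sigmoidnotch_necktop = sqrt((g$V_rf - g$V_ta)^2 + g$hn^2),
    height_neck = g$hn,
    length_neck_middle = params$neck_middle_length,
    ramus_height = params$ramus_height,
    width_neck_basal = params$neck_basal_width,
    width_head = params$head_width,
    thickness_sigmoid_notch = params$notch_thickness,
    angle_posteriorline_notchpoint = atan2(g$V_notch, g$U_n) * 180 / pi,
    height_neck_new_classification = g$U_t - g$V_ta * g$U_n / g$V_notch)
  lm <- list(
    sigmoid_notch_lowest = c(0, g$V_notch, g$U_n),
    ramus_lowest = c(0, g$V_low, 0),
    condylion = c(0, g$V_c, g$H),
    baseline_lowest = c(0, 0, 0),
    head_reference_level = g$U_t)
  structure(list(params = params,
                 true_measurements = measurement_set(m),
                 landmarks = lm,
                 baseline_true = baseline(point = c(0, 0, 0),
                                          direction = c(0, 0, 1),
                                          lateral = c(1, 0, 0))),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> analytic condyle phantom truth\n")
  print(x$true_measurements)
  invisible(x)
}

# extent helpers on sampled planes of the implicit solid
.plane_extent <- function(g, level, step, what = c("v", "w"), v_window = NULL) {
  what <- match.arg(what)
  xs <- seq(-g$W_h / 2 - 0.5, g$W_h / 2 + 0.5, by = step)
  ys <- seq(-0.5, g$V_rf + 0.5, by = step)
  if (!is.null(v_window)) ys <- ys[ys >= v_window[1] & ys <= v_window[2]]
  XX <- matrix(xs, nrow = length(xs), ncol = length(ys))
  YY <- matrix(ys, nrow = length(xs), ncol = length(ys), byrow = TRUE)
  ins <- phantom_inside(XX, YY, array(level, dim(XX)), g)
  if (!any(ins)) return(NA_real_)
  if (what == "v") diff(range(YY[ins])) else diff(range(XX[ins]))
}

#' Numerical ground-truth oracle on the implicit phantom surface
#'
#' Recomputes the 11 ground-truth measurements by dense extreme-point search
#' on the analytic implicit solid (planar sampling at `step` mm plus the
#' head-region slab sweep), independently of both the voxelisation and the
#' closed-form truth expressions.  Used to verify that the shipped analytic
#' truth is consistent with the implicit surface to well under 0.05 mm.
#'
#' @param params a [phantom_params()] object.
#' @param step sampling step in mm (default 0.02).
#' @return Named numeric vector of the 11 measurements.
#' @export
phantom_truth_numeric <- function(params, step = 0.02) {
  g <- phantom_geometry(params)

  # sagittal plane x = 0: craniocaudal extent and the notch floor
  ys <- seq(-0.5, g$V_rf + 0.5, by = step)
  zs <- seq(-0.5, g$H + 0.5, by = step)
  YY <- matrix(ys, nrow = length(ys), ncol = length(zs))
  ZZ <- matrix(zs, nrow = length(ys), ncol = length(zs), byrow = TRUE)
  ins <- phantom_inside(array(0, dim(YY)), YY, ZZ, g)
  zr <- range(ZZ[ins])
  ramus_height <- diff(zr)

  # upper envelope along y and its interior local minimum (the notch floor)
  env <- apply(ins, 1, function(row) if (any(row)) max(zs[row]) else -Inf)
  ok <- is.finite(env)
  run_max_left <- cummax(ifelse(ok, env, -Inf))
  run_max_right <- rev(cummax(rev(ifelse(ok, env, -Inf))))
  prom <- pmin(run_max_left, run_max_right) - env
  cand <- which(ok & prom > 0.5)
  if (!length(cand)) stop_condylometry("numerical oracle found no notch")
  i_n <- cand[which.min(env[cand])]
  # local refinement of the notch floor on a fine sagittal grid
  ys_f <- seq(ys[i_n] - 2 * step, ys[i_n] + 2 * step, by = step / 20)
  env_f <- vapply(ys_f, function(yy) {
    zz <- seq(env[i_n] - 2 * step, env[i_n] + 2 * step, by = step / 20)
    ins_f <- phantom_inside(numeric(length(zz)), rep(yy, length(zz)), zz, g)
    if (any(ins_f)) max(zz[ins_f]) else Inf
  }, 0)
  # the floor is locally quadratic and flat near its apex; a parabola fit on
  # the fine envelope resolves the apex far below the grid resolution
  okf <- is.finite(env_f)
  if (sum(okf) >= 5) {
    cf <- as.numeric(coef(lm(env_f[okf] ~ ys_f[okf] + I(ys_f[okf]^2))))
    if (is.finite(cf[3]) && cf[3] > 0 &&
        abs(-cf[2] / (2 * cf[3]) - ys_f[which.min(env_f)]) < 4 * step) {
      V_notch_num <- -cf[2] / (2 * cf[3])
      U_n_num <- sum(cf * c(1, V_notch_num, V_notch_num^2))
    } else {
      j <- which.min(env_f); V_notch_num <- ys_f[j]; U_n_num <- env_f[j]
    }
  } else {
    j <- which.min(env_f); V_notch_num <- ys_f[j]; U_n_num <- env_f[j]
  }
  # refine the craniocaudal extremes the same way
  refine_z <- function(z0, sign) {
    zz <- seq(z0 - 2 * step, z0 + 2 * step, by = step / 20)
    yy <- seq(-0.5, g$V_rf + 0.5, by = step)
    YYf <- matrix(yy, nrow = length(yy), ncol = length(zz))
    ZZf <- matrix(zz, nrow = length(yy), ncol = length(zz), byrow = TRUE)
    insf <- phantom_inside(array(0, dim(YYf)), YYf, ZZf, g)
    if (!any(insf)) return(z0)
    if (sign > 0) max(ZZf[insf]) else min(ZZf[insf])
  }
  zr <- c(refine_z(zr[1], -1), refine_z(zr[2], 1))
  ramus_height <- diff(zr)
  U_c_top <- zr[2]
  U_t_num <- U_c_top - g$head_fraction * (U_c_top - U_n_num)

  basal_v <- .plane_extent(g, U_n_num, step, "v")
  basal_w <- .plane_extent(g, U_n_num, step, "w")
  top_v <- .plane_extent(g, U_t_num, step, "v")
  mid_v <- .plane_extent(g, (U_n_num + U_t_num) / 2, step, "v")
  thick_w <- .plane_extent(g, U_n_num - 1, step / 2, "w",
                           v_window = V_notch_num + c(-1, 1))

  # most anterior points of the basal and top planes
  ant_at <- function(level) {
    ys2 <- seq(-0.5, g$V_rf + 0.5, by = step / 10)
    ins2 <- phantom_inside(numeric(length(ys2)), ys2, rep(level, length(ys2)), g)
    max(ys2[ins2])
  }
  V_ba <- ant_at(U_n_num); V_tafwd <- ant_at(U_t_num)
  dist_nt <- sqrt((V_ba - V_tafwd)^2 + (U_t_num - U_n_num)^2)

  # widest head slab: coarse sweep of z through the head region, then a fine
  # sweep around the coarse optimum (x sampled at `step` so the width itself
  # is resolved finely; y can be coarser, the width varies smoothly with y)
  xs <- seq(-g$W_h / 2 - 0.5, g$W_h / 2 + 0.5, by = step)
  yc <- seq(-0.5, g$V_rf + 0.5, by = max(step, 0.1))
  XX <- matrix(xs, nrow = length(xs), ncol = length(yc))
  YY2 <- matrix(yc, nrow = length(xs), ncol = length(yc), byrow = TRUE)
  width_at <- function(z) {
    insz <- phantom_inside(XX, YY2, array(z, dim(XX)), g)
    if (any(insz)) diff(range(XX[insz])) else 0
  }
  zc <- seq(U_n_num, zr[2], by = 0.2)
  wc <- vapply(zc, width_at, 0)
  z0 <- zc[which.max(wc)]
  zf <- seq(max(U_n_num, z0 - 0.25), min(zr[2], z0 + 0.25), by = step)
  wmax <- max(wc, vapply(zf, width_at, 0))

  angle <- atan2(V_notch_num, U_n_num - zr[1]) * 180 / pi
  hnn <- abs(U_t_num - (zr[1] + (U_n_num - zr[1]) * V_tafwd / V_notch_num))

  c(length_neck_basal = basal_v,
    length_neck_top = top_v,
    distance_sigmoidnotch_necktop = dist_nt,
    height_neck = U_t_num - U_n_num,
    length_neck_middle = mid_v,
    ramus_height = ramus_height,
    width_neck_basal = basal_w,
    width_head = wmax,
    thickness_sigmoid_notch = thick_w,
    angle_posteriorline_notchpoint = angle,
    height_neck_new_classification = hnn)
}

#' Mirror a phantom volume across the sagittal midplane
#'
#' Produces the contralateral condyle of a subject by reflecting the volume
#' along the mediolateral axis.  The constructive phantom is mirror
#' symmetric, so all ground-truth measurements are unchanged.
#'
#' @param vol a [density_volume()].
#' @return The reflected [density_volume()].
#' @export
mirror_volume <- function(vol) {
  stopifnot(inherits(vol, "density_volume"))
  d <- dim(vol$voxels)
  flipped <- vol$voxels[d[1]:1, , , drop = FALSE]
  xmax <- vol$origin[1] + (d[1] - 1) * vol$spacing[1]
  density_volume(flipped, vol$spacing,
                 origin = c(-xmax, vol$origin[2], vol$origin[3]))
}

#' Write phantom ground truth as JSON
#'
#' Serialises the parameter set, landmark positions (mm triplets) and the 11
#' true measurements (keyed by the canonical measurement names in lower snake
#' case) to a JSON file.
#'
#' @param truth a `ground_truth` object from [build_phantom()].
#' @param file output path.
#' @export
write_ground_truth <- function(truth, file) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(
    params = unclass(truth$params),
    landmarks = truth$landmarks,
    true_measurements = as.list(unclass(truth$true_measurements)),
    baseline = truth$baseline_true[c("point", "direction")])
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
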