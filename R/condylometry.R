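# The condylar morphometry protocol: posterior ramus baseline construction,
# landmark detection and the 11 measurements, all defined relative to the
# baseline frame (u along the baseline, cranial; v perpendicular in the
# sagittal plane, anterior; w mediolateral).

canonical_measurements <- c(
  "length_neck_basal", "length_neck_top", "distance_sigmoidnotch_necktop",
  "height_neck", "length_neck_middle", "ramus_height", "width_neck_basal",
  "width_head", "thickness_sigmoid_notch", "angle_posteriorline_notchpoint",
  "height_neck_new_classification")

#' The 11-measurement set of one condyle
#'
#' A named numeric vector (mm, except the angle in degrees) over the
#' canonical measurement names, in canonical order.
#'
#' @param x named numeric vector covering the canonical names.
#' @return An object of class `measurement_set`.
#' @export
measurement_set <- function(x) {
  miss <- setdiff(canonical_measurements, names(x))
  if (length(miss))
    stop_condylometry(paste("missing measurements:", paste(miss, collapse = ", ")))
  structure(as.numeric(x[canonical_measurements]),
            names = canonical_measurements, class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("<measurement_set> (mm; angle in degrees)\n")
  for (nm in canonical_measurements)
    cat(sprintf("  %-32s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA", sprintf("%8.3f", x[[nm]]))))
  invisible(x)
}

#' Posterior ramus baseline
#'
#' @param point a point on the line (mm).
#' @param direction unit direction, cranially oriented, zero mediolateral
#'   component in the standard frame.
#' @param lateral unit mediolateral axis of the measurement frame (rotates
#'   with the mesh under rigid motion).
#' @return An object of class `baseline`.
#' @export
baseline <- function(point, direction, lateral = c(1, 0, 0)) {
  direction <- direction / sqrt(sum(direction^2))
  lateral <- lateral / sqrt(sum(lateral^2))
  structure(list(point = as.numeric(point), direction = as.numeric(direction),
                 lateral = as.numeric(lateral)),
            class = "baseline")
}

#' @export
print.baseline <- function(x, ...) {
  cat(sprintf("<baseline> point (%s), direction (%s)\n",
              paste(signif(x$point, 5), collapse = ", "),
              paste(signif(x$direction, 5), collapse = ", ")))
  invisible(x)
}

# anterior in-plane unit vector of the baseline frame
.baseline_v <- function(bl) {
  u <- bl$direction; w <- bl$lateral
  v <- c(u[2] * w[3] - u[3] * w[2],
         u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  v / sqrt(sum(v^2))
}

#' Fit the posterior ramus baseline to a condyle mesh
#'
#' Projects all vertices to the sagittal plane and returns the posterior
#' tangent line: the edge of the projection's 2-D convex hull that has every
#' vertex on its anterior side and is the most nearly craniocaudal such edge.
#' Ties are broken towards the edge with the more posterior supporting
#' point.  The direction is normalised cranially.
#'
#' @param mesh a [surface_mesh()] in the standard frame (x mediolateral, y
#'   anteroposterior anterior-positive, z craniocaudal cranial-positive).
#' @return A [baseline()].  The supporting vertex indices are attached as
#'   attribute `support` for audit.
#' @export
fit_baseline <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  p <- mesh$vertices[, 2:3, drop = FALSE]     # sagittal projection (y, z)
  keep <- !duplicated(round(p, 9))
  pu <- p[keep, , drop = FALSE]
  if (nrow(pu) < 3)
    stop_condylometry("degenerate mesh: fewer than 3 distinct sagittal points")
  h <- grDevices::chull(pu[, 1], pu[, 2])
  if (length(h) < 3)
    stop_condylometry("degenerate mesh: collinear sagittal projection")
  hp <- pu[h, , drop = FALSE]
  nh <- nrow(hp)
  # candidate edges must be longer than the voxel-rounding scale: the
  # iso-surface rounds corners into short arcs whose facets can be more
  # craniocaudal than the true posterior border
  min_len <- 2 * (mesh$provenance$voxel %||% 0.5)
  for (pass in 1:2) {
  best <- NULL
  for (i in seq_len(nh)) {
    a <- hp[i, ]; b <- hp[if (i == nh) 1L else i + 1L, ]
    d <- b - a
    len <- sqrt(sum(d^2))
    if (len < 1e-12 || (pass == 1L && len < min_len)) next
    d <- d / len
    # inward normal candidates; pick the one pointing towards the hull
    n1 <- c(d[2], -d[1])
    ctr <- colMeans(hp)
    m <- if (sum((ctr - a) * n1) > 0) n1 else -n1
    if (m[1] <= 1e-9) next                   # anterior side requires m_y > 0
    score <- abs(d[2])                        # |craniocaudal component|
    post <- min(a[1], b[1])                   # tie-break: more posterior
    if (is.null(best) || score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 && post < best$post)) {
      dir2 <- if (d[2] >= 0) d else -d        # cranial orientation
      best <- list(score = score, post = post, a = a, b = b, dir2 = dir2)
    }
  }
  if (!is.null(best)) break
  }
  if (is.null(best))
    stop_condylometry("no posterior supporting edge found")
  pt <- if (best$a[2] <= best$b[2]) best$a else best$b
  bl <- baseline(point = c(0, pt[1], pt[2]),
                 direction = c(0, best$dir2[1], best$dir2[2]),
                 lateral = c(1, 0, 0))
  attr(bl, "support") <- rbind(best$a, best$b)
  bl
}

#' Landmark set of one condyle
#'
#' Positions in mm: the lowest point of the sigmoid (semilunar) notch, the
#' lowest ramus point, the condylion (highest point), the lowest point on
#' the baseline (projection of the ramus lowest point onto the line) and the
#' condylar-head reference level, stored as a coordinate along the baseline
#' direction measured from the baseline's reference point.
#'
#' @param sigmoid_notch_lowest,ramus_lowest,condylion,baseline_lowest mm
#'   points.
#' @param head_reference_level scalar u-coordinate (mm along the baseline).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(sigmoid_notch_lowest, ramus_lowest, condylion,
                         baseline_lowest, head_reference_level) {
  structure(list(sigmoid_notch_lowest = as.numeric(sigmoid_notch_lowest),
                 ramus_lowest = as.numeric(ramus_lowest),
                 condylion = as.numeric(condylion),
                 baseline_lowest = as.numeric(baseline_lowest),
                 head_reference_level = as.numeric(head_reference_level)),
            class = "landmark_set")
}

#' Detect the condylar landmarks on a mesh
#'
#' The ramus lowest point and condylion are the extreme vertices along the
#' baseline direction.  The sigmoid-notch lowest point is found on the upper
#' envelope of the sagittal profile: vertices are binned along the
#' anteroposterior axis, the per-bin maximum height forms the envelope, and
#' the deepest interior local minimum with sufficient prominence is the
#' notch floor (vertices at the floor are averaged, which centres the
#' landmark mediolaterally on symmetric anatomy).  A convex profile has no
#' such minimum and raises a "no sigmoid notch" error.  The condylar-head
#' reference level is placed `head_fraction` of the head height (condylion
#' to notch, along the baseline) below the condylion.
#'
#' @param mesh a [surface_mesh()].
#' @param bl a [baseline()], typically from [fit_baseline()].
#' @param head_fraction fraction of the head height defining the reference
#'   level (default 0.15).
#' @param bin envelope bin width in mm; defaults to the mesh's voxel width.
#' @param prominence minimum envelope prominence (mm) for the notch;
#'   defaults to twice the bin width.
#' @return A [landmark_set()].
#' @export
detect_landmarks <- function(mesh, bl, head_fraction = 0.15, bin = NULL,
                             prominence = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(bl, "baseline"))
  vx <- mesh$vertices
  u <- bl$direction; v <- .baseline_v(bl)
  rel <- sweep(vx, 2, bl$point, "-")
  U <- drop(rel %*% u); V <- drop(rel %*% v)

  # extreme landmarks as centroids of the extreme cluster: robust when the
  # extreme surface is locally flat (e.g. the top of the condylar head)
  ext_cluster <- function(idx) colMeans(vx[idx, , drop = FALSE])
  U_max <- max(U); U_min <- min(U)
  tol0 <- 0.25 * (mesh$provenance$voxel %||% 0.5)
  condylion <- ext_cluster(which(U >= U_max - tol0))
  ramus_lowest <- ext_cluster(which(U <= U_min + tol0))
  baseline_lowest <- bl$point + sum((ramus_lowest - bl$point) * u) * u

  bin <- bin %||% (mesh$provenance$voxel %||% 0.5)
  prominence <- prominence %||% (2 * bin)
  br <- range(V)
  nb <- max(3L, ceiling(diff(br) / bin))
  bidx <- pmin(pmax(1L, 1L + floor((V - br[1]) / bin)), nb)
  env <- rep(-Inf, nb)
  agg <- tapply(U, bidx, max)
  env[as.integer(names(agg))] <- agg
  ok <- is.finite(env)
  left <- cummax(ifelse(ok, env, -Inf))
  right <- rev(cummax(rev(ifelse(ok, env, -Inf))))
  prom <- pmin(left, right) - env
  cand <- which(ok & prom >= prominence)
  if (!length(cand))
    stop_condylometry("no sigmoid notch: anterior profile has no concavity",
                      "condylometry_notch_error")
  b_star <- cand[which.min(env[cand])]
  V_star <- br[1] + (b_star - 0.5) * bin
  # sub-voxel refinement: fit a parabola to the local top-edge envelope
  # (the notch floor is locally quadratic) and take its apex
  w_axis <- bl$lateral
  Wc <- drop(rel %*% w_axis)
  near <- which(abs(V - V_star) <= max(2, 4 * bin) &
                U <= env[b_star] + 2 * bin)
  notch <- NULL
  if (length(near) >= 6) {
    # per-sub-bin top-edge points of the notch floor, restricted to a band
    # around the envelope minimum so that plate-wall vertices (where the
    # upper cap truncates the edge) cannot contaminate the fit
    sub <- bin / 4
    sb <- round((V[near] - V_star) / sub)
    top <- tapply(seq_along(near), sb, function(ii) near[ii][which.max(U[near][ii])])
    ti <- as.integer(top)
    ti <- ti[abs(U[ti] - env[b_star]) <= 1.5 * bin]
    if (length(ti) >= 5) {
      fit <- try(lm(U[ti] ~ V[ti] + I(V[ti]^2)), silent = TRUE)
      if (!inherits(fit, "try-error") && all(is.finite(coef(fit))) &&
          coef(fit)[3] > 0) {
        apex <- -coef(fit)[2] / (2 * coef(fit)[3])
        if (apex >= min(V[ti]) - bin && apex <= max(V[ti]) + bin) {
          U_apex <- sum(coef(fit) * c(1, apex, apex^2))
          x_bar <- mean(Wc[ti])
          notch <- bl$point + U_apex * u + apex * .baseline_v(bl) +
            x_bar * w_axis
        }
      }
    }
  }
  if (is.null(notch)) {
    in_bin <- which(bidx == b_star & U >= env[b_star] - bin / 2)
    notch <- colMeans(vx[in_bin, , drop = FALSE])
  }

  U_notch <- sum((notch - bl$point) * u)
  U_top <- U_max
  if (!(U_min < U_notch && U_notch < U_top))
    stop_condylometry("landmark ordering violated: notch outside ramus span")
  head_ref <- U_top - head_fraction * (U_top - U_notch)
  lm <- landmark_set(notch, ramus_lowest, condylion, baseline_lowest, head_ref)
  attr(lm, "head_fraction") <- head_fraction
  lm
}

#' Compute the 11 condylar measurements
#'
#' All measurements are taken in the baseline frame (u along the baseline,
#' v anteroposterior, w mediolateral).  A "level" is a slab of one voxel
#' thickness perpendicular to u; extents are vertex-based.  In canonical
#' order: basal, top and middle neck lengths are v-extents of the slabs
#' through the notch, the head reference level and their midpoint; the
#' notch-to-neck-top distance joins the most anterior points of the basal
#' and top slabs; neck height is the u-distance between those levels; ramus
#' height the total u-extent; basal neck width the w-extent of the basal
#' slab; head width the maximal per-slab w-extent over the head region
#' (above the notch level); sigmoid-notch thickness the w-extent of the slab
#' 1 mm below the notch restricted to an anteroposterior window of +/- 1 mm
#' around the notch (the local thin-plate thickness); the posterior-line
#' angle is taken at the lowest baseline point between the baseline and the
#' ray to the notch; and the corresponding-angles neck height is the
#' distance, parallel to the baseline, from the most anterior point of the
#' top level to that ray (the medial arm).
#'
#' Failed measurements (an empty slab at a required level) are set to `NA`
#' with a warning naming the level; the remaining measurements are still
#' returned.
#'
#' @param mesh a [surface_mesh()].
#' @param bl a [baseline()].
#' @param landmarks a [landmark_set()].
#' @param slab slab thickness in mm; defaults to the mesh's voxel width.
#' @param notch_window half-width (mm) of the anteroposterior window used
#'   for the notch-thickness measurement (default 1).
#' @param notch_offset distance (mm) below the notch at which the plate
#'   thickness is taken (protocol constant, default 1).
#' @return A [measurement_set()]; failed entries are `NA` and listed in the
#'   `errors` attribute.
#' @export
measure <- function(mesh, bl, landmarks, slab = NULL, notch_window = 1,
                    notch_offset = 1) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(bl, "baseline"),
            inherits(landmarks, "landmark_set"))
  slab <- slab %||% (mesh$provenance$voxel %||% 0.5)
  vx <- mesh$vertices
  u <- bl$direction; v <- .baseline_v(bl); w <- bl$lateral
  rel <- sweep(vx, 2, bl$point, "-")
  # projected coordinates rounded to 1e-6 mm so that slab membership
  # decisions are stable under rigid motions (floating-point rotation noise
  # cannot flip a vertex across a slab boundary)
  rnd <- function(x) round(x * 1e6) / 1e6
  U <- rnd(drop(rel %*% u)); V <- rnd(drop(rel %*% v)); W <- rnd(drop(rel %*% w))

  U_notch <- rnd(sum((landmarks$sigmoid_notch_lowest - bl$point) * u))
  V_notch <- rnd(sum((landmarks$sigmoid_notch_lowest - bl$point) * v))
  U_top <- rnd(landmarks$head_reference_level)
  U_base <- rnd(sum((landmarks$baseline_lowest - bl$point) * u))
  U_mid <- (U_notch + U_top) / 2
  U_max <- max(U)

  errs <- character(0)
  out <- setNames(rep(NA_real_, length(canonical_measurements)),
                  canonical_measurements)
  slab_at <- function(level, what) {
    idx <- which(abs(U - level) <= slab / 2)
    if (!length(idx)) {
      errs[[length(errs) + 1L]] <<- sprintf(
        "%s: empty slab at u = %.3f mm", what, level)
      return(NULL)
    }
    idx
  }
  try_set <- function(nm, val) out[[nm]] <<- val

  ib <- slab_at(U_notch, "length_neck_basal")
  it <- slab_at(U_top, "length_neck_top")
  im <- slab_at(U_mid, "length_neck_middle")
  if (!is.null(ib)) {
    try_set("length_neck_basal", diff(range(V[ib])))
    try_set("width_neck_basal", diff(range(W[ib])))
  }
  if (!is.null(it)) try_set("length_neck_top", diff(range(V[it])))
  if (!is.null(im)) try_set("length_neck_middle", diff(range(V[im])))

  # most anterior point of a level, interpolated to the exact level: the
  # anterior boundary is locally linear in u, so a vertex-based extreme
  # carries a half-slab bias that a short linear fit removes
  level_anterior <- function(idx, level) {
    j <- idx[V[idx] >= max(V[idx]) - slab]
    Vl <- max(V[idx])
    if (length(j) >= 4 && diff(range(U[j])) > slab / 4) {
      fit <- try(lm(V[j] ~ U[j]), silent = TRUE)
      if (!inherits(fit, "try-error") && all(is.finite(coef(fit)))) {
        cand <- sum(coef(fit) * c(1, level))
        if (abs(cand - Vl) <= slab) Vl <- cand
      }
    }
    bl$point + level * u + Vl * v + W[idx[which.max(V[idx])]] * w
  }
  if (!is.null(ib) && !is.null(it)) {
    pa_b <- level_anterior(ib, U_notch)
    pa_t <- level_anterior(it, U_top)
    try_set("distance_sigmoidnotch_necktop", sqrt(sum((pa_b - pa_t)^2)))
  }
  try_set("height_neck", abs(U_top - U_notch))
  try_set("ramus_height", diff(range(U)))

  # widest head slab above the notch level
  head_idx <- which(U >= U_notch - slab / 2)
  if (length(head_idx)) {
    levels <- seq(U_notch, U_max, by = slab)
    wmax <- 0
    for (lv in levels) {
      idx <- head_idx[abs(U[head_idx] - lv) <= slab / 2]
      if (length(idx) > 1) wmax <- max(wmax, diff(range(W[idx])))
    }
    try_set("width_head", wmax)
  } else errs[[length(errs) + 1L]] <- "width_head: empty head region"

  # local plate thickness: minimum mediolateral extent over overlapping
  # anteroposterior sub-slabs of the notch window, so that the thin bone is
  # measured at its thinnest point and concave plate-neck fillets (partial
  # volume webbing under heavy blur) cannot inflate it
  ith_lvl <- U_notch - notch_offset
  ith <- which(abs(U - ith_lvl) <= slab / 2 & abs(V - V_notch) <= notch_window)
  th <- Inf
  if (length(ith) > 1) {
    centers <- seq(V_notch - notch_window + slab / 2,
                   V_notch + notch_window - slab / 2, by = slab / 2)
    if (!length(centers)) centers <- V_notch
    for (cv in centers) {
      jj <- ith[abs(V[ith] - cv) <= slab / 2]
      if (length(jj) >= 6) th <- min(th, diff(range(W[jj])))
    }
    if (!is.finite(th)) th <- diff(range(W[ith]))
    try_set("thickness_sigmoid_notch", th)
  } else errs[[length(errs) + 1L]] <- sprintf(
    "thickness_sigmoid_notch: empty slab at u = %.3f mm", ith_lvl)

  # angle taken in the sagittal plane of the baseline frame, as in the
  # cephalometric construction
  ray <- landmarks$sigmoid_notch_lowest - landmarks$baseline_lowest
  try_set("angle_posteriorline_notchpoint",
          atan2(abs(sum(ray * v)), sum(ray * u)) * 180 / pi)

  if (!is.null(it) && V_notch > 1e-9) {
    pa_t <- level_anterior(it, U_top)
    U_t_fwd <- sum((pa_t - bl$point) * u)
    V_t_fwd <- sum((pa_t - bl$point) * v)
    U_int <- U_base + (U_notch - U_base) * (V_t_fwd / V_notch)
    try_set("height_neck_new_classification", abs(U_t_fwd - U_int))
  }

  res <- measurement_set(out)
  if (length(errs)) {
    warning(paste("measurement errors:", paste(errs, collapse = "; ")),
            call. = FALSE)
    attr(res, "errors") <- errs
  }
  attr(res, "slab") <- slab
  attr(res, "head_fraction") <- attr(landmarks, "head_fraction") %||% NA_real_
  attr(res, "interpretation_dependent") <- "height_neck_new_classification"
  res
}

#' Measure a condyle mesh end to end
#'
#' Convenience wrapper: fits the baseline, detects landmarks and computes the
#' 11 measurements.
#'
#' @inheritParams detect_landmarks
#' @inheritParams measure
#' @return A [measurement_set()] with the baseline and landmarks attached as
#'   attributes.
#' @export
measure_condyle <- function(mesh, head_fraction = 0.15, slab = NULL) {
  bl <- fit_baseline(mesh)
  lm <- detect_landmarks(mesh, bl, head_fraction = head_fraction)
  res <- measure(mesh, bl, lm, slab = slab)
  attr(res, "baseline") <- bl
  attr(res, "landmarks") <- lm
  res
}
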