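# voxel box mask -> mesh, for simple oracle geometries
box_mesh <- function(wx, wy, wz, spacing = 1) {
  n <- ceiling(c(wx, wy, wz) / spacing) + 4
  X <- array((seq_len(n[1]) - 0.5) * spacing, n)
  Y <- array(rep((seq_len(n[2]) - 0.5) * spacing, each = n[1]), n)
  Z <- array(rep((seq_len(n[3]) - 0.5) * spacing, each = n[1] * n[2]), n)
  mask <- X > spacing & X <= wx + spacing & Y > spacing & Y <= wy + spacing &
    Z > spacing & Z <= wz + spacing
  extract_surface(binary_model(mask, rep(spacing, 3),
                               origin = rep(spacing / 2, 3)))
}

test_that("baseline of an axis-aligned box is its posterior vertical edge", {
  mesh <- box_mesh(10, 20, 30)
  bl <- fit_baseline(mesh)
  expect_equal(abs(bl$direction), c(0, 0, 1), tolerance = 1e-6)
  expect_gt(bl$direction[3], 0)
  # posterior face sits at the minimal y of the mesh
  expect_equal(bl$point[2], min(mesh$vertices[, 2]), tolerance = 1e-6)
})

test_that("every vertex lies on the anterior side of the fitted baseline", {
  mesh <- fixture_phantom()$mesh
  bl <- fit_baseline(mesh)
  v <- condylometry:::.baseline_v(bl)
  signed <- drop(sweep(mesh$vertices, 2, bl$point, "-") %*% v)
  expect_gt(min(signed), -1e-6)
})

test_that("baseline direction is equivariant under mediolateral rotation", {
  # a box keeps its posterior face as the unique posterior support under
  # moderate rotations, so the fitted line must rotate exactly with it.
  # (On a condyle, tipping the anatomy changes which structures support the
  # posterior tangent -- the line is attitude-dependent by construction.)
  mesh <- box_mesh(10, 20, 30, spacing = 0.5)
  bl <- fit_baseline(mesh)
  for (ang in c(10, -10) * pi / 180) {
    R <- rot3(c(1, 0, 0), ang)
    bl2 <- fit_baseline(transform_mesh(mesh, R))
    expect_equal(drop(R %*% bl$direction), bl2$direction, tolerance = 1e-3)
  }
})

test_that("detected landmarks fall within two voxel widths of ground truth", {
  fx <- fixture_phantom()
  bl <- fit_baseline(fx$mesh)
  lmk <- detect_landmarks(fx$mesh, bl)
  tru <- fx$phantom$truth$landmarks
  tol <- 2 * max(fx$model$spacing)
  for (nm in c("sigmoid_notch_lowest", "ramus_lowest", "condylion",
               "baseline_lowest"))
    expect_lt(sqrt(sum((lmk[[nm]] - tru[[nm]])^2)), tol)
  # reference level compared as an absolute position along the baseline
  lvl <- (bl$point + lmk$head_reference_level * bl$direction)[3]
  expect_lt(abs(lvl - tru$head_reference_level), tol)
})

test_that("a convex mesh has no sigmoid notch", {
  ball <- fixture_ball(radius = 6, spacing = 0.5)
  mesh <- extract_surface(ball)
  bl <- fit_baseline(mesh)
  expect_error(detect_landmarks(mesh, bl), "no sigmoid notch")
})

test_that("landmarks translate with the mesh", {
  mesh <- fixture_phantom(0.5)$mesh
  bl <- fit_baseline(mesh)
  lmk <- detect_landmarks(mesh, bl)
  t <- c(5, 5, 5)
  mesh2 <- transform_mesh(mesh, diag(3), t)
  lmk2 <- detect_landmarks(mesh2, fit_baseline(mesh2))
  for (nm in c("sigmoid_notch_lowest", "ramus_lowest", "condylion"))
    expect_equal(lmk2[[nm]], lmk[[nm]] + t, tolerance = 1e-6)
})

test_that("box measurements match hand values, with a notch on the baseline", {
  mesh <- box_mesh(10, 20, 30, spacing = 0.5)
  bl <- fit_baseline(mesh)
  ylo <- min(mesh$vertices[, 2]); zlo <- min(mesh$vertices[, 3])
  zhi <- max(mesh$vertices[, 3])
  lmk <- landmark_set(
    sigmoid_notch_lowest = c(5, ylo, (zlo + zhi) / 2),
    ramus_lowest = c(5, ylo, zlo),
    condylion = c(5, ylo, zhi),
    baseline_lowest = bl$point + (zlo - bl$point[3]) * bl$direction,
    head_reference_level = (zhi - 2) - bl$point[3])
  res <- suppressWarnings(measure(mesh, bl, lmk, slab = 0.5))
  expect_equal(res[["ramus_height"]], 30, tolerance = 0.1)
  expect_equal(res[["length_neck_basal"]], 20, tolerance = 0.1)
  expect_equal(res[["length_neck_top"]], 20, tolerance = 0.1)
  expect_equal(res[["width_neck_basal"]], 10, tolerance = 0.1)
  expect_equal(res[["angle_posteriorline_notchpoint"]], 0, tolerance = 1e-3)
})

test_that("slab extents equal brute-force vertex exhaustion", {
  fx <- fixture_phantom(0.5)
  bl <- fit_baseline(fx$mesh)
  lmk <- detect_landmarks(fx$mesh, bl)
  res <- suppressWarnings(measure(fx$mesh, bl, lmk))
  u <- bl$direction; v <- condylometry:::.baseline_v(bl); w <- bl$lateral
  U_notch <- sum((lmk$sigmoid_notch_lowest - bl$point) * u)
  U_top <- lmk$head_reference_level
  slab <- fx$mesh$provenance$voxel
  vx <- fx$mesh$vertices
  expect_equal(res[["length_neck_basal"]],
               brute_extent(vx, bl$point, u, v, U_notch, slab),
               tolerance = 1e-6)
  expect_equal(res[["length_neck_top"]],
               brute_extent(vx, bl$point, u, v, U_top, slab),
               tolerance = 1e-6)
  expect_equal(res[["length_neck_middle"]],
               brute_extent(vx, bl$point, u, v, (U_notch + U_top) / 2, slab),
               tolerance = 1e-6)
  expect_equal(res[["width_neck_basal"]],
               brute_extent(vx, bl$point, u, w, U_notch, slab),
               tolerance = 1e-6)
})

test_that("measurements are invariant under rigid motion", {
  fx <- fixture_phantom(0.5)
  bl <- fit_baseline(fx$mesh)
  lmk <- detect_landmarks(fx$mesh, bl)
  res <- suppressWarnings(measure(fx$mesh, bl, lmk))
  tr <- transform_all(fx$mesh, bl, lmk, rot3(c(2, -1, 4), 0.6), c(-7, 3, 12))
  res2 <- suppressWarnings(measure(tr$mesh, tr$bl, tr$lmk))
  expect_equal(as.numeric(res2), as.numeric(res), tolerance = 1e-3)
})

test_that("similarity scaling multiplies lengths and fixes the angle", {
  fx <- fixture_phantom(0.5)
  bl <- fit_baseline(fx$mesh)
  lmk <- detect_landmarks(fx$mesh, bl)
  res <- suppressWarnings(measure(fx$mesh, bl, lmk))
  s <- 2
  mesh2 <- surface_mesh(fx$mesh$vertices * s, fx$mesh$faces,
                        fx$mesh$provenance)
  lmk2 <- landmark_set(lmk$sigmoid_notch_lowest * s, lmk$ramus_lowest * s,
                       lmk$condylion * s, lmk$baseline_lowest * s,
                       lmk$head_reference_level * s)
  bl2 <- baseline(bl$point * s, bl$direction, bl$lateral)
  res2 <- suppressWarnings(measure(mesh2, bl2, lmk2,
                                   slab = s * fx$mesh$provenance$voxel,
                                   notch_window = s, notch_offset = s))
  for (nm in setdiff(names(res), "angle_posteriorline_notchpoint"))
    expect_equal(res2[[nm]] / res[[nm]], s, tolerance = 0.01)
  expect_equal(res2[["angle_posteriorline_notchpoint"]],
               res[["angle_posteriorline_notchpoint"]], tolerance = 1e-6)
})

test_that("an unreachable level gives a per-measurement NA with a warning", {
  fx <- fixture_phantom(0.5)
  bl <- fit_baseline(fx$mesh)
  lmk <- detect_landmarks(fx$mesh, bl)
  bad <- landmark_set(lmk$sigmoid_notch_lowest, lmk$ramus_lowest,
                      lmk$condylion, lmk$baseline_lowest,
                      head_reference_level = lmk$head_reference_level + 500)
  expect_warning(res <- measure(fx$mesh, bl, bad), "length_neck_top")
  expect_true(is.na(res[["length_neck_top"]]))
  expect_false(is.na(res[["length_neck_basal"]]))
})

test_that("the mean-profile phantom reproduces the published means", {
  ph <- build_phantom(phantom_params(), spacing = 0.2)
  res <- suppressWarnings(measure_condyle(extract_surface(segment(ph$volume))))
  published <- c(length_neck_basal = 21.27, length_neck_top = 12.07,
                 distance_sigmoidnotch_necktop = 14.91, height_neck = 10.26,
                 length_neck_middle = 13.18, ramus_height = 69.61,
                 width_neck_basal = 10.29, width_head = 20.74,
                 thickness_sigmoid_notch = 2.15,
                 height_neck_new_classification = 14.56)
  for (nm in names(published))
    expect_lt(abs(res[[nm]] - published[[nm]]),
              max(0.3, 0.02 * published[[nm]]))
  # the angle is checked against the phantom's own ground truth
  expect_lt(abs(res[["angle_posteriorline_notchpoint"]] -
                ph$truth$true_measurements[["angle_posteriorline_notchpoint"]]),
            0.3)
})
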