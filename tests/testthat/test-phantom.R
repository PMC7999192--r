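test_that("parameter invariants are enforced", {
  expect_s3_class(phantom_params(), "phantom_params")
  expect_error(phantom_params(neck_basal_length = -1), "positive")
  expect_error(phantom_params(notch_thickness = 12), "notch_thickness")
  expect_error(phantom_params(neck_top_length = 14), "neck_top_length")
  expect_error(phantom_params(density_soft = 2000), "density_soft")
})

test_that("population sampling: zero-variance limit, determinism, rejection", {
  p0 <- phantom_params()
  one <- sample_population(1, p0, cv = 1e-9, seed = 5)[[1]]
  for (nm in condylometry:::length_param_names())
    expect_equal(one[[nm]], p0[[nm]], tolerance = 1e-6)

  a <- sample_population(5, p0, cv = 0.1, seed = 42)
  b <- sample_population(5, p0, cv = 0.1, seed = 42)
  expect_identical(a, b)
  expect_error(sample_population(0, p0), "positive count")
  expect_error(sample_population(3, p0, cv = 0.7), "cv")
  expect_error(sample_population(3, p0, cv = 0), "cv")
})

test_that("population means stay near the profile (n = 200, cv = 0.1)", {
  p0 <- phantom_params()
  pop <- sample_population(200, p0, cv = 0.1, seed = 99)
  for (nm in c("neck_basal_length", "head_width", "notch_thickness",
               "ramus_height")) {
    vals <- vapply(pop, `[[`, 0, nm)
    se <- 0.1 * p0[[nm]] / sqrt(200)
    expect_lt(abs(mean(vals) - p0[[nm]]), 3 * se)
  }
})

test_that("build rejects spacing too coarse for the notch plate", {
  expect_error(build_phantom(phantom_params(), spacing = 1.5), "notch plate")
})

test_that("ground truth matches the profile parameters", {
  fx <- fixture_phantom()
  tm <- fx$phantom$truth$true_measurements
  expect_equal(tm[["thickness_sigmoid_notch"]], 2.15, tolerance = 0.05)
  expect_equal(tm[["length_neck_basal"]], 21.27, tolerance = 1e-9)
  expect_equal(tm[["ramus_height"]], 69.61, tolerance = 1e-9)
  expect_equal(tm[["width_head"]], 20.74, tolerance = 1e-9)
  expect_equal(tm[["height_neck"]], 10.26, tolerance = 1e-9)
  # emergent measurements reproduce the published means at the mean profile
  expect_equal(tm[["distance_sigmoidnotch_necktop"]], 14.91, tolerance = 0.05)
  expect_equal(tm[["height_neck_new_classification"]], 14.56, tolerance = 0.01)
})

test_that("voxel histogram has exactly three tissue modes before blurring", {
  fx <- fixture_phantom()
  vals <- sort(unique(as.numeric(fx$phantom$volume$voxels)))
  p <- phantom_params()
  expect_identical(vals, c(p$density_soft, p$density_trabecular,
                           p$density_cortical))
})

test_that("similarity: doubling all lengths doubles length truths, fixes angle", {
  p0 <- phantom_params()
  args <- p0[condylometry:::length_param_names()]
  p2 <- do.call(phantom_params,
                c(lapply(args, `*`, 2), list(notch_angle = p0$notch_angle)))
  t1 <- condylometry:::phantom_truth(p0)$true_measurements
  t2 <- condylometry:::phantom_truth(p2)$true_measurements
  for (nm in setdiff(names(t1), "angle_posteriorline_notchpoint"))
    expect_equal(t2[[nm]] / t1[[nm]], 2, tolerance = 0.01)
  expect_equal(t2[["angle_posteriorline_notchpoint"]],
               t1[["angle_posteriorline_notchpoint"]], tolerance = 0.01)
})

test_that("mirror reflection leaves the measured phantom unchanged", {
  ph <- build_phantom(phantom_params(), spacing = 0.5)
  m1 <- suppressWarnings(measure_condyle(extract_surface(segment(ph$volume))))
  m2 <- suppressWarnings(measure_condyle(extract_surface(segment(
    mirror_volume(ph$volume)))))
  expect_equal(as.numeric(m1), as.numeric(m2), tolerance = 1e-6)
})

test_that("numerical extreme-point oracle agrees with the analytic truth", {
  p0 <- phantom_params()
  num <- phantom_truth_numeric(p0, step = 0.02)
  ana <- condylometry:::phantom_truth(p0)$true_measurements
  for (nm in setdiff(names(num), "angle_posteriorline_notchpoint"))
    expect_lt(abs(num[[nm]] - ana[[nm]]), 0.05)
  expect_lt(abs(num[["angle_posteriorline_notchpoint"]] -
                ana[["angle_posteriorline_notchpoint"]]), 0.1)
})

test_that("phantom keeps a soft-tissue margin and writes valid NIfTI + JSON", {
  fx <- fixture_phantom()
  vox <- fx$phantom$volume$voxels
  soft <- phantom_params()$density_soft
  d <- dim(vox)
  expect_true(all(vox[1:2, , ] == soft) && all(vox[, 1:2, ] == soft) &&
              all(vox[, , 1:2] == soft))
  expect_true(all(vox[(d[1] - 1):d[1], , ] == soft))

  tf <- tempfile(fileext = ".nii.gz")
  write_volume(fx$phantom$volume, tf)
  back <- read_volume(tf)
  expect_equal(back$voxels, vox, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(back$spacing, fx$phantom$volume$spacing, tolerance = 1e-6)
  expect_equal(back$origin, fx$phantom$volume$origin, tolerance = 1e-4)

  tj <- tempfile(fileext = ".json")
  write_ground_truth(fx$phantom$truth, tj)
  gt <- jsonlite::read_json(tj, simplifyVector = TRUE)
  expect_equal(gt$true_measurements$thickness_sigmoid_notch, 2.15,
               tolerance = 1e-9)
  expect_length(gt$landmarks$sigmoid_notch_lowest, 3)
  unlink(c(tf, tj))
})
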