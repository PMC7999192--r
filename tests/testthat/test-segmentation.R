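test_that("symmetric bimodal volume splits 50/50", {
  vox <- array(rep(c(0, 100), each = 500), c(10, 10, 10))
  vol <- density_volume(vox, rep(1, 3))
  thr <- select_threshold(vol)
  expect_gt(thr, 0)
  expect_lte(thr, 100)
  expect_equal(sum(vox >= thr), 500)
})

test_that("threshold equals exhaustive between-class-variance search", {
  set.seed(12)
  for (rep in 1:3) {
    v <- c(rnorm(2000, 20, 5), rnorm(2000, 80, 5))
    vol <- density_volume(array(v, c(20, 20, 10)), rep(1, 3))
    expect_equal(select_threshold(vol), brute_otsu(v), tolerance = 1e-9)
  }
})

test_that("adding a constant shifts the threshold by the same constant", {
  set.seed(4)
  v <- c(rnorm(1000, 30, 6), rnorm(1000, 90, 8))
  vol1 <- density_volume(array(v, c(10, 10, 20)), rep(1, 3))
  vol2 <- density_volume(array(v + 17, c(10, 10, 20)), rep(1, 3))
  bw <- diff(range(v)) / 256
  expect_lt(abs(select_threshold(vol2) - select_threshold(vol1) - 17), bw + 1e-9)
})

test_that("constant volumes are rejected", {
  vol <- density_volume(array(5, c(4, 4, 4)), rep(1, 3))
  expect_error(select_threshold(vol), "histogram")
})

test_that("threshold below the minimum yields one all-foreground component", {
  set.seed(8)
  vol <- density_volume(array(runif(125, 10, 20), c(5, 5, 5)), rep(1, 3))
  model <- segment(vol, threshold = 5)
  expect_true(all(model$mask))
  expect_equal(model$threshold_used, 5)
})

test_that("only the largest of two disjoint blobs survives", {
  vox <- array(0, c(20, 10, 10))
  vox[2:9, 2:9, 2:9] <- 100        # large blob
  vox[15:16, 2:3, 2:3] <- 100      # small blob, 10x smaller
  model <- segment(density_volume(vox, rep(1, 3)), threshold = 50)
  expect_equal(sum(model$mask), 8^3)
  expect_false(any(model$mask[15:16, , ]))
})

test_that("raising the threshold never increases mask volume", {
  vol <- fixture_phantom(0.5)$phantom$volume
  img <- acquire(vol, default_profiles()$fbct, seed = 2)
  thrs <- seq(200, 1200, by = 200)
  vols <- vapply(thrs, function(t) sum(segment(img, threshold = t)$mask), 0)
  expect_true(all(diff(vols) <= 0))
})

test_that("auto threshold recovers the analytic solid volume within 2%", {
  fx <- fixture_phantom()
  # Monte-Carlo integration oracle on the implicit solid
  g <- condylometry:::phantom_geometry(phantom_params())
  set.seed(1234)
  n <- 2e6
  lo <- c(-g$W_h / 2 - 1, -1, -1)
  hi <- c(g$W_h / 2 + 1, g$V_rf + 1, g$H + 1)
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  frac <- mean(condylometry:::phantom_inside(pts[, 1], pts[, 2], pts[, 3], g))
  vol_mc <- frac * prod(hi - lo)
  vol_mask <- sum(fx$model$mask) * prod(fx$model$spacing)
  expect_lt(abs(vol_mask - vol_mc) / vol_mc, 0.02)
})

test_that("empty masks raise an error naming the threshold", {
  vol <- density_volume(array(runif(64, 0, 1), c(4, 4, 4)), rep(1, 3))
  expect_error(segment(vol, threshold = 99), "99")
})
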