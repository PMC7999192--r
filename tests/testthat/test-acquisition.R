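test_that("identity profile reproduces the input volume exactly", {
  vol <- density_volume(array(rnorm(6 * 7 * 8, 100, 10), c(6, 7, 8)),
                        spacing = rep(0.5, 3))
  ident <- acquisition_profile("identity", voxel_out = 0.5, psf_sigma = 0,
                               noise_sigma = 0, contrast_scale = 1)
  out <- acquire(vol, ident, seed = 1)
  expect_identical(out$voxels, vol$voxels)
  expect_identical(out$spacing, vol$spacing)
})

test_that("acquisition is deterministic given the seed", {
  vol <- fixture_phantom(0.5)$phantom$volume
  prof <- default_profiles()$cbct
  a <- acquire(vol, prof, seed = 7)
  b <- acquire(vol, prof, seed = 7)
  c <- acquire(vol, prof, seed = 8)
  expect_identical(a$voxels, b$voxels)
  expect_false(identical(a$voxels, c$voxels))
})

# closed-form blurred slab profile: 0.5 * (erf((x+t/2)/(s*sqrt(2))) -
# erf((x-t/2)/(s*sqrt(2))))
slab_profile <- function(x, t, s) {
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  0.5 * (erf((x + t / 2) / (s * sqrt(2))) - erf((x - t / 2) / (s * sqrt(2))))
}
# analytic above-level half-width of the blurred slab
slab_halfwidth <- function(t, s, level = 0.5) {
  if (slab_profile(0, t, s) <= level) return(0)
  uniroot(function(x) slab_profile(x, t, s) - level, c(0, t / 2 + 6 * s))$root
}

test_that("blurred slab width matches the erf closed form within one voxel", {
  sp <- 0.2; t <- 1.9
  n <- c(201, 41, 41)
  xs <- (seq_len(n[1]) - (n[1] + 1) / 2) * sp
  inside <- abs(xs) <= t / 2
  t_eff <- sum(inside) * sp          # thickness the voxelisation realises
  vox <- array(rep(as.numeric(inside), n[2] * n[3]), n)
  vol <- density_volume(vox, rep(sp, 3))
  for (s in c(0.4, 0.8)) {
    prof <- acquisition_profile("blur", voxel_out = sp, psf_sigma = s,
                                noise_sigma = 0, contrast_scale = 1)
    out <- acquire(vol, prof, seed = 1)
    line <- out$voxels[, (n[2] + 1) %/% 2, (n[3] + 1) %/% 2]
    measured <- sum(line > 0.5) * sp
    expect_lt(abs(measured - 2 * slab_halfwidth(t_eff, s)), sp)
  }
})

test_that("above-half-maximum plate width is non-increasing in PSF width", {
  sp <- 0.2; t <- 1.5
  n <- c(201, 31, 31)
  xs <- (seq_len(n[1]) - (n[1] + 1) / 2) * sp
  inside <- abs(xs) <= t / 2
  t_eff <- sum(inside) * sp
  vol <- density_volume(array(rep(as.numeric(inside), n[2] * n[3]), n),
                        rep(sp, 3))
  sigmas <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  widths <- vapply(sigmas, function(s) {
    out <- acquire(vol, acquisition_profile("b", sp, s, 0, 1), seed = 1)
    sum(out$voxels[, 16, 16] > 0.5) * sp
  }, 0)
  expect_true(all(diff(widths) <= sp / 2 + 1e-9))
  oracle <- vapply(sigmas, function(s) 2 * slab_halfwidth(t_eff, s), 0)
  expect_true(all(abs(widths - oracle) <= sp))
  expect_true(all(diff(oracle) <= 0))
})

test_that("blur and box resampling conserve mean density", {
  set.seed(31)
  blob <- array(150, c(40, 40, 40))
  blob[12:28, 10:30, 8:32] <- 1200
  vol <- density_volume(blob + rnorm(length(blob), 0, 5), rep(0.5, 3))
  prof <- acquisition_profile("pve", voxel_out = 1.0, psf_sigma = 0.8,
                              noise_sigma = 0, contrast_scale = 1)
  out <- acquire(vol, prof, seed = 1)
  expect_lt(abs(mean(out$voxels) - mean(vol$voxels)) / mean(vol$voxels), 0.005)
})

test_that("shipped profiles satisfy the modality contract and YAML round-trip", {
  pr <- default_profiles()
  expect_gt(pr$cbct$psf_sigma, pr$fbct$psf_sigma)
  expect_lt(pr$cbct$contrast_scale, pr$fbct$contrast_scale)
  tf <- tempfile(fileext = ".yaml")
  write_profiles(pr, tf)
  back <- read_profiles(tf)
  for (nm in c("fbct", "cbct"))
    for (f in c("voxel_out", "psf_sigma", "noise_sigma", "contrast_scale"))
      expect_equal(back[[nm]][[f]], pr[[nm]][[f]])
  unlink(tf)
})

test_that("invalid profiles and oversized voxels are rejected", {
  expect_error(acquisition_profile("x", -1, 0, 0, 1), "voxel_out")
  expect_error(acquisition_profile("x", 0.5, -1, 0, 1), "psf_sigma")
  expect_error(acquisition_profile("x", 0.5, 0, 0, 1.5), "contrast_scale")
  vol <- density_volume(array(rnorm(4^3), rep(4, 3)), rep(0.5, 3))
  big <- acquisition_profile("x", voxel_out = 3, psf_sigma = 0,
                             noise_sigma = 0, contrast_scale = 1)
  expect_error(acquire(vol, big), "extent")
})
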