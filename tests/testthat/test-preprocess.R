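test_that("mean image averages all frames for BOLD, control frames for ASL", {
  v <- array(stats::runif(8), c(2, 2, 2))
  const <- fmri_run(array(v, c(2, 2, 2, 3)), tr = 1, modality = "bold",
                    frame_roles = rep("plain", 3), frame_times = 0:2,
                    voxel_size = c(1, 1, 1))
  expect_equal(mean_image(const), v)

  bold2 <- fmri_run(array(c(v, 3 * v), c(2, 2, 2, 2)), tr = 1,
                    modality = "bold", frame_roles = rep("plain", 2),
                    frame_times = 0:1, voxel_size = c(1, 1, 1))
  expect_equal(mean_image(bold2), 2 * v)

  asl <- toy_ct_run(c(10, 8, 10, 8, 10))
  expect_equal(as.vector(mean_image(asl)), 10)
})

test_that("brain mask rules behave as documented on a toy volume", {
  v <- array(c(rep(0, 90), rep(100, 10)), c(10, 10, 1))
  m1 <- brain_mask(v, "above_mean")            # mu = 10
  expect_equal(sum(m1$mask), 10L)
  expect_true(all(v[m1$mask] == 100))

  m2 <- brain_mask(v, "band")                  # sigma ~ 30.15: keeps zeros
  expect_equal(sum(m2$mask), 90L)
  expect_true(all(v[m2$mask] == 0))

  m3 <- brain_mask(v, "above_mean_minus_sd")   # mu - sigma < 0: keeps all
  expect_equal(sum(m3$mask), 100L)

  const <- array(5, c(3, 3, 1))
  expect_equal(sum(brain_mask(const, "above_mean")$mask), 9L)
})

test_that("gaussian smoothing preserves constants and interior mass", {
  d <- c(9, 9, 5)
  const <- fmri_run(array(7, c(d, 2)), tr = 1, modality = "bold",
                    frame_roles = rep("plain", 2), frame_times = 0:1,
                    voxel_size = c(4, 4, 4))
  sm <- smooth_gaussian(const, fwhm = 8)
  expect_equal(sm$data, const$data, tolerance = 1e-12)

  # mass conservation needs the impulse at least two kernel radii from
  # every edge (edge rows are renormalized)
  imp <- array(0, c(17, 17, 17, 1))
  imp[9, 9, 9, 1] <- 1
  impr <- fmri_run(imp, tr = 1, modality = "bold", frame_roles = "plain",
                   frame_times = 0, voxel_size = c(4, 4, 4))
  smi <- smooth_gaussian(impr, fwhm = 8)
  expect_equal(sum(smi$data), 1, tolerance = 1e-12)
  expect_lt(max(smi$data), 1)                  # mass actually spread
  expect_identical(smooth_gaussian(impr, fwhm = 0)$data, imp)
})

test_that("smoothing kernel rows are normalized weights", {
  K <- brainstate:::gauss_band_matrix(11, 8 / (2 * sqrt(2 * log(2))) / 4)
  expect_equal(rowSums(K), rep(1, 11), tolerance = 1e-12)
  expect_true(all(K >= 0))
  # interior row symmetric around its diagonal
  expect_equal(K[6, 6 + 1:3], K[6, 6 - 1:3])
})

test_that("surround subtraction matches the hand-worked example", {
  r <- toy_ct_run(c(12, 10, 12, 10, 12))
  out <- surround_subtract(r)
  expect_equal(as.vector(out$data), rep(2, 4))
  expect_equal(out$modality, "subtracted")
  expect_equal(out$frame_times, 0:3)
  expect_true(all(out$frame_roles == "plain"))

  const <- toy_ct_run(rep(5, 6))
  expect_equal(as.vector(surround_subtract(const)$data), rep(0, 5))

  r75 <- toy_ct_run(stats::rnorm(75), tr = 4)
  expect_equal(dim(surround_subtract(r75)$data)[4], 74L)

  bold <- fmri_run(array(1, c(1, 1, 1, 5)), tr = 2, modality = "bold",
                   frame_roles = rep("plain", 5), frame_times = 0:4 * 2,
                   voxel_size = c(1, 1, 1))
  expect_error(surround_subtract(bold), "control/tag")
})

test_that("surround subtraction annihilates affine drift at interior frames", {
  set.seed(21)
  for (rep in 1:10) {
    a <- stats::rnorm(1, 0, 100); b <- stats::rnorm(1, 0, 5)
    tt <- 0:19 * 2.2
    r <- toy_ct_run(a + b * tt, tr = 2.2)
    out <- as.vector(surround_subtract(r)$data)
    expect_equal(out[-1], rep(0, 18), tolerance = 1e-9)
  }
})

test_that("constant perfusion is recovered at every output frame", {
  base <- 50; perf <- 3
  vals <- base + perf * rep_len(c(1, 0), 20)   # control = base + perf
  out <- as.vector(surround_subtract(toy_ct_run(vals))$data)
  expect_equal(out, rep(perf, 19), tolerance = 1e-12)
})

test_that("voxel-wise normalization z-scores and is idempotent", {
  d <- array(0, c(2, 1, 1, 3))
  d[1, 1, 1, ] <- c(1, 2, 3)
  d[2, 1, 1, ] <- 4                            # constant voxel
  r <- fmri_run(d, tr = 1, modality = "bold", frame_roles = rep("plain", 3),
                frame_times = 0:2, voxel_size = c(1, 1, 1))
  z <- normalize_voxelwise(r)
  expect_equal(as.vector(z$data[1, 1, 1, ]), c(-1, 0, 1))
  expect_equal(as.vector(z$data[2, 1, 1, ]), c(0, 0, 0))
  expect_equal(normalize_voxelwise(z)$data, z$data, tolerance = 1e-12)

  set.seed(5)
  rr <- fmri_run(array(stats::rnorm(4 * 4 * 2 * 20), c(4, 4, 2, 20)), tr = 1,
                 modality = "bold", frame_roles = rep("plain", 20),
                 frame_times = 0:19, voxel_size = c(1, 1, 1))
  zz <- normalize_voxelwise(rr)
  m <- matrix(zz$data, 32)
  expect_true(all(abs(rowMeans(m)) < 1e-10))
  expect_true(all(abs(apply(m, 1, stats::sd) - 1) < 1e-10))
})

test_that("subsampling halves counts and doubles the effective TR", {
  r <- fmri_run(array(stats::rnorm(150), c(1, 1, 1, 150)), tr = 2,
                modality = "bold", frame_roles = rep("plain", 150),
                frame_times = 0:149 * 2, voxel_size = c(1, 1, 1))
  s2 <- subsample_run(r, 2)
  expect_equal(dim(s2$data)[4], 75L)
  expect_equal(s2$tr, 4)
  expect_identical(subsample_run(r, 1)$data, r$data)

  r7 <- fmri_run(array(1:7, c(1, 1, 1, 7)), tr = 1, modality = "bold",
                 frame_roles = rep("plain", 7), frame_times = 0:6,
                 voxel_size = c(1, 1, 1))
  expect_equal(dim(subsample_run(r7, 2)$data)[4], 4L)
  expect_equal(as.vector(subsample_run(r7, 2, offset = 1)$data), c(2, 4, 6))
})
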