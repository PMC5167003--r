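p5 <- paradigm(30, 5)

test_that("frame counts follow floor(duration / TR)", {
  s <- synth_params(grid = micro_grid())
  expect_equal(dim(generate_run("bold", p5, s, 1)$data)[4], 150L)
  expect_equal(dim(generate_run("asl", p5, s, 1)$data)[4], 75L)
  expect_equal(dim(generate_run("avast", p5, s, 1, tr = 1.9)$data)[4], 157L)
})

test_that("roles alternate for control/tag runs and are plain for BOLD", {
  s <- synth_params(grid = micro_grid())
  b <- generate_run("bold", p5, s, 1)
  expect_true(all(b$frame_roles == "plain"))
  a <- generate_run("asl", p5, s, 1)
  expect_equal(a$frame_roles[1:4], c("control", "tag", "control", "tag"))
  expect_error(generate_run("pet", p5, s, 1))
})

test_that("generation is seed-deterministic", {
  s <- synth_params(grid = micro_grid())
  r1 <- generate_run("avast", p5, s, 7)
  r2 <- generate_run("avast", p5, s, 7)
  r3 <- generate_run("avast", p5, s, 8)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, r3$data))
})

test_that("runs of a subject share the deterministic signal component", {
  s <- synth_params(grid = micro_grid())
  sig1 <- brainstate:::run_signal("asl", p5, s, 4)
  sig2 <- brainstate:::run_signal("asl", p5, s, 4)
  expect_identical(sig1$signal, sig2$signal)
  subj <- generate_subject(s, 42, modalities = "asl")
  noise1 <- subj$runs$asl$run1$data - sig1$signal
  noise2 <- subj$runs$asl$run2$data - sig1$signal
  expect_false(identical(noise1, noise2))
  # ground-truth ROI sits inside the brain
  expect_true(all(subj$brain_mask[subj$roi_mask]))
})

test_that("zero CNR leaves ROI and background time courses equal", {
  s <- synth_params(grid = micro_grid(),
                    cnr = c(bold = 0, asl = 0, avast = 0))
  roi <- roi_mask(s)
  brain <- ellipsoid_mask(s$grid, s$brain_ellipsoid)
  bg <- brain & !roi
  diffs <- vapply(1:50, function(seed) {
    r <- generate_run("bold", p5, s, seed)
    m <- matrix(r$data, prod(dim(r$data)[1:3]))
    mean(m[roi, ]) - mean(m[bg, ])
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("with no AR coefficient the noise is temporally white", {
  s <- synth_params(grid = micro_grid(), ar1_coeff = 0,
                    drift_slope = c(bold = 0, asl = 0, avast = 0),
                    cnr = c(bold = 0, asl = 0, avast = 0))
  r <- generate_run("bold", p5, s, 3)
  m <- matrix(r$data, prod(dim(r$data)[1:3]))
  nT <- ncol(m)
  ac1 <- apply(m[1:40, ], 1, function(x) stats::cor(x[-1], x[-nT]))
  expect_lt(abs(mean(ac1)), 3 / sqrt(nT * 40) * 3)
  expect_true(all(abs(ac1) < 3 / sqrt(nT) * 2))
})

test_that("control-minus-tag during rest recovers the labeling offset", {
  s <- synth_params(grid = micro_grid())
  r <- generate_run("asl", p5, s, 9)
  brain <- ellipsoid_mask(s$grid, s$brain_ellipsoid)
  roi <- roi_mask(s)
  m <- matrix(r$data, prod(dim(r$data)[1:3]))
  rest <- label_at_time(p5, r$frame_times) < 0
  ctrl <- r$frame_roles == "control"
  vox <- which(brain & !roi)
  d <- rowMeans(m[vox, rest & ctrl]) - rowMeans(m[vox, rest & !ctrl])
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - s$tag_efficiency_delta), 3 * se)
})

test_that("doubling CNR doubles the task-vs-rest subtracted ROI contrast", {
  base <- list(grid = micro_grid(), noise_sd = 10)
  s1 <- do.call(synth_params, c(base, list(cnr = c(bold = 1, asl = 1, avast = 1))))
  s2 <- do.call(synth_params, c(base, list(cnr = c(bold = 2, asl = 2, avast = 2))))
  contrast <- function(s) {
    sig <- brainstate:::run_signal("asl", p5, s, 4)
    r <- fmri_run(sig$signal, tr = 4, modality = "asl",
                  frame_roles = sig$roles, frame_times = sig$times,
                  voxel_size = s$grid$voxel_size)
    sub <- surround_subtract(r)
    m <- matrix(sub$data, prod(dim(sub$data)[1:3]))
    lab <- label_at_time(p5, sub$frame_times)
    roi <- roi_mask(s)
    mean(m[roi, lab > 0]) - mean(m[roi, lab < 0])
  }
  c1 <- contrast(s1); c2 <- contrast(s2)
  expect_gt(c1, 0)
  expect_equal(c2 / c1, 2, tolerance = 1e-10)
})

test_that("subject-level AVAST TR draws match the tailored-TR table", {
  tab <- avast_tr_table()
  expect_equal(sum(tab$weight), 1)
  s <- synth_params(grid = grid_spec(4, 4, 2, c(60, 60, 66)))
  trs <- vapply(1:40, function(i) {
    generate_subject(s, i, modalities = "avast")$avast_tr
  }, numeric(1))
  expect_true(all(trs %in% tab$tr))
  # the most frequent calibrated TR (2.4 s) appears; the rarest not dominant
  expect_gt(mean(trs == 2.4), 0.05)
  expect_lt(mean(trs == 2.5), 0.5)
})
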