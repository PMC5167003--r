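#' Voxel grid specification
#'
#' @param nx,ny,nz Voxel counts per axis. Default 64 x 64 x 11, the in-plane
#'   matrix and slice count of a 24-cm field of view acquisition with 6-mm
#'   slices.
#' @param voxel_size Numeric length-3, mm per axis. Default
#'   `c(3.75, 3.75, 6)` (240 mm / 64 in plane).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(nx = 64L, ny = 64L, nz = 11L,
                      voxel_size = c(3.75, 3.75, 6)) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, length(voxel_size) == 3,
            all(voxel_size > 0))
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), voxel_size = as.numeric(voxel_size)),
            class = "grid_spec")
}

#' Ellipsoid in fractional grid coordinates
#'
#' Centers and radii are fractions of the grid extent along each axis, so the
#' same geometry scales to any grid resolution.
#'
#' @param center Length-3 fractional center in `(0, 1)`.
#' @param radii Length-3 fractional radii.
#' @param amplitude Activation amplitude weight inside the ellipsoid.
#' @return An `ellipsoid` list.
#' @export
ellipsoid <- function(center, radii, amplitude = 1) {
  stopifnot(length(center) == 3, length(radii) == 3, all(radii > 0),
            amplitude >= 0)
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 amplitude = amplitude), class = "ellipsoid")
}

#' Logical mask of an ellipsoid on a grid
#' @param grid A [grid_spec()].
#' @param ell An [ellipsoid()].
#' @return Logical 3D array of dim `(nx, ny, nz)`.
#' @export
ellipsoid_mask <- function(grid, ell) {
  dims <- c(grid$nx, grid$ny, grid$nz)
  cen <- ell$center * dims
  rad <- ell$radii * dims
  x <- (seq_len(dims[1]) - 0.5 - cen[1]) / rad[1]
  y <- (seq_len(dims[2]) - 0.5 - cen[2]) / rad[2]
  z <- (seq_len(dims[3]) - 0.5 - cen[3]) / rad[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

default_brain_ellipsoid <- function() {
  ellipsoid(center = c(0.5, 0.5, 0.5), radii = c(0.45, 0.45, 0.48))
}

default_roi_spec <- function() {
  list(
    motor  = ellipsoid(center = c(0.35, 0.45, 0.65),
                       radii = c(0.12, 0.12, 0.25)),
    visual = ellipsoid(center = c(0.50, 0.75, 0.45),
                       radii = c(0.12, 0.12, 0.25))
  )
}

#' Parameters of the synthetic block-design generator
#'
#' Defines the ground truth shared by all synthetic runs of a subject: grid
#' geometry, baseline image, activated regions ("motor" and "visual"
#' ellipsoids), per-modality contrast-to-noise ratios and repetition times,
#' noise structure, scanner drift (BOLD only by default), and the baseline
#' control-minus-tag offset of the labeling sequence.
#'
#' @param grid A [grid_spec()].
#' @param baseline_intensity Baseline image intensity inside the brain, a.u.
#' @param roi_spec Named list of [ellipsoid()]s receiving task activation.
#' @param brain_ellipsoid [ellipsoid()] delimiting the brain.
#' @param cnr Named numeric, peak activation amplitude divided by noise SD,
#'   per modality. Defaults are ordered `avast > asl` to reflect the higher
#'   SNR of arterial-volume-weighted tagging over perfusion-weighted ASL, with
#'   `bold` set so default end-to-end cross-run accuracies fall in (0.7, 1).
#' @param noise_sd Innovation standard deviation of the voxel noise, a.u.
#' @param ar1_coeff Lag-1 autoregressive coefficient of the temporal noise,
#'   in `[0, 1)`.
#' @param drift_slope Named numeric, linear scanner drift in a.u. per second
#'   per modality (nonzero only for BOLD by default; subtraction-based
#'   contrasts cancel slow drift at acquisition).
#' @param tag_efficiency_delta Baseline control-minus-tag intensity
#'   difference inside the brain, a.u.
#' @param hrf_params List of overrides passed to [hrf_double_gamma()].
#' @param tr Named numeric, repetition time in seconds per modality. The
#'   AVAST entry is the fallback used when a run is generated outside
#'   [generate_subject()], which instead draws a per-subject tailored TR.
#' @param control_first Logical; first frame of control/tag series is a
#'   control frame.
#' @param seed Default subject seed used when none is given.
#' @return A `synth_params` list.
#' @export
synth_params <- function(grid = grid_spec(),
                         baseline_intensity = 1000,
                         roi_spec = default_roi_spec(),
                         brain_ellipsoid = default_brain_ellipsoid(),
                         cnr = c(bold = 2, asl = 1.2, avast = 4),
                         noise_sd = 10,
                         ar1_coeff = 0.3,
                         drift_slope = c(bold = 0.03, asl = 0, avast = 0),
                         tag_efficiency_delta = 15,
                         hrf_params = list(),
                         tr = c(bold = 2, asl = 4, avast = 2.2),
                         control_first = TRUE,
                         seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), all(cnr >= 0), noise_sd >= 0,
            ar1_coeff >= 0, ar1_coeff < 1, baseline_intensity >= 0)
  structure(list(grid = grid, baseline_intensity = baseline_intensity,
                 roi_spec = roi_spec, brain_ellipsoid = brain_ellipsoid,
                 cnr = cnr, noise_sd = noise_sd, ar1_coeff = ar1_coeff,
                 drift_slope = drift_slope,
                 tag_efficiency_delta = tag_efficiency_delta,
                 hrf_params = hrf_params, tr = tr,
                 control_first = control_first, seed = as.integer(seed)),
            class = "synth_params")
}

#' Ground-truth activated-region mask
#' @param s A [synth_params()].
#' @return Logical 3D array: voxels belonging to any activation ellipsoid.
#' @export
roi_mask <- function(s) {
  stopifnot(inherits(s, "synth_params"))
  amp <- roi_amplitude_map(s)
  amp > 0
}

roi_amplitude_map <- function(s) {
  dims <- c(s$grid$nx, s$grid$ny, s$grid$nz)
  amp <- array(0, dims)
  for (ell in s$roi_spec) {
    amp <- pmax(amp, ell$amplitude * ellipsoid_mask(s$grid, ell))
  }
  amp
}

#' 4D acquisition run container
#'
#' @param data 4D array `(nx, ny, nz, n_frames)`, arbitrary units.
#' @param tr Repetition time, seconds.
#' @param modality One of `"bold"`, `"asl"`, `"avast"`, `"subtracted"`.
#' @param frame_roles Character per frame: `"plain"`, `"control"` or `"tag"`.
#' @param frame_times Acquisition start time of each frame, seconds.
#' @param voxel_size Length-3 mm per axis.
#' @return An `fmri_run` object.
#' @export
fmri_run <- function(data, tr, modality, frame_roles, frame_times,
                     voxel_size) {
  stopifnot(length(dim(data)) == 4, tr > 0,
            modality %in% c("bold", "asl", "avast", "subtracted"),
            length(frame_roles) == dim(data)[4],
            length(frame_times) == dim(data)[4],
            all(frame_roles %in% c("plain", "control", "tag")))
  if (modality %in% c("asl", "avast")) {
    r <- unique(frame_roles[seq(1, length(frame_roles), by = 2)])
    r2 <- unique(frame_roles[seq(2, length(frame_roles), by = 2)])
    if (length(r) != 1L || length(r2) != 1L || r == r2 ||
        any(c(r, r2) == "plain")) {
      stop("asl/avast frame roles must strictly alternate control/tag")
    }
  }
  structure(list(data = data, tr = tr, modality = modality,
                 frame_roles = frame_roles, frame_times = frame_times,
                 voxel_size = as.numeric(voxel_size)),
            class = "fmri_run")
}

#' @export
print.fmri_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fmri_run> %s, %d frames of %dx%dx%d, TR %.3g s\n",
              x$modality, d[4], d[1], d[2], d[3], x$tr))
  invisible(x)
}

n_frames <- function(r) dim(r$data)[4]

# Evaluate `expr` under a private RNG stream; global .Random.seed untouched.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic noiseless signal component of a run, shared across the two
# runs of a subject. Returns list(signal = 4D array, roles, times).
run_signal <- function(modality, p, s, tr) {
  dims <- c(s$grid$nx, s$grid$ny, s$grid$nz)
  n <- floor(p$total_duration / tr)
  times <- (seq_len(n) - 1) * tr
  brain <- ellipsoid_mask(s$grid, s$brain_ellipsoid)
  amp <- roi_amplitude_map(s) * brain        # activation confined to brain
  h <- do.call(task_regressor, c(list(p = p, times = times), s$hrf_params))
  cnr <- s$cnr[[modality]]
  drift <- if (!is.null(s$drift_slope[[modality]])) s$drift_slope[[modality]] else 0

  base <- s$baseline_intensity * brain
  sig <- array(0, c(dims, n))
  if (modality == "bold") {
    roles <- rep("plain", n)
    for (t in seq_len(n)) {
      sig[, , , t] <- base + cnr * s$noise_sd * h[t] * amp +
        drift * times[t] * brain
    }
  } else {
    roles <- if (s$control_first) {
      rep_len(c("control", "tag"), n)
    } else {
      rep_len(c("tag", "control"), n)
    }
    m <- as.numeric(roles == "control")
    for (t in seq_len(n)) {
      sig[, , , t] <- base +
        m[t] * (s$tag_efficiency_delta * brain +
                  cnr * s$noise_sd * h[t] * amp)
    }
  }
  list(signal = sig, roles = roles, times = times)
}

# AR(1) noise, innovation SD sigma, stationary start.
ar1_noise <- function(dims, n, phi, sigma) {
  nvox <- prod(dims)
  e <- matrix(0, nvox, n)
  if (sigma == 0) return(array(e, c(dims, n)))
  e[, 1] <- stats::rnorm(nvox, sd = sigma / sqrt(1 - phi^2))
  if (n > 1) {
    for (t in 2:n) e[, t] <- phi * e[, t - 1] + stats::rnorm(nvox, sd = sigma)
  }
  array(e, c(dims, n))
}

#' Generate one synthetic acquisition run
#'
#' Produces a 4D block-design time series for the given contrast. BOLD runs
#' carry the activation directly on every frame plus a linear scanner drift;
#' control/tag runs (`asl`, `avast`) carry both the baseline labeling offset
#' and the activation on control frames only, so that the task signal lives
#' in the control-minus-tag difference. Voxel noise is temporally AR(1);
#' voxels outside the brain ellipsoid contain noise only. The output is
#' bit-reproducible for a fixed `run_seed`.
#'
#' @param modality `"bold"`, `"asl"` or `"avast"`.
#' @param p A [paradigm()].
#' @param s A [synth_params()].
#' @param run_seed Integer seed of this run's private noise stream.
#' @param tr Optional TR override in seconds (defaults to `s$tr[[modality]]`).
#' @return An [fmri_run()].
#' @export
generate_run <- function(modality, p, s, run_seed, tr = NULL) {
  modality <- match.arg(modality, c("bold", "asl", "avast"))
  stopifnot(inherits(p, "paradigm"), inherits(s, "synth_params"))
  if (is.null(tr)) tr <- s$tr[[modality]]
  if (is.null(tr) || !is.finite(tr) || tr <= 0) {
    stop("no valid TR for modality ", modality)
  }
  comp <- run_signal(modality, p, s, tr)
  dims <- c(s$grid$nx, s$grid$ny, s$grid$nz)
  n <- dim(comp$signal)[4]
  eps <- with_local_seed(run_seed,
                         ar1_noise(dims, n, s$ar1_coeff, s$noise_sd))
  fmri_run(comp$signal + eps, tr = tr, modality = modality,
           frame_roles = comp$roles, frame_times = comp$times,
           voxel_size = s$grid$voxel_size)
}

#' AVAST tailored repetition times
#'
#' The per-subject distribution of calibrated AVAST TRs: values
#' 2.0, 2.1, 2.2, 2.4 and 2.5 s with relative frequencies 2, 2, 2, 3 and 1
#' out of 10 subjects.
#' @return Data frame with columns `tr` and `weight`.
#' @export
avast_tr_table <- function() {
  data.frame(tr = c(2.0, 2.1, 2.2, 2.4, 2.5),
             weight = c(2, 2, 2, 3, 1) / 10)
}

#' Generate a full synthetic subject
#'
#' Draws a tailored AVAST TR for the subject, then generates two runs for
#' each requested modality. All six runs share the same baseline image and
#' activation geometry (the ground truth), and differ only in their noise
#' realizations, which use independent per-run seeds derived from
#' `subject_seed`.
#'
#' @param s A [synth_params()].
#' @param subject_seed Integer seed for this subject.
#' @param p A [paradigm()] (default: five 30-s task/rest cycles).
#' @param modalities Character vector of modalities to generate.
#' @return A list with elements `runs` (per modality, a list of `run1`,
#'   `run2`), `roi_mask`, `brain_mask`, `avast_tr` and `subject_seed`.
#' @export
generate_subject <- function(s, subject_seed, p = paradigm(30, 5),
                             modalities = c("bold", "asl", "avast")) {
  stopifnot(inherits(s, "synth_params"))
  draws <- with_local_seed(subject_seed, {
    tab <- avast_tr_table()
    list(avast_tr = sample(tab$tr, 1L, prob = tab$weight),
         run_seeds = sample.int(.Machine$integer.max,
                                2L * length(modalities)))
  })
  runs <- list()
  for (i in seq_along(modalities)) {
    mod <- modalities[i]
    tr <- if (mod == "avast") draws$avast_tr else s$tr[[mod]]
    runs[[mod]] <- list(
      run1 = generate_run(mod, p, s, draws$run_seeds[2L * i - 1L], tr = tr),
      run2 = generate_run(mod, p, s, draws$run_seeds[2L * i], tr = tr)
    )
  }
  list(runs = runs, roi_mask = roi_mask(s),
       brain_mask = ellipsoid_mask(s$grid, s$brain_ellipsoid),
       avast_tr = draws$avast_tr, subject_seed = subject_seed)
}
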