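#' Mean image of a run
#'
#' For BOLD (or subtracted) runs, the voxel-wise mean over all frames. For
#' control/tag runs, the voxel-wise mean over the control frames only — the
#' baseline image of the labeling sequence.
#'
#' @param r An [fmri_run()].
#' @return 3D numeric array.
#' @export
mean_image <- function(r) {
  stopifnot(inherits(r, "fmri_run"), n_frames(r) >= 1)
  keep <- if (r$modality %in% c("asl", "avast")) {
    w <- which(r$frame_roles == "control")
    if (!length(w)) stop("no control frames in ", r$modality, " run")
    w
  } else {
    seq_len(n_frames(r))
  }
  d <- dim(r$data)
  m <- rowMeans(matrix(r$data, prod(d[1:3]), d[4])[, keep, drop = FALSE])
  array(m, d[1:3])
}

#' Brain mask from a mean image
#'
#' Thresholds the mean (baseline) image against its global statistics.
#' Three rules are available:
#' \describe{
#'   \item{`"above_mean"` (default)}{include voxels with intensity at or
#'     above the global mean — on a bright-brain/dark-background image this
#'     keeps the brain.}
#'   \item{`"band"`}{include voxels within one SD of the global mean,
#'     `|v - mu| <= sigma`. On a bright-brain image this keeps the
#'     *background* and drops the brain; it is retained as a documented
#'     alternative, not the default.}
#'   \item{`"above_mean_minus_sd"`}{include voxels with `v >= mu - sigma`.}
#' }
#' SDs use the sample (N-1) denominator.
#'
#' @param mean_vol 3D numeric array, all finite.
#' @param rule_name One of the rules above.
#' @param rule_params Optional list (unused by the built-in rules; recorded).
#' @return A `brain_mask` object: logical array `mask` plus the rule used.
#' @export
brain_mask <- function(mean_vol, rule_name = c("above_mean", "band",
                                               "above_mean_minus_sd"),
                       rule_params = list()) {
  rule_name <- match.arg(rule_name)
  if (!all(is.finite(mean_vol))) stop("mean volume must be finite")
  mu <- mean(mean_vol)
  sig <- stats::sd(as.vector(mean_vol))
  mask <- switch(rule_name,
    above_mean = mean_vol >= mu,
    band = abs(mean_vol - mu) <= sig,
    above_mean_minus_sd = mean_vol >= mu - sig
  )
  if (!any(mask)) stop("brain mask is empty under rule '", rule_name, "'")
  structure(list(mask = mask, rule_name = rule_name,
                 rule_params = rule_params),
            class = "brain_mask")
}

#' Compute a run's brain mask
#'
#' Convenience wrapper: [mean_image()] followed by [brain_mask()]. Masks are
#' computed from unsmoothed data.
#' @inheritParams mean_image
#' @inheritParams brain_mask
#' @export
compute_brain_mask <- function(r, rule_name = "above_mean",
                               rule_params = list()) {
  brain_mask(mean_image(r), rule_name, rule_params)
}

# 1D Gaussian convolution matrix with edge renormalization: each output is a
# weighted average of in-range neighbors, so constants are preserved exactly.
gauss_band_matrix <- function(n, sigma_vox) {
  if (sigma_vox < 1e-8) return(diag(n))
  rad <- max(1L, ceiling(4 * sigma_vox))
  off <- (-rad):rad
  kern <- exp(-off^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- kern[ok] / sum(kern[ok])
  }
  K
}

#' Spatial Gaussian smoothing
#'
#' Convolves every frame with a separable 3D Gaussian kernel. The kernel
#' width is given as full width at half maximum in millimetres and converted
#' per axis to `sigma = fwhm / (2 sqrt(2 ln 2)) / voxel_size` voxels. At the
#' volume edges the truncated kernel is renormalized, so constant images are
#' unchanged.
#'
#' @param r An [fmri_run()].
#' @param fwhm Kernel full width at half maximum, mm (default 8; `0` is the
#'   identity).
#' @return Smoothed [fmri_run()].
#' @export
smooth_gaussian <- function(r, fwhm = 8) {
  stopifnot(inherits(r, "fmri_run"), fwhm >= 0)
  if (fwhm == 0) return(r)
  d <- dim(r$data)
  sig_vox <- fwhm / (2 * sqrt(2 * log(2))) / r$voxel_size
  x <- r$data
  # axis 1
  K <- gauss_band_matrix(d[1], sig_vox[1])
  x <- array(K %*% matrix(x, d[1]), d)
  # axis 2
  K <- gauss_band_matrix(d[2], sig_vox[2])
  x <- aperm(array(K %*% matrix(aperm(x, c(2, 1, 3, 4)), d[2]),
                   d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  # axis 3
  K <- gauss_band_matrix(d[3], sig_vox[3])
  x <- aperm(array(K %*% matrix(aperm(x, c(3, 1, 2, 4)), d[3]),
                   d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  r$data <- x
  r
}

#' Surround subtraction of a control/tag series
#'
#' Converts an alternating control/tag time series into a difference series
#' in which the labeling signal (perfusion or arterial volume) is isolated
#' and slow drift cancels. With sign `s_i = +1` for control frames and `-1`
#' for tag frames (0-based raw index `i`):
#' \deqn{out_0 = s_0 (x_0 - x_1), \quad
#'       out_i = s_i \left(x_i - \frac{x_{i-1} + x_{i+1}}{2}\right),\;
#'       1 \le i \le N-2,}
#' giving `N - 1` output frames. Interior outputs are exactly zero for any
#' signal affine in time, and a constant control-minus-tag offset `p` is
#' recovered as `p` at every output frame. Output frames keep the raw frame
#' times `t_0 ... t_{N-2}`, all roles become `"plain"`, and the modality
#' becomes `"subtracted"`.
#'
#' @param r An [fmri_run()] with modality `"asl"` or `"avast"`.
#' @return A subtracted [fmri_run()] with one fewer frame.
#' @export
surround_subtract <- function(r) {
  stopifnot(inherits(r, "fmri_run"))
  if (!r$modality %in% c("asl", "avast")) {
    stop("surround subtraction applies to control/tag runs, not ", r$modality)
  }
  n <- n_frames(r)
  if (n < 3) stop("need at least 3 frames for surround subtraction")
  d <- dim(r$data)
  x <- matrix(r$data, prod(d[1:3]), n)
  s <- ifelse(r$frame_roles == "control", 1, -1)
  out <- matrix(0, prod(d[1:3]), n - 1L)
  out[, 1] <- s[1] * (x[, 1] - x[, 2])
  if (n > 2) {
    i <- 2:(n - 1)
    out[, i] <- t(s[i] * t(x[, i] - (x[, i - 1] + x[, i + 1]) / 2))
  }
  fmri_run(array(out, c(d[1:3], n - 1L)), tr = r$tr, modality = "subtracted",
           frame_roles = rep("plain", n - 1L),
           frame_times = r$frame_times[seq_len(n - 1L)],
           voxel_size = r$voxel_size)
}

#' Voxel-wise temporal normalization
#'
#' Z-scores every voxel's time course: subtract its temporal mean, divide by
#' its temporal SD (sample, N-1 denominator). Voxels with zero variance are
#' set to all-zero. Idempotent up to floating point.
#'
#' @param r An [fmri_run()] with at least 2 frames.
#' @return Normalized [fmri_run()].
#' @export
normalize_voxelwise <- function(r) {
  stopifnot(inherits(r, "fmri_run"), n_frames(r) >= 2)
  d <- dim(r$data)
  x <- matrix(r$data, prod(d[1:3]), d[4])
  m <- rowMeans(x)
  x <- x - m
  sd <- sqrt(rowSums(x^2) / (d[4] - 1))
  keep <- sd > 0
  x[keep, ] <- x[keep, ] / sd[keep]
  x[!keep, ] <- 0
  r$data <- array(x, d)
  r
}

#' Temporal subsampling
#'
#' Keeps frames at indices `offset + 1, offset + 1 + stride, ...` (0-based
#' `offset`), multiplying the effective TR by `stride`. Used to equalize
#' example counts across contrasts with different native TRs (e.g. "sBOLD":
#' every other BOLD frame, effective TR 4 s).
#'
#' @param r An [fmri_run()].
#' @param stride Keep every `stride`-th frame (>= 1).
#' @param offset 0-based index of the first kept frame (`< stride`).
#' @return Subsampled [fmri_run()] with `tr = stride * tr`.
#' @export
subsample_run <- function(r, stride = 2L, offset = 0L) {
  stopifnot(inherits(r, "fmri_run"), stride >= 1, offset >= 0,
            offset < stride)
  idx <- seq(offset + 1L, n_frames(r), by = stride)
  r$data <- r$data[, , , idx, drop = FALSE]
  r$frame_roles <- r$frame_roles[idx]
  r$frame_times <- r$frame_times[idx]
  r$tr <- r$tr * stride
  r
}

#' Standard preprocessing chain for one run
#'
#' Control/tag runs: surround subtraction, then spatial smoothing, then
#' voxel-wise normalization. BOLD runs: smoothing, then normalization.
#' The brain mask is *not* applied here (masking happens when examples are
#' assembled) and should be computed from the unsmoothed run via
#' [compute_brain_mask()].
#'
#' @param r An [fmri_run()].
#' @param fwhm Smoothing kernel FWHM, mm.
#' @return Preprocessed [fmri_run()] (modality `"subtracted"` for asl/avast
#'   input).
#' @export
preprocess_run <- function(r, fwhm = 8) {
  stopifnot(inherits(r, "fmri_run"))
  if (r$modality %in% c("asl", "avast")) r <- surround_subtract(r)
  normalize_voxelwise(smooth_gaussian(r, fwhm))
}
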