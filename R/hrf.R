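#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma-density-shaped lobes: a positive response peaking
#' around `peak_delay` seconds and a negative undershoot peaking around
#' `undershoot_delay` seconds, scaled so the maximum over time equals 1.
#' Shapes are parameterized by the lobe modes directly
#' (`shape = delay / dispersion + 1`, `scale = dispersion`), so with unit
#' dispersion the positive lobe peaks exactly at `peak_delay`.
#'
#' @param t Time(s) since stimulus onset, seconds (`>= 0`).
#' @param peak_delay Mode of the positive lobe, seconds (default 6).
#' @param undershoot_delay Mode of the undershoot lobe, seconds (default 16).
#' @param undershoot_ratio Amplitude of the undershoot relative to the main
#'   lobe before normalization (default 1/6).
#' @param dispersion Common gamma scale parameter, seconds (default 1).
#' @return Dimensionless response sampled at `t`, with unit peak.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             undershoot_ratio = 1 / 6, dispersion = 1) {
  if (any(t < 0)) stop("hrf is defined for t >= 0")
  if (peak_delay <= 0 || undershoot_delay <= 0 || dispersion <= 0 ||
      undershoot_ratio < 0) {
    stop("hrf shape parameters must be positive (ratio nonnegative)")
  }
  lobe <- function(tt, delay) {
    # gamma density with mode `delay`, rescaled to unit peak
    shp <- delay / dispersion + 1
    stats::dgamma(tt, shape = shp, scale = dispersion) /
      stats::dgamma(delay, shape = shp, scale = dispersion)
  }
  raw <- function(tt) lobe(tt, peak_delay) - undershoot_ratio * lobe(tt, undershoot_delay)
  # unit-peak normalization over a fine grid covering both lobes
  grid <- seq(0, undershoot_delay + 16, by = 0.01)
  raw(t) / max(raw(grid))
}

#' Task regressor: block boxcar convolved with the HRF
#'
#' Convolves the paradigm's task indicator (1 during task blocks, 0 during
#' rest) with [hrf_double_gamma()] on a fine time grid and samples the result
#' at the requested times. The regressor is rescaled to unit maximum so that
#' the contrast-to-noise ratio of the synthetic generator reads directly as
#' peak activation amplitude over noise SD.
#'
#' @param p A [paradigm()].
#' @param times Sample times in seconds within `[0, total_duration)`.
#' @param dt Convolution grid step, seconds.
#' @param ... Passed to [hrf_double_gamma()].
#' @return Numeric vector of regressor values in `[min, 1]` at `times`.
#' @export
task_regressor <- function(p, times, dt = 0.1, ...) {
  stopifnot(inherits(p, "paradigm"))
  grid <- seq(0, p$total_duration - dt / 2, by = dt)
  box <- as.numeric(label_at_time(p, grid) > 0)
  h <- hrf_double_gamma(seq(0, 32, by = dt), ...)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)] * dt
  m <- max(conv)
  if (m > 0) conv <- conv / m
  idx <- pmin(pmax(floor(times / dt) + 1L, 1L), length(grid))
  conv[idx]
}
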