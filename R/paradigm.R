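#' Block stimulation paradigm
#'
#' Constructs the alternating task/rest block schedule used throughout the
#' package. A paradigm of `n_cycles` cycles contains `2 * n_cycles` blocks of
#' `block_duration` seconds each, strictly alternating between the two states,
#' starting with `first_state`. States are coded `+1` (task) and `-1` (rest).
#' Block `b` (0-based) spans the half-open interval
#' `[b * block_duration, (b + 1) * block_duration)`: a time exactly on a
#' boundary belongs to the *later* block.
#'
#' @param block_duration Duration of a single block in seconds (> 0).
#' @param n_cycles Number of task/rest cycles (>= 1).
#' @param first_state State of the first block, `+1` or `-1`.
#'
#' @return An object of class `paradigm` with fields `block_duration`,
#'   `n_cycles`, `first_state`, `total_duration`, `n_blocks`.
#'
#' @examples
#' p <- paradigm(30, 5)          # 300 s, 10 blocks, task first
#' label_at_time(p, 15)          # +1
#' transition_times(p)           # 30, 60, ..., 270
#' @export
paradigm <- function(block_duration, n_cycles, first_state = 1L) {
  if (!is.numeric(block_duration) || length(block_duration) != 1L ||
      !is.finite(block_duration) || block_duration <= 0) {
    stop("`block_duration` must be a single positive number of seconds")
  }
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L ||
      n_cycles < 1 || n_cycles != round(n_cycles)) {
    stop("`n_cycles` must be a positive whole number")
  }
  if (!first_state %in% c(1, -1)) {
    stop("`first_state` must be +1 (task) or -1 (rest)")
  }
  structure(
    list(
      block_duration = as.numeric(block_duration),
      n_cycles       = as.integer(n_cycles),
      first_state    = as.integer(first_state),
      n_blocks       = 2L * as.integer(n_cycles),
      total_duration = 2 * n_cycles * block_duration
    ),
    class = "paradigm"
  )
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf(
    "Block paradigm: %d x %.4g s blocks (%.4g s total), %s first, %d transitions\n",
    x$n_blocks, x$block_duration, x$total_duration,
    if (x$first_state > 0) "task (+1)" else "rest (-1)",
    x$n_blocks - 1L
  ))
  invisible(x)
}

#' State label at a given time
#'
#' Returns the task/rest label (`+1`/`-1`) of the block containing time `t`.
#' Vectorized over `t`. Boundaries follow the half-open block convention: the
#' label switches exactly at each transition time.
#'
#' @param p A [paradigm()].
#' @param t Time(s) in seconds, `0 <= t < total_duration`.
#' @return Integer vector of `+1`/`-1` labels.
#' @export
label_at_time <- function(p, t) {
  stopifnot(inherits(p, "paradigm"))
  if (any(t < 0 | t >= p$total_duration)) {
    stop("time outside run: need 0 <= t < ", p$total_duration)
  }
  block <- floor(t / p$block_duration)      # 0-based block index
  as.integer(p$first_state * (1L - 2L * (block %% 2)))
}

#' Times of state transitions
#'
#' The interior block boundaries of the paradigm, i.e. the instants at which
#' the subject switches between task and rest. A paradigm with `2 n` blocks
#' has `2 n - 1` transitions; `t = 0` and the run end are not transitions.
#'
#' @param p A [paradigm()].
#' @return Strictly increasing numeric vector of length `2 * n_cycles - 1`.
#' @export
transition_times <- function(p) {
  stopifnot(inherits(p, "paradigm"))
  p$block_duration * seq_len(p$n_blocks - 1L)
}

#' Frames excluded around state transitions
#'
#' For each transition, marks the last `k` frames (by acquisition time) of the
#' preceding block and the first `k` frames of the following block. These are
#' the frames acquired while the hemodynamic response is still ramping between
#' states; excluding them from training and testing removes the most
#' ambiguously labeled examples.
#'
#' @param p A [paradigm()].
#' @param frame_times Sorted ascending acquisition times in seconds, one per
#'   frame.
#' @param k Number of frames to drop on each side of every transition
#'   (`k = 0` excludes nothing).
#' @return Sorted integer vector of 1-based frame indices (possibly empty).
#'   A frame claimed by two adjacent transitions is reported once. If `k`
#'   exceeds the number of frames in some block the whole block is excluded,
#'   with a warning.
#' @export
excluded_frame_indices <- function(p, frame_times, k) {
  stopifnot(inherits(p, "paradigm"))
  if (length(frame_times) && is.unsorted(frame_times)) {
    stop("`frame_times` must be sorted ascending")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k)) {
    stop("`k` must be a nonnegative whole number")
  }
  k <- as.integer(k)
  if (k == 0L || length(frame_times) == 0L) return(integer(0))

  block_of <- floor(frame_times / p$block_duration)   # 0-based
  counts <- tabulate(block_of + 1L, nbins = p$n_blocks)
  if (any(counts > 0L & counts < k)) {
    warning("k exceeds the number of frames in at least one block; ",
            "entire block(s) excluded")
  }
  excl <- logical(length(frame_times))
  for (b in seq_len(p$n_blocks - 1L)) {       # transition after block b-1
    prev <- which(block_of == b - 1L)
    nxt  <- which(block_of == b)
    if (length(prev)) excl[utils::tail(prev, k)] <- TRUE
    if (length(nxt))  excl[utils::head(nxt, k)] <- TRUE
  }
  which(excl)
}
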