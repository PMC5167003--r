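# Shared fixtures: everything is generated in code at test time.

# Reduced study grid: same field of view as the full 64x64x11 acquisition
# grid, at coarse resolution, so geometry fractions are preserved.
small_grid <- function() grid_spec(16, 16, 4, voxel_size = c(15, 15, 16.5))

# Micro grid for the cheapest end-to-end runs.
micro_grid <- function() grid_spec(8, 8, 2, voxel_size = c(30, 30, 33))

small_params <- function(...) synth_params(grid = small_grid(), ...)

# A single-voxel control/tag run with prescribed frame values.
toy_ct_run <- function(values, tr = 1, modality = "asl",
                       control_first = TRUE) {
  n <- length(values)
  roles <- if (control_first) rep_len(c("control", "tag"), n)
           else rep_len(c("tag", "control"), n)
  fmri_run(array(values, c(1, 1, 1, n)), tr = tr, modality = modality,
           frame_roles = roles, frame_times = (seq_len(n) - 1) * tr,
           voxel_size = c(1, 1, 1))
}

# Label-independent example set: pure-noise features, balanced labels.
noise_example_set <- function(n = 40, d = 20, seed = 1) {
  set.seed(seed)
  structure(list(features = matrix(rnorm(n * d), n, d),
                 labels = rep(c(1L, -1L), length.out = n),
                 frame_times = seq_len(n),
                 voxel_index = cbind(x = seq_len(d), y = 1L, z = 1L),
                 mask = NULL),
            class = "example_set")
}

# Independent re-derivation of transition exclusion by direct enumeration
# over transitions (used as oracle against excluded_frame_indices).
enumerate_excluded <- function(p, frame_times, k) {
  if (k == 0) return(integer(0))
  out <- integer(0)
  for (tt in transition_times(p)) {
    prev <- which(frame_times >= tt - p$block_duration & frame_times < tt)
    nxt <- which(frame_times >= tt & frame_times < tt + p$block_duration)
    out <- c(out, utils::tail(prev, k), utils::head(nxt, k))
  }
  sort(unique(out))
}
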