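#' Assemble a labeled example set from a preprocessed run
#'
#' Each retained frame becomes one example whose features are the in-mask
#' voxel intensities of that frame; its class label (`+1` task / `-1` rest)
#' is the paradigm state at the frame's acquisition time. Frames within
#' `k_ignore` frames of a task/rest transition (on either side, per block)
#' are dropped via [excluded_frame_indices()]. For subtracted runs the
#' exclusion operates on the subtracted-series frames through their frame
#' times.
#'
#' Voxels are flattened in ascending `(z, y, x)` lexicographic order (`x`
#' fastest), i.e. the native array linear order, and the mapping is recorded
#' in `voxel_index` so weight vectors can be folded back into brain space
#' bit-exactly with [map_to_volume()].
#'
#' @param r A preprocessed [fmri_run()].
#' @param p The [paradigm()] of the run.
#' @param m A [brain_mask()] on the same grid.
#' @param k_ignore Transition frames to drop on each side of every boundary.
#' @return An `example_set`: list with `features` (examples x voxels matrix),
#'   `labels` (+1/-1), `frame_times`, `voxel_index` (n_features x 3 integer
#'   matrix of x, y, z), and the `mask`.
#' @export
build_examples <- function(r, p, m, k_ignore = 0L) {
  stopifnot(inherits(r, "fmri_run"), inherits(p, "paradigm"),
            inherits(m, "brain_mask"))
  d <- dim(r$data)
  if (!identical(dim(m$mask), d[1:3])) {
    stop("mask grid ", paste(dim(m$mask), collapse = "x"),
         " does not match run grid ", paste(d[1:3], collapse = "x"))
  }
  excl <- excluded_frame_indices(p, r$frame_times, k_ignore)
  keep <- setdiff(seq_len(d[4]), excl)
  if (!length(keep)) stop("all frames excluded at k_ignore = ", k_ignore)

  vox <- which(m$mask)                       # native linear order: x fastest
  X <- t(matrix(r$data, prod(d[1:3]), d[4])[vox, keep, drop = FALSE])
  idx <- arrayInd(vox, d[1:3])
  colnames(idx) <- c("x", "y", "z")
  structure(list(features = X,
                 labels = label_at_time(p, r$frame_times[keep]),
                 frame_times = r$frame_times[keep],
                 voxel_index = idx,
                 mask = m),
            class = "example_set")
}

#' @export
print.example_set <- function(x, ...) {
  cat(sprintf("<example_set> %d examples x %d features (+1: %d, -1: %d)\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels > 0), sum(x$labels < 0)))
  invisible(x)
}

#' Fold a per-feature vector back into brain space
#'
#' Inverse of the flattening performed by [build_examples()]: places `values`
#' (one per mask voxel, in the set's recorded voxel order) into a 3D volume,
#' with `fill` elsewhere.
#'
#' @param values Numeric (or logical) vector, one entry per feature.
#' @param es The `example_set` whose `voxel_index` defines the mapping.
#' @param fill Background value (default `NA`).
#' @return 3D array on the mask grid.
#' @export
map_to_volume <- function(values, es, fill = NA_real_) {
  stopifnot(inherits(es, "example_set"),
            length(values) == nrow(es$voxel_index))
  vol <- array(fill, dim(es$mask$mask))
  vol[es$voxel_index] <- values
  vol
}
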