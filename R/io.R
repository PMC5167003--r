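#' Write a run as NIfTI-1 plus a JSON sidecar
#'
#' The 4D data go to `<path>.nii.gz` (or the extension given) and the
#' acquisition metadata (TR, modality, frame roles, frame times, voxel size)
#' to `<path>.json`, so a run round-trips losslessly through [read_run()].
#'
#' @param r An [fmri_run()].
#' @param path Output path; `.nii` / `.nii.gz` appended if absent.
#' @return Invisibly, the NIfTI path written.
#' @export
write_run <- function(r, path) {
  stopifnot(inherits(r, "fmri_run"))
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  img <- RNifti::asNifti(r$data)
  RNifti::pixdim(img) <- c(r$voxel_size, r$tr)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(tr = r$tr, modality = r$modality, frame_roles = r$frame_roles,
         frame_times = r$frame_times, voxel_size = r$voxel_size),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run written by [write_run()]
#' @param path The NIfTI path (sidecar expected alongside).
#' @return An [fmri_run()].
#' @export
read_run <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  fmri_run(array(as.numeric(img), dim(img)), tr = meta$tr,
           modality = meta$modality, frame_roles = meta$frame_roles,
           frame_times = meta$frame_times, voxel_size = meta$voxel_size)
}

#' Write a 3D map (weights, p-values, masks) as NIfTI-1
#' @param vol 3D numeric or logical array.
#' @param path Output path; extension appended if absent.
#' @param voxel_size Length-3 mm per axis.
#' @return Invisibly, the path written.
#' @export
write_map <- function(vol, path, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(vol)) == 3)
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Serialize a paradigm to JSON
#' @param p A [paradigm()].
#' @param path Optional file; if `NULL`, the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
write_paradigm <- function(p, path = NULL) {
  stopifnot(inherits(p, "paradigm"))
  rec <- list(block_duration = p$block_duration, n_cycles = p$n_cycles,
              first_state = p$first_state)
  if (is.null(path)) {
    return(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deserialize a paradigm from JSON
#' @param x A file path or JSON string from [write_paradigm()].
#' @return A [paradigm()].
#' @export
read_paradigm <- function(x) {
  rec <- if (file.exists(x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else jsonlite::fromJSON(x)
  paradigm(rec$block_duration, rec$n_cycles, rec$first_state)
}

#' Write an example set as TSV plus a JSON manifest
#'
#' One row per example: `time`, `label`, then the feature columns in the
#' set's voxel order. The manifest records the voxel index map and mask
#' provenance so [read_examples()] reconstructs the set.
#'
#' @param es An `example_set`.
#' @param path TSV path; the manifest goes to `<path>.json`.
#' @return Invisibly, the TSV path.
#' @export
write_examples <- function(es, path) {
  stopifnot(inherits(es, "example_set"))
  df <- data.frame(time = es$frame_times, label = es$labels,
                   es$features, check.names = FALSE)
  colnames(df) <- c("time", "label",
                    paste0("v", seq_len(ncol(es$features))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(voxel_index = as.data.frame(es$voxel_index),
         mask_dim = dim(es$mask$mask),
         mask_rule = es$mask$rule_name),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an example set written by [write_examples()]
#' @param path The TSV path.
#' @return An `example_set`.
#' @export
read_examples <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  idx <- as.matrix(meta$voxel_index)
  storage.mode(idx) <- "integer"
  dimnames(idx) <- list(NULL, c("x", "y", "z"))
  mask <- array(FALSE, unlist(meta$mask_dim))
  mask[idx] <- TRUE
  structure(list(features = as.matrix(df[, -(1:2), drop = FALSE]),
                 labels = as.integer(df$label),
                 frame_times = df$time,
                 voxel_index = idx,
                 mask = structure(list(mask = mask,
                                       rule_name = meta$mask_rule,
                                       rule_params = list()),
                                  class = "brain_mask")),
            class = "example_set")
}

#' Serialize an SVM model to JSON
#' @param m An `svm_model`.
#' @param path Optional file; if `NULL`, the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
write_svm_model <- function(m, path = NULL) {
  stopifnot(inherits(m, "svm_model"))
  rec <- unclass(m)
  if (is.null(path)) {
    return(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
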