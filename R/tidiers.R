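#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SVM model into one row per feature
#'
#' @param x An `svm_model`.
#' @param ... Unused.
#' @return Tibble with columns `feature` and `weight` (plus the bias is in
#'   [glance.svm_model()]).
#' @export
tidy.svm_model <- function(x, ...) {
  tibble::tibble(feature = seq_along(x$w), weight = x$w)
}

#' One-row summary of an SVM model
#' @param x An `svm_model`.
#' @param ... Unused.
#' @export
glance.svm_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$w), n_train = x$n_train,
                 C = x$C, bias = x$bias, b = x$b,
                 n_support = length(x$support_indices),
                 objective = x$objective,
                 train_error = mean(x$slacks >= 1))
}

#' Tidy a permutation result into one row per voxel
#'
#' @param x A `perm_result`.
#' @param ... Unused.
#' @return Tibble with voxel coordinates, normalized weight, exceedance
#'   count, p-value and significance flag.
#' @export
tidy.perm_result <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$voxel_index))
  out$weight <- x$w_orig_norm
  out$exceedance_count <- x$exceedance_counts
  out$p_value <- x$p_values
  out$significant <- x$significant_mask
  out
}

#' One-row summary of a permutation result
#' @param x A `perm_result`.
#' @param ... Unused.
#' @export
glance.perm_result <- function(x, ...) {
  tibble::tibble(n_voxels = length(x$p_values), n_perm = x$n_perm,
                 statistic = x$statistic, alpha = x$alpha,
                 n_significant = sum(x$significant_mask),
                 dice_vs_truth = if (is.null(x$dice_vs_truth)) NA_real_
                                 else x$dice_vs_truth)
}
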