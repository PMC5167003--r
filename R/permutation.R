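#' Normalize a weight vector to unit standard deviation
#'
#' Divides the weight vector by its sample SD (N-1 denominator) so weight
#' maps from differently scaled trainings are comparable. An all-zero (or
#' constant-zero-SD) vector is returned unchanged.
#'
#' @param w Numeric vector, length >= 2.
#' @return Rescaled vector with `sd(w) == 1` (unless degenerate).
#' @export
normalize_weights <- function(w) {
  stopifnot(length(w) >= 2)
  s <- stats::sd(w)
  if (!is.finite(s) || s == 0) return(w)
  w / s
}

#' Label-permutation null for the SVM weight map
#'
#' Estimates, voxel by voxel, how extreme the trained SVM weight is relative
#' to an empirical null obtained by retraining on randomly permuted class
#' labels. The model is trained once with the true labels; its weight vector
#' is normalized to unit SD ([normalize_weights()]). Then `n_perm`
#' permutations of the labels are drawn (uniformly over rearrangements,
#' which preserve the class counts), the SVM retrained on each, its weights
#' normalized the same way, and for every voxel the number of permutations
#' in which the permuted statistic meets or exceeds the original statistic
#' is accumulated. The empirical p-value is that exceedance count divided by
#' `n_perm`.
#'
#' Two exceedance statistics are available: `"absolute"` (default) compares
#' `|w|`, a two-sided test matching the view that a voxel's discriminative
#' importance is the magnitude of its weight; `"signed"` compares the raw
#' weights, the literal one-sided count. With `add_one = TRUE` the p-value
#' is `(count + 1) / (n_perm + 1)`, guaranteeing nonzero p-values.
#'
#' Permuted weight vectors are not retained — only the running counts — so
#' memory is independent of `n_perm`.
#'
#' @param es An `example_set` (both classes present).
#' @param C SVM trade-off parameter.
#' @param n_perm Number of permutations (>= 1; large studies use 2000).
#' @param seed Integer seed of the permutation stream.
#' @param statistic `"absolute"` or `"signed"`.
#' @param block_permute Permute labels as whole paradigm blocks (examples
#'   grouped by containing block) instead of freely; off by default, for
#'   strongly autocorrelated series.
#' @param p A [paradigm()]; required when `block_permute = TRUE`.
#' @param add_one Use the `(count + 1) / (n_perm + 1)` estimator.
#' @param alpha Significance level for the thresholded map (default 0.01).
#' @param ... Passed to [train_svm()].
#' @return A `perm_result`: `w_orig_norm`, `exceedance_counts`, `n_perm`,
#'   `p_values`, `alpha`, `significant_mask`, `statistic`, `seed`.
#' @export
permutation_null <- function(es, C = 1, n_perm = 2000L, seed = 1L,
                             statistic = c("absolute", "signed"),
                             block_permute = FALSE, p = NULL,
                             add_one = FALSE, alpha = 0.01, ...) {
  stopifnot(inherits(es, "example_set"))
  statistic <- match.arg(statistic)
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  y <- es$labels
  n <- length(y)
  if (block_permute) {
    if (is.null(p)) stop("block_permute needs the paradigm `p`")
    block_of <- floor(es$frame_times / p$block_duration)
    blocks <- sort(unique(block_of))
    block_lab <- vapply(blocks, function(b) y[block_of == b][1], numeric(1))
  }

  m0 <- train_svm(es, C = C, ...)
  w0 <- normalize_weights(m0$w)
  s0 <- if (statistic == "absolute") abs(w0) else w0

  counts <- integer(length(w0))
  with_local_seed(seed, {
    for (it in seq_len(n_perm)) {
      yp <- if (block_permute) {
        perm <- sample(block_lab)
        perm[match(block_of, blocks)]
      } else {
        sample(y)
      }
      mp <- train_svm(es$features, C = C, labels = yp, ...)
      wp <- normalize_weights(mp$w)
      sp <- if (statistic == "absolute") abs(wp) else wp
      counts <- counts + (sp >= s0)
    }
  })
  pv <- if (add_one) (counts + 1) / (n_perm + 1) else counts / n_perm
  structure(list(w_orig_norm = w0, exceedance_counts = counts,
                 n_perm = n_perm, p_values = pv, alpha = alpha,
                 significant_mask = pv < alpha, statistic = statistic,
                 seed = seed, voxel_index = es$voxel_index),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "<perm_result> %d voxels, %d permutations (%s statistic): %d significant at p < %g\n",
    length(x$p_values), x$n_perm, x$statistic,
    sum(x$significant_mask), x$alpha))
  invisible(x)
}

#' Threshold a permutation result
#'
#' Voxels with empirical `p < alpha` are marked significant. With `n_perm`
#' permutations this is exactly the rule "exceedance count below
#' `alpha * n_perm`" whenever `alpha * n_perm` is an integer (e.g. a
#' critical count of 20 at the 1% level with 2000 permutations).
#'
#' @param pr A `perm_result`.
#' @param alpha Significance level in `(0, 1)`.
#' @return Logical vector, one entry per voxel.
#' @export
significance_threshold <- function(pr, alpha = 0.01) {
  stopifnot(inherits(pr, "perm_result"), alpha > 0, alpha < 1)
  pr$p_values < alpha
}

#' Dice overlap between a detected mask and a reference mask
#'
#' `2 |A n B| / (|A| + |B|)`; 0 when both are empty.
#' @param a,b Logical vectors/arrays of equal length.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}
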