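#' Train a linear soft-margin SVM
#'
#' Fits the two-class linear SVM minimizing
#' \deqn{\|w\|^2 + C \sum_i \xi_i \quad \text{s.t.}\quad
#'       y_i (w^\top x_i + b) \ge 1 - \xi_i,\; \xi_i \ge 0,}
#' the trade-off form in which `C` penalizes margin violations directly
#' (note: no 1/2 on the quadratic term). Solvers working with
#' `1/2 ||w||^2 + C' sum xi` are equivalent under `C' = C / 2`; the default
#' backend (libsvm via \pkg{e1071}) is called with that mapping, so the
#' reported `C` always refers to the objective above.
#'
#' With `bias = FALSE` the hyperplane is forced through the origin
#' (`f(x) = w^T x`); this uses an internal dual coordinate-descent solver,
#' since the dual then has no equality constraint.
#'
#' @param x An `example_set` (from [build_examples()]), or a numeric feature
#'   matrix (examples in rows) with `labels` supplied.
#' @param C Trade-off parameter, > 0 (default 1).
#' @param labels Numeric `+1`/`-1` labels (only when `x` is a matrix).
#' @param bias Include an intercept term `b` (default `TRUE`).
#' @param tolerance Solver termination tolerance (default `1e-8`).
#' @return An `svm_model`: `w` (length `n_features`), `b`, `C`, `bias`,
#'   `support_indices`, `slacks` (`max(0, 1 - y f)` per training example),
#'   `objective` (the value of the objective above at the solution) and
#'   `n_train`.
#' @export
train_svm <- function(x, C = 1, labels = NULL, bias = TRUE,
                      tolerance = 1e-8) {
  if (inherits(x, "example_set")) {
    X <- x$features
    y <- x$labels
  } else {
    X <- as.matrix(x)
    y <- labels
  }
  if (is.null(y) || length(y) != nrow(X)) {
    stop("labels must match the number of examples")
  }
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  if (!is.numeric(C) || C <= 0) stop("C must be positive")

  if (bias) {
    # libsvm orients the separating plane by the first class it sees;
    # presenting the +1 examples first fixes the orientation regardless of
    # input order.
    ord <- order(y, decreasing = TRUE)
    fit <- e1071::svm(X[ord, , drop = FALSE],
                      factor(y[ord], levels = c(1, -1)), kernel = "linear",
                      cost = C / 2, scale = FALSE, tolerance = tolerance,
                      shrinking = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    sv <- sort(ord[fit$index])
  } else {
    cd <- svm_dual_cd(X, y, Cprime = C / 2, tol = tolerance)
    w <- cd$w
    b <- 0
    sv <- which(cd$alpha > tolerance)
  }
  f <- drop(X %*% w) + b
  slacks <- pmax(0, 1 - y * f)
  structure(list(w = as.numeric(w), b = as.numeric(b), C = C, bias = bias,
                 support_indices = sv, slacks = slacks,
                 objective = sum(w^2) + C * sum(slacks),
                 n_train = nrow(X)),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf(
    "<svm_model> %d features, C = %g, %s, %d support vectors, objective %.6g\n",
    length(x$w), x$C, if (x$bias) sprintf("b = %.4g", x$b) else "no bias",
    length(x$support_indices), x$objective))
  invisible(x)
}

# Dual coordinate descent for the bias-free linear SVM:
# min 1/2 a'Qa - 1'a, 0 <= a <= Cprime, Q = (yy') * (XX'). Deterministic
# cyclic sweeps from a zero start.
svm_dual_cd <- function(X, y, Cprime, tol = 1e-8, max_sweeps = 100000L) {
  n <- nrow(X)
  qii <- rowSums(X^2)
  alpha <- numeric(n)
  w <- numeric(ncol(X))
  for (sweep in seq_len(max_sweeps)) {
    delta_max <- 0
    for (i in seq_len(n)) {
      g <- y[i] * sum(w * X[i, ]) - 1
      if (qii[i] > 0) {
        a_new <- min(max(alpha[i] - g / qii[i], 0), Cprime)
      } else {
        a_new <- if (g < 0) Cprime else 0
      }
      d <- a_new - alpha[i]
      if (d != 0) {
        w <- w + d * y[i] * X[i, ]
        alpha[i] <- a_new
        delta_max <- max(delta_max, abs(d) * max(qii[i], 1))
      }
    }
    if (delta_max < tol) break
  }
  if (delta_max >= tol) {
    stop("bias-free SVM solver did not converge (last update ", delta_max, ")")
  }
  list(alpha = alpha, w = w)
}

#' Decision values of a linear SVM
#'
#' @param m An `svm_model`.
#' @param X Feature matrix (or `example_set`) with columns matching `m$w`.
#' @return Numeric vector `w . x + b` per row.
#' @export
decision_values <- function(m, X) {
  stopifnot(inherits(m, "svm_model"))
  if (inherits(X, "example_set")) X <- X$features
  X <- rbind(X)                      # promote a single example
  if (ncol(X) != length(m$w)) {
    stop("feature dimension ", ncol(X), " does not match model (",
         length(m$w), ")")
  }
  drop(X %*% m$w) + m$b
}

#' Predict class labels
#'
#' Sign of the decision function; an exact zero is assigned to `+1`
#' (documented tie-break).
#' @inheritParams decision_values
#' @return Integer vector of `+1`/`-1`.
#' @export
predict_labels <- function(m, X) {
  f <- decision_values(m, X)
  ifelse(f >= 0, 1L, -1L)
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  predict_labels(object, newdata)
}

check_matching_features <- function(a, b) {
  if (ncol(a$features) != ncol(b$features) ||
      !identical(a$voxel_index, b$voxel_index)) {
    stop("example sets live in different feature spaces ",
         "(mask or voxel order differs)")
  }
}

#' Cross-run classification accuracy
#'
#' Trains on one run's example set and reports the fraction of correctly
#' classified examples of the other run — the study design in which run 1
#' trains and run 2 tests. Both sets must share the mask and voxel order.
#'
#' @param train_set,test_set `example_set`s over the same feature space.
#' @param C SVM trade-off parameter.
#' @param ... Passed to [train_svm()].
#' @return Accuracy in `[0, 1]`.
#' @export
cross_run_accuracy <- function(train_set, test_set, C = 1, ...) {
  check_matching_features(train_set, test_set)
  m <- train_svm(train_set, C = C, ...)
  mean(predict_labels(m, test_set$features) == test_set$labels)
}

#' Both-direction cross-run accuracy
#'
#' Evaluates run 1 -> run 2 and run 2 -> run 1 and their mean.
#' @param set1,set2 `example_set`s over the same feature space.
#' @inheritParams cross_run_accuracy
#' @return Tibble with columns `direction` (`"1->2"`, `"2->1"`, `"mean"`)
#'   and `accuracy`.
#' @export
paired_accuracy <- function(set1, set2, C = 1, ...) {
  a12 <- cross_run_accuracy(set1, set2, C = C, ...)
  a21 <- cross_run_accuracy(set2, set1, C = C, ...)
  tibble::tibble(direction = c("1->2", "2->1", "mean"),
                 accuracy = c(a12, a21, (a12 + a21) / 2))
}

#' Exact small-instance SVM reference solver
#'
#' Solves the dual of the soft-margin linear SVM *exactly* by enumerating
#' active sets: every assignment of the dual variables to \{lower bound,
#' free, upper bound\} is tried, the stationarity system solved for the free
#' block, and Karush-Kuhn-Tucker feasibility checked. Intended as an
#' independent reference for problems with at most ~8 examples; cost grows
#' as `3^n`. The objective reported is the same trade-off form as
#' [train_svm()] (`||w||^2 + C sum xi`).
#'
#' @param X Feature matrix (examples in rows).
#' @param y `+1`/`-1` labels.
#' @param C Trade-off parameter.
#' @param bias Include an intercept.
#' @param tol Feasibility tolerance of the enumeration.
#' @return List with `w`, `b`, `alpha`, `objective` and `dual_objective`
#'   (of the internal `1/2`-scaled dual).
#' @export
svm_solve_exact <- function(X, y, C = 1, bias = TRUE, tol = 1e-7) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n > 10L) stop("exact enumeration solver is for small instances only")
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L) {
    stop("need both classes with +1/-1 labels")
  }
  Cp <- C / 2                                 # map to 1/2||w||^2 + Cp sum xi
  Q <- (y %o% y) * tcrossprod(X)
  best <- NULL
  states <- expand.grid(rep(list(c("L", "F", "U")), n),
                        stringsAsFactors = FALSE)
  for (row in seq_len(nrow(states))) {
    st <- unlist(states[row, ], use.names = FALSE)
    Fi <- which(st == "F"); Ui <- which(st == "U")
    alpha <- numeric(n)
    alpha[Ui] <- Cp
    nu <- 0
    if (length(Fi)) {
      rhs <- rep(1, length(Fi)) -
        if (length(Ui)) rowSums(Q[Fi, Ui, drop = FALSE]) * Cp else 0
      if (bias) {
        A <- rbind(cbind(Q[Fi, Fi, drop = FALSE], y[Fi]), c(y[Fi], 0))
        bvec <- c(rhs, -sum(y[Ui]) * Cp)
      } else {
        A <- Q[Fi, Fi, drop = FALSE]
        bvec <- rhs
      }
      sol <- tryCatch(solve(A, bvec), error = function(e) NULL)
      if (is.null(sol) || any(!is.finite(sol))) next
      if (max(abs(A %*% sol - bvec)) > tol) next
      aF <- sol[seq_along(Fi)]
      if (bias) nu <- sol[length(sol)]
      if (any(aF < -tol) || any(aF > Cp + tol)) next
      alpha[Fi] <- pmin(pmax(aF, 0), Cp)
    } else if (bias) {
      if (abs(sum(y[Ui]) * Cp) > tol) next    # equality constraint
    }
    g <- drop(Q %*% alpha) - 1
    if (bias && !length(Fi)) {
      # nu must satisfy the bound-set KKT inequalities; take the midpoint
      lo <- suppressWarnings(max(c(-Inf,
        -g[st == "L" & y > 0], g[st == "U" & y < 0])))
      hi <- suppressWarnings(min(c(Inf,
        -g[st == "U" & y > 0], g[st == "L" & y < 0])))
      if (lo > hi + tol) next
      nu <- mean(c(max(lo, min(hi, 0)), min(hi, max(lo, 0))))
    }
    kkt <- g + if (bias) nu * y else 0
    if (any(kkt[st == "L"] < -tol) || any(kkt[st == "U"] > tol)) next
    dual <- sum(alpha) - 0.5 * drop(alpha %*% Q %*% alpha)
    if (is.null(best) || dual > best$dual + 1e-12) {
      best <- list(alpha = alpha, nu = nu, dual = dual, Fi = Fi)
    }
  }
  if (is.null(best)) stop("no KKT point found (numerically degenerate input)")
  w <- drop(t(X) %*% (best$alpha * y))
  b <- if (!bias) 0 else if (length(best$Fi)) {
    mean(y[best$Fi] - drop(X[best$Fi, , drop = FALSE] %*% w))
  } else {
    # minimize the hinge sum over its breakpoints (piecewise-linear convex)
    cand <- y - drop(X %*% w)
    cand[which.min(vapply(cand, function(bb)
      sum(pmax(0, 1 - y * (drop(X %*% w) + bb))), numeric(1)))]
  }
  obj <- sum(w^2) + C * sum(pmax(0, 1 - y * (drop(X %*% w) + b)))
  list(w = w, b = b, alpha = best$alpha, objective = obj,
       dual_objective = best$dual)
}
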