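test_that("symmetric two-point problem gives the unit-margin hyperplane", {
  m <- train_svm(matrix(c(1, -1), 2, 1), labels = c(1, -1), C = 1,
                 tolerance = 1e-10)
  expect_equal(m$w, 1, tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-6)
  expect_equal(m$slacks, c(0, 0), tolerance = 1e-6)
  expect_setequal(m$support_indices, 1:2)
  expect_equal(m$objective, 1, tolerance = 1e-6)
})

test_that("trained objective matches the exact dual enumeration", {
  X <- rbind(c(2, 0), c(3, 1), c(-2, 0), c(-3, -1))
  y <- c(1, 1, -1, -1)
  o <- svm_solve_exact(X, y, C = 1)
  m <- train_svm(X, labels = y, C = 1, tolerance = 1e-10)
  expect_lt(abs(m$objective - o$objective), 1e-6)
  # the printed objective is twice the half-scaled dual optimum
  expect_equal(o$objective, 2 * o$dual_objective, tolerance = 1e-9)

  # C mapping holds away from C = 1 too
  o3 <- svm_solve_exact(X, y, C = 3)
  m3 <- train_svm(X, labels = y, C = 3, tolerance = 1e-10)
  expect_lt(abs(m3$objective - o3$objective), 1e-6)
})

test_that("random small instances satisfy oracle equivalence and KKT", {
  for (i in 1:25) {
    set.seed(i)
    n <- sample(3:6, 1); d <- sample(1:3, 1)
    X <- matrix(stats::rnorm(n * d), n)
    y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    m <- train_svm(X, labels = y, C = 1, tolerance = 1e-10)
    o <- svm_solve_exact(X, y, C = 1)
    expect_lt(abs(m$objective - o$objective), 1e-6)
    # complementary slackness: slack > 0 only at bound-saturated duals;
    # margin violations imply slack = 1 - y f exactly
    f <- decision_values(m, X)
    expect_equal(m$slacks, pmax(0, 1 - y * f), tolerance = 1e-12)
  }
})

test_that("bias-free mode matches the bias-free oracle", {
  for (i in 1:10) {
    set.seed(100 + i)
    n <- sample(3:6, 1); d <- sample(1:3, 1)
    X <- matrix(stats::rnorm(n * d), n)
    y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    m <- train_svm(X, labels = y, C = 1, bias = FALSE)
    o <- svm_solve_exact(X, y, C = 1, bias = FALSE)
    expect_equal(m$b, 0)
    expect_lt(abs(m$objective - o$objective), 1e-6)
  }
})

test_that("decision values, prediction and the zero tie-break", {
  m <- structure(list(w = 1, b = 0, C = 1, bias = TRUE,
                      support_indices = integer(0), slacks = numeric(0),
                      objective = NA_real_, n_train = 0L),
                 class = "svm_model")
  expect_equal(decision_values(m, matrix(c(0, 2), 2, 1)), c(0, 2))
  expect_equal(predict_labels(m, matrix(c(-0.5, 0.2, 0), 3, 1)),
               c(-1L, 1L, 1L))
  expect_error(decision_values(m, matrix(0, 1, 3)), "dimension")
})

test_that("separable clusters train to perfect accuracy with unit margins", {
  set.seed(9)
  X <- rbind(matrix(stats::rnorm(40, 10), 20), matrix(stats::rnorm(40, -10), 20))
  y <- rep(c(1, -1), each = 20)
  m <- train_svm(X, labels = y, C = 1, tolerance = 1e-10)
  expect_equal(predict_labels(m, X), y)
  f <- decision_values(m, X)
  expect_equal(min(abs(f[m$support_indices])), 1, tolerance = 1e-4)
})

test_that("hard-margin weights scale inversely with feature scale", {
  set.seed(10)
  X <- rbind(matrix(stats::rnorm(20, 5), 10), matrix(stats::rnorm(20, -5), 10))
  y <- rep(c(1, -1), each = 10)
  w1 <- train_svm(X, labels = y, C = 1e3, tolerance = 1e-10)$w
  w3 <- train_svm(3 * X, labels = y, C = 1e3, tolerance = 1e-10)$w
  expect_equal(w3, w1 / 3, tolerance = 1e-4)
})

test_that("example order does not affect the solution", {
  set.seed(12)
  X <- matrix(stats::rnorm(60), 20, 3)
  y <- rep(c(1, -1), 10)
  m1 <- train_svm(X, labels = y, C = 1, tolerance = 1e-10)
  perm <- sample(20)
  m2 <- train_svm(X[perm, ], labels = y[perm], C = 1, tolerance = 1e-10)
  expect_equal(m1$w, m2$w, tolerance = 1e-6)
  expect_equal(m1$b, m2$b, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  expect_error(train_svm(matrix(1:4, 2), labels = c(1, 1)), "single class")
  expect_error(train_svm(matrix(1:4, 2), labels = c(1, -1), C = 0), "positive")
  expect_error(train_svm(matrix(1:4, 2), labels = c(1, 2)), "\\+1/-1")
})

test_that("cross-run accuracy is 1 on itself and chance on pure noise", {
  set.seed(14)
  X <- rbind(matrix(stats::rnorm(40, 6), 20), matrix(stats::rnorm(40, -6), 20))
  y <- rep(c(1L, -1L), each = 20)
  idx <- cbind(x = 1:2, y = 1L, z = 1L)
  es <- structure(list(features = X, labels = y, frame_times = seq_len(40),
                       voxel_index = idx, mask = NULL),
                  class = "example_set")
  expect_equal(cross_run_accuracy(es, es), 1)
  pa <- paired_accuracy(es, es)
  expect_equal(pa$accuracy, rep(1, 3))
  expect_equal(pa$direction, c("1->2", "2->1", "mean"))

  accs <- vapply(1:30, function(s) {
    a <- noise_example_set(60, 5, seed = s)
    b <- noise_example_set(60, 5, seed = 1000 + s)
    cross_run_accuracy(a, b)
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("mismatched feature spaces are rejected", {
  a <- noise_example_set(10, 4)
  b <- noise_example_set(10, 5)
  expect_error(cross_run_accuracy(a, b), "feature spaces")
})
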