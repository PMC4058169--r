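test_that("the symmetric two-point problem is solved exactly", {
  m <- svm_train(toy_two_points(), kernel_linear(), C = 10, tol = 1e-8)
  expect_equal(m$alphas, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(m$bias, 0, tolerance = 1e-8)
  expect_equal(dual_objective(m), 0.5, tolerance = 1e-8)
  pred <- predict(m, c(1, 0))
  expect_equal(as.vector(pred), 1)
  expect_equal(attr(pred, "decision"), 1, tolerance = 1e-6)
})

test_that("SMO reaches the brute-force dual optimum on tiny instances", {
  kernels <- list(kernel_linear(), kernel_rbf(1))
  set.seed(100)
  cases <- expand.grid(n = 3:6, C = c(0.5, 10))
  for (r in seq_len(nrow(cases))) {
    n <- cases$n[r]; C <- cases$C[r]
    d <- random_dataset(n, d = 2)
    for (kern in kernels) {
      m <- svm_train(d, kern, C = C, tol = 1e-6)
      oracle <- dual_oracle(d, kern, C)
      expect_lt(abs(dual_objective(m) - oracle$objective),
                1e-5 * (abs(oracle$objective) + 1e-12),
                label = sprintf("n=%d C=%g kernel=%s rel gap", n, C, kern$kind))
      # SMO objective is also >= any feasible alpha the oracle found
      expect_gte(dual_objective(m) + 1e-7, oracle$objective)
    }
  }
})

test_that("SMO agrees with an interior-point QP solve of the same dual", {
  # independent second oracle via kernlab::ipop on a 6-point instance
  d <- random_dataset(6, d = 2, seed = 7)
  C <- 2
  kern <- kernel_rbf(0.9)
  m <- svm_train(d, kern, C = C, tol = 1e-6)
  H <- (d$labels %o% d$labels) * kernel_matrix(kern, d$features)
  qp <- kernlab::ipop(c = rep(-1, 6), H = H, A = matrix(d$labels, 1),
                      b = 0, l = rep(0, 6), u = rep(C, 6), r = 0)
  a <- kernlab::primal(qp)
  qp_obj <- sum(a) - 0.5 * drop(crossprod(a, H %*% a))
  expect_lt(abs(dual_objective(m) - qp_obj), 1e-4 * (abs(qp_obj) + 1))
})

test_that("trained models satisfy feasibility and KKT conditions", {
  set.seed(11)
  for (case in 1:4) {
    n <- 30
    C <- c(0.1, 1, 10, 100)[case]
    d <- random_dataset(n, d = 3)
    tol <- 1e-3
    m <- svm_train(d, kernel_rbf(1), C = C, tol = tol)
    a <- m$alphas
    # box and equality constraints
    expect_true(all(a >= -1e-12 & a <= C + 1e-12))
    expect_lt(abs(sum(a * d$labels)), 1e-8 * (sum(a) + 1))
    # KKT at tolerance: margins consistent with each alpha's status
    yf <- d$labels * decision_values(m, d$features)
    expect_true(all(yf[a < 1e-8 * C] >= 1 - 2 * tol))
    free <- a > 1e-8 * C & a < C * (1 - 1e-8)
    expect_true(all(abs(yf[free] - 1) <= 2 * tol))
    expect_true(all(yf[a >= C * (1 - 1e-8)] <= 1 + 2 * tol))
  }
})

test_that("tiny C keeps every alpha inside the shrunken box", {
  d <- random_dataset(20, seed = 5)
  m <- suppressWarnings(svm_train(d, kernel_linear(), C = 1e-6))
  expect_true(all(m$alphas <= 1e-6 + 1e-18))
  expect_true(all(m$alphas >= 0))
})

test_that("negating the labels negates the predictions", {
  d <- random_dataset(16, seed = 21)
  flipped <- labeled_dataset(d$features, -d$labels)
  m1 <- svm_train(d, kernel_rbf(1), C = 5, tol = 1e-5)
  m2 <- svm_train(flipped, kernel_rbf(1), C = 5, tol = 1e-5)
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(decision_values(m2, X), -decision_values(m1, X),
               tolerance = 1e-4)
})

test_that("duplicating every point leaves the linear decision boundary intact", {
  # holds when no alpha sits at the box bound (separable, generous C), where
  # the alpha mass can redistribute freely across the duplicates
  d <- generate_synthetic(c(10, 10), 2, separation = 8, seed = 8)
  doubled <- labeled_dataset(rbind(d$features, d$features),
                             c(d$labels, d$labels))
  m1 <- svm_train(d, kernel_linear(), C = 100, tol = 1e-6)
  m2 <- svm_train(doubled, kernel_linear(), C = 100, tol = 1e-6)
  expect_lt(max(m1$alphas), 100)  # unbounded regime, precondition
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(decision_values(m1, X), decision_values(m2, X),
               tolerance = 1e-3)
})

test_that("bias shifts with a translated problem and ties go to +1", {
  # shifting both classes along the separating axis moves b so the midpoint
  # stays on the boundary: for the toy pair shifted by delta, f(delta, 0) = 0
  delta <- 3
  shifted <- labeled_dataset(rbind(c(1 + delta, 0), c(-1 + delta, 0)), c(1, -1))
  m <- svm_train(shifted, kernel_linear(), C = 10, tol = 1e-8)
  expect_equal(decision_values(m, c(delta, 0)), 0, tolerance = 1e-6)
  expect_equal(m$bias, -delta, tolerance = 1e-6)
  # exact zero decision value maps to +1
  expect_equal(as.vector(predict(m, c(delta, 0))), 1)
})

test_that("training rejects degenerate input and sigmoid kernels warn", {
  one_class <- labeled_dataset(matrix(rnorm(8), 4), rep(1, 4))
  expect_error(svm_train(one_class), "single class")
  d <- random_dataset(10, seed = 3)
  expect_warning(svm_train(d, kernel_sigmoid(1, 0), C = 1), "sigmoid")
})

test_that("a saved model reloads and predicts identically", {
  d <- random_dataset(25, d = 3, seed = 14)
  m <- svm_train(d, kernel_rbf(0.7), C = 3)
  path <- withr::local_tempfile(fileext = ".json")
  svm_save(m, path)
  m2 <- svm_load(path)
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(decision_values(m2, X), decision_values(m, X), tolerance = 1e-12)
  expect_equal(m2$kernel$params$sigma, 0.7)
})
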