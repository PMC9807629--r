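test_that("kernel_eval: rbf limits and linear dot product", {
  expect_equal(kernel_eval(kernel_spec("rbf", 2), c(1, 2), c(1, 2)), 1)
  expect_gt(kernel_eval(kernel_spec("rbf", 1e3), 0, 1), 0.999)
  expect_equal(kernel_eval(kernel_spec("linear"), c(1, 2), c(3, 4)), 11)
  # parameterization is exp(-d2 / sigma^2)
  expect_equal(kernel_eval(kernel_spec("rbf", 2), 0, 3), exp(-9 / 4))
  expect_error(kernel_eval(kernel_spec("rbf"), 1:2, 1:3), "dimension")
  expect_error(kernel_spec("rbf", sigma = -1), "sigma")
})

test_that("single point: alpha forced to 1, zero radius, inside", {
  m <- fit_svdd(matrix(c(3, 4), 1, 2), C = 1)
  expect_equal(m$alphas, 1)
  expect_equal(m$radius_sq, 0)
  expect_equal(decision_distance(m, c(3, 4)), 0, tolerance = 1e-12)
  expect_equal(predict_sphere(m, c(3, 4)), "inside")
})

test_that("two-point linear model matches the hand derivation", {
  # points {0, 2}: dual = 4 a2 - 4 a2^2, maximized at a2 = 1/2
  m <- fit_svdd(matrix(c(0, 2), 2, 1), C = 1, kernel_spec("linear"))
  expect_equal(m$alphas, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(m$radius_sq, 1, tolerance = 1e-6)
  expect_equal(decision_distance(m, 1), 0, tolerance = 1e-8) # center at 1
  expect_equal(decision_distance(m, 3), 4, tolerance = 1e-8)
  expect_equal(predict_sphere(m, 3), "outside")
  expect_equal(predict_sphere(m, 1), "inside")
})

test_that("dual solver matches the brute-force simplex oracle on n <= 4", {
  set.seed(31)
  cases <- list(
    list(X = matrix(rnorm(6), 3, 2), C = 1, k = kernel_spec("rbf", 1)),
    list(X = matrix(rnorm(6), 3, 2), C = 0.5, k = kernel_spec("rbf", 0.7)),
    list(X = matrix(rnorm(3), 3, 1), C = 1, k = kernel_spec("linear")),
    list(X = matrix(rnorm(8), 4, 2), C = 1, k = kernel_spec("rbf", 1)),
    list(X = matrix(rnorm(8), 4, 2), C = 0.4, k = kernel_spec("rbf", 2))
  )
  for (cs in cases) {
    K <- if (cs$k$kind == "rbf") {
      outer(seq_len(nrow(cs$X)), seq_len(nrow(cs$X)), Vectorize(function(i, j)
        kernel_eval(cs$k, cs$X[i, ], cs$X[j, ])))
    } else {
      tcrossprod(cs$X)
    }
    sol <- svdd_solve_dual(K, cs$C)
    step <- if (nrow(cs$X) == 3) 1e-3 else 1e-2
    oracle <- brute_force_dual(K, cs$C, step = step)
    # the solver must do at least as well as the grid (up to tolerance)
    expect_gte(sol$objective, oracle$objective - 1e-4)
    if (nrow(cs$X) == 3) {
      expect_equal(sol$objective, oracle$objective, tolerance = 1e-4)
    }
  }
})

test_that("solver agrees with an off-the-shelf QP (kernlab ipop)", {
  set.seed(17)
  X <- matrix(rnorm(24), 12, 2)
  k <- kernel_spec("rbf", 1.5)
  K <- .rbf <- exp(-as.matrix(dist(X))^2 / k$sigma^2)
  C <- 0.3
  sol <- svdd_solve_dual(K, C)
  qp <- kernlab::ipop(
    c = matrix(-diag(K)), H = 2 * K + diag(1e-10, nrow(K)),
    A = matrix(1, 1, nrow(K)), b = 1, r = 0,
    l = matrix(0, nrow(K)), u = matrix(C, nrow(K))
  )
  a_qp <- kernlab::primal(qp)
  obj_qp <- sum(a_qp * diag(K)) - drop(crossprod(a_qp, K %*% a_qp))
  expect_equal(sol$objective, obj_qp, tolerance = 1e-5)
})

test_that("KKT conditions classify training points correctly", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  C <- 0.15
  m <- fit_svdd(X, C, kernel_spec("rbf", 1.2))
  expect_equal(sum(m$alphas), 1, tolerance = 1e-6)
  expect_true(all(m$alphas >= -1e-9 & m$alphas <= C + 1e-9))
  d2 <- decision_distance(m, X)
  tol <- 1e-4
  inner <- m$alphas < 1e-6
  boundary <- m$alphas > 1e-6 & m$alphas < C - 1e-6
  bound <- m$alphas > C - 1e-6
  expect_true(all(d2[inner] <= m$radius_sq + tol))
  if (any(boundary)) {
    expect_true(all(abs(d2[boundary] - m$radius_sq) <= tol))
  }
  expect_true(all(d2[bound] >= m$radius_sq - tol))
})

test_that("outlier count is non-increasing in C and rows can be permuted", {
  set.seed(23)
  X <- rbind(matrix(rnorm(60, 0, 0.5), 30, 2),
             matrix(rnorm(10, 4, 0.5), 5, 2))
  k <- kernel_spec("rbf", 1.5)
  outside <- vapply(c(0.05, 0.1, 0.2, 0.5, 1), function(C) {
    m <- fit_svdd(X, C, k)
    sum(predict_sphere(m, X) == "outside")
  }, numeric(1))
  expect_true(all(diff(outside) <= 0))
  # permutation invariance of the decision function
  m1 <- fit_svdd(X, 0.2, k)
  perm <- sample(nrow(X))
  m2 <- fit_svdd(X[perm, ], 0.2, k)
  probes <- matrix(rnorm(20), 10, 2)
  expect_equal(decision_distance(m1, probes), decision_distance(m2, probes),
               tolerance = 1e-8)
})

test_that("fit_svdd rejects infeasible C and mismatched dimensions", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(fit_svdd(X, C = 0.1), "infeasible")
  m <- fit_svdd(X, C = 1)
  expect_error(decision_distance(m, c(1, 2, 3)), "dimension")
})
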