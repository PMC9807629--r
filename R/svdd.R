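#' Kernel specification
#'
#' The RBF kernel is parameterized as `exp(-||x - y||^2 / sigma^2)` (note:
#' `sigma^2`, not `2 sigma^2`); the linear kernel is the plain dot product.
#'
#' @param kind `"rbf"` or `"linear"`.
#' @param sigma Positive RBF width (ignored for linear).
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("rbf", "linear"), sigma = 1) {
  kind <- match.arg(kind)
  if (kind == "rbf" && (!is.numeric(sigma) || sigma <= 0)) {
    stop("rbf kernel requires sigma > 0", call. = FALSE)
  }
  structure(list(kind = kind, sigma = sigma), class = "kernel_spec")
}

#' Evaluate a kernel between two vectors
#'
#' @param k A [kernel_spec()].
#' @param x,y Numeric vectors of equal length.
#' @return The scalar similarity.
#' @export
kernel_eval <- function(k, x, y) {
  stopifnot(inherits(k, "kernel_spec"))
  if (length(x) != length(y)) {
    stop("kernel_eval: dimension mismatch", call. = FALSE)
  }
  if (k$kind == "rbf") exp(-sum((x - y)^2) / k$sigma^2) else sum(x * y)
}

# Kernel Gram matrix between rows of X and rows of Y.
kernel_matrix <- function(k, X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop("kernel_matrix: dimension mismatch", call. = FALSE)
  }
  if (k$kind == "rbf") .rbf_kernel_cpp(X, Y, k$sigma) else tcrossprod(X, Y)
}

#' Solve the SVDD dual for a given Gram matrix
#'
#' Maximizes `sum_i a_i K_ii - sum_ij a_i a_j K_ij` subject to `sum a = 1`,
#' `0 <= a_i <= C`, via pairwise coordinate (SMO-style) updates on the
#' capped simplex; the stopping rule is the maximal Karush-Kuhn-Tucker
#' violation falling below `tol`.
#'
#' @param K Symmetric positive semi-definite Gram matrix.
#' @param C Box constraint; must satisfy `C >= 1/n`.
#' @param tol Convergence tolerance on the KKT violation.
#' @param max_iter Iteration cap (0 = automatic).
#' @param solver Either `"smo"` or a function `(K, C) -> alpha` implementing
#'   an alternative dual solver.
#' @return List with `alpha`, `objective`, `iterations`, `converged`.
#' @export
svdd_solve_dual <- function(K, C, tol = 1e-8, max_iter = 0, solver = "smo") {
  n <- nrow(K)
  if (C < 1 / n - 1e-12) {
    stop(sprintf("C = %g < 1/n = %g makes sum(alpha) = 1 infeasible",
                 C, 1 / n), call. = FALSE)
  }
  if (is.function(solver)) {
    alpha <- solver(K, C)
    return(list(alpha = alpha,
                objective = sum(alpha * diag(K)) -
                  drop(crossprod(alpha, K %*% alpha)),
                iterations = NA_integer_, converged = TRUE))
  }
  res <- .svdd_solve_dual_cpp(K, C, tol, as.integer(max_iter))
  if (!res$converged) {
    stop(sprintf("SVDD dual solver did not converge in %d iterations",
                 res$iterations), call. = FALSE)
  }
  res
}

#' Fit a single SVDD hypersphere
#'
#' Finds the minimal kernel-space hypersphere containing the training points,
#' with penalty `C` trading radius against slack for outliers: the larger
#' `C`, the fewer points are left outside. Support vectors are the points
#' with `alpha > 0`; boundary support vectors (`0 < alpha < C`) lie on the
#' sphere and define the squared radius (averaged for numerical stability; if
#' no strict-interior alpha exists, the maximum distance over support
#' vectors is used).
#'
#' @param X Sample matrix (rows = points).
#' @param C Penalty in `[1/n, Inf)`.
#' @param kernel A [kernel_spec()].
#' @param tol Dual solver tolerance.
#' @param sv_tol Threshold for classifying alphas as zero / at the box edge.
#' @param solver Passed to [svdd_solve_dual()].
#' @return An `svdd_model`: `support_vectors`, `alphas` (all training
#'   points; zeros retained), `C`, `kernel`, `radius_sq`, `center_norm_sq`,
#'   `objective`.
#' @export
fit_svdd <- function(X, C, kernel = kernel_spec("rbf", 1), tol = 1e-8,
                     sv_tol = 1e-6, solver = "smo") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1) stop("fit_svdd: need at least one sample", call. = FALSE)
  if (n == 1L) {
    alpha <- 1
    K <- kernel_matrix(kernel, X)
    sol <- list(alpha = alpha, objective = 0, iterations = 0L,
                converged = TRUE)
  } else {
    K <- kernel_matrix(kernel, X)
    sol <- svdd_solve_dual(K, C, tol = tol, solver = solver)
    alpha <- sol$alpha
  }
  center_norm_sq <- drop(crossprod(alpha, K %*% alpha))
  m <- structure(list(
    support_vectors = X, alphas = as.numeric(alpha), C = C, kernel = kernel,
    center_norm_sq = center_norm_sq, radius_sq = NA_real_,
    objective = sol$objective
  ), class = "svdd_model")
  d2 <- decision_distance(m, X)
  boundary <- alpha > sv_tol & alpha < C - sv_tol
  m$radius_sq <- if (any(boundary)) {
    mean(d2[boundary])
  } else {
    max(d2[alpha > sv_tol])
  }
  m$radius_sq <- max(m$radius_sq, 0)
  m
}

#' Squared kernel-space distance from the sphere center
#'
#' `phi(z,z) - 2 sum_i a_i phi(z, x_i) + ||center||^2` for each row of `Z`.
#'
#' @param m An `svdd_model`.
#' @param Z Vector (one point) or matrix (rows = points).
#' @return Numeric vector of squared distances (clamped at 0).
#' @export
decision_distance <- function(m, Z) {
  stopifnot(inherits(m, "svdd_model"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (ncol(Z) != ncol(m$support_vectors)) {
    stop("decision_distance: dimension mismatch", call. = FALSE)
  }
  kzz <- if (m$kernel$kind == "rbf") rep(1, nrow(Z)) else rowSums(Z^2)
  Kzx <- kernel_matrix(m$kernel, Z, m$support_vectors)
  d2 <- kzz - 2 * drop(Kzx %*% m$alphas) + m$center_norm_sq
  pmax(d2, 0)
}

#' Classify points against a fitted sphere
#'
#' A point is inside iff its squared center distance does not exceed the
#' squared radius. The tolerance `R^2 * (1 + rel_tol) + abs_tol` absorbs
#' floating-point noise; the absolute floor is an order of magnitude above
#' the dual solver's convergence tolerance so that boundary support vectors
#' (whose distances scatter by the solver tolerance around `R^2`) classify
#' as inside.
#'
#' @param m An `svdd_model`.
#' @param Z Vector or matrix of query points.
#' @param rel_tol Relative slack on the squared radius.
#' @param abs_tol Absolute slack on the squared radius.
#' @return Character vector `"inside"` / `"outside"`.
#' @export
predict_sphere <- function(m, Z, rel_tol = 1e-9, abs_tol = 1e-7) {
  d2 <- decision_distance(m, Z)
  ifelse(d2 <= m$radius_sq * (1 + rel_tol) + abs_tol, "inside", "outside")
}

#' @export
print.svdd_model <- function(x, ...) {
  cat(sprintf(
    "<svdd_model> n = %d, kernel = %s%s, C = %.4g, R^2 = %.4g, SVs = %d\n",
    nrow(x$support_vectors), x$kernel$kind,
    if (x$kernel$kind == "rbf") sprintf("(sigma = %.4g)", x$kernel$sigma)
    else "",
    x$C, x$radius_sq, sum(x$alphas > 1e-6)
  ))
  invisible(x)
}
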