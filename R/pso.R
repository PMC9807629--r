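#' Particle swarm optimizer configuration
#'
#' Canonical inertia-weight PSO with an adaptive-mutation refinement: when
#' the global best stagnates for `stagnation_window` consecutive iterations,
#' with probability `mutation_prob` the global best is re-perturbed by
#' Gaussian noise scaled to the search box, letting the swarm escape local
#' optima. Defaults use the constriction-equivalent coefficients
#' `w = 0.729`, `c1 = c2 = 1.49445`.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param n_iterations Velocity/position update sweeps.
#' @param w Inertia weight.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param mutation_prob Probability of perturbing the stagnated global best.
#' @param stagnation_window Iterations without improvement that trigger the
#'   mutation check.
#' @param mutation_scale Gaussian sd as a fraction of each box width.
#' @param bounds Two-column matrix (low, high) per dimension.
#' @param seed Integer seed.
#' @return A `pso_config` list.
#' @export
pso_config <- function(swarm_size = 20, n_iterations = 30,
                       w = 0.729, c1 = 1.49445, c2 = 1.49445,
                       mutation_prob = 0.2, stagnation_window = 5,
                       mutation_scale = 0.1,
                       bounds = cbind(low = c(-5, -5), high = c(5, 5)),
                       seed = 1L) {
  bounds <- as.matrix(bounds)
  stopifnot(
    swarm_size >= 2, n_iterations >= 1, ncol(bounds) == 2,
    all(bounds[, 1] < bounds[, 2]),
    mutation_prob >= 0, mutation_prob <= 1
  )
  structure(list(swarm_size = as.integer(swarm_size),
                 n_iterations = as.integer(n_iterations),
                 w = w, c1 = c1, c2 = c2,
                 mutation_prob = mutation_prob,
                 stagnation_window = as.integer(stagnation_window),
                 mutation_scale = mutation_scale,
                 bounds = bounds, seed = as.integer(seed)),
            class = "pso_config")
}

#' Maximize a fitness function by particle swarm optimization
#'
#' Positions and velocities follow the canonical updates
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`; positions are clamped
#' to the box. A particle whose fitness evaluation throws an error scores
#' `-Inf` and the run continues. The returned best score is re-evaluated at
#' the best position, and the history of the best score per iteration is
#' non-decreasing.
#'
#' @param fitness Function mapping a parameter vector (length = number of
#'   bound rows) to a scalar score; higher is better.
#' @param config A [pso_config()].
#' @return List with `best_params`, `best_score`, `history` (best score per
#'   iteration).
#' @export
pso_optimize <- function(fitness, config = pso_config()) {
  stopifnot(inherits(config, "pso_config"))
  lo <- config$bounds[, 1]; hi <- config$bounds[, 2]
  d <- length(lo)
  ns <- config$swarm_size
  span <- hi - lo

  safe_fit <- function(x) {
    v <- tryCatch(fitness(x), error = function(e) -Inf)
    if (!is.finite(v) && !identical(v, -Inf)) v <- -Inf
    v
  }

  with_seed(derive_seed(config$seed, "pso"), {
    X <- matrix(0, ns, d)
    for (j in seq_len(d)) X[, j] <- stats::runif(ns, lo[j], hi[j])
    V <- matrix(0, ns, d)
    for (j in seq_len(d)) V[, j] <- stats::runif(ns, -span[j], span[j]) * 0.1

    pbest <- X
    pbest_val <- apply(X, 1, safe_fit)
    g <- which.max(pbest_val)
    gbest <- pbest[g, ]
    gbest_val <- pbest_val[g]

    history <- numeric(config$n_iterations)
    stagnant <- 0L
    for (it in seq_len(config$n_iterations)) {
      r1 <- matrix(stats::runif(ns * d), ns, d)
      r2 <- matrix(stats::runif(ns * d), ns, d)
      V <- config$w * V +
        config$c1 * r1 * (pbest - X) +
        config$c2 * r2 * sweep(X, 2, gbest, function(x, g) g - x)
      X <- X + V
      for (j in seq_len(d)) X[, j] <- pmin(pmax(X[, j], lo[j]), hi[j])

      vals <- apply(X, 1, safe_fit)
      improved <- vals > pbest_val
      pbest[improved, ] <- X[improved, , drop = FALSE]
      pbest_val[improved] <- vals[improved]
      g <- which.max(pbest_val)
      if (pbest_val[g] > gbest_val) {
        gbest_val <- pbest_val[g]
        gbest <- pbest[g, ]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }

      # adaptive mutation: jolt the stagnated global best
      if (stagnant >= config$stagnation_window &&
          stats::runif(1) < config$mutation_prob) {
        cand <- gbest + stats::rnorm(d, 0, config$mutation_scale * span)
        cand <- pmin(pmax(cand, lo), hi)
        cval <- safe_fit(cand)
        if (cval > gbest_val) {
          gbest <- cand
          gbest_val <- cval
        }
        stagnant <- 0L
      }
      history[it] <- gbest_val
    }
  })

  list(best_params = gbest, best_score = safe_fit(gbest), history = history)
}
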