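# Fixtures and independent oracles shared across the suite.

# Two well-separated 2-D Gaussian blobs (the canonical clustering fixture).
two_blob_fixture <- function(n_per = 10, sd = 0.1, sep = 5, seed = 42) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(2 * n_per, 0, sd), n_per, 2),
    matrix(rnorm(2 * n_per, sep, sd), n_per, 2)
  )
  list(X = X, truth = rep(1:2, each = n_per))
}

# Brute-force maximization of the SVDD dual over the capped simplex
# {sum(alpha) = 1, 0 <= alpha <= C} by grid enumeration of the free
# coordinates (the last coordinate is 1 - sum of the others). Independent of
# the package's solver; only feasible for n <= 4.
brute_force_dual <- function(K, C, step = 1e-3) {
  n <- nrow(K)
  obj <- function(a) sum(a * diag(K)) - drop(crossprod(a, K %*% a))
  stopifnot(n >= 1, n <= 4)
  if (n == 1) return(list(objective = obj(1), alpha = 1))
  g <- seq(0, min(1, C), by = step)
  best <- -Inf
  best_a <- NULL
  if (n == 2) {
    a1 <- g
    a2 <- 1 - a1
    ok <- a2 >= 0 & a2 <= C
    vals <- vapply(which(ok), function(i) obj(c(a1[i], a2[i])), numeric(1))
    best <- max(vals)
    best_a <- c(a1[which(ok)[which.max(vals)]],
                a2[which(ok)[which.max(vals)]])
  } else if (n == 3) {
    for (a1 in g) {
      a2 <- g[g <= min(C, 1 - a1)]
      a3 <- 1 - a1 - a2
      ok <- a3 >= 0 & a3 <= C
      if (!any(ok)) next
      vals <- vapply(which(ok), function(i) obj(c(a1, a2[i], a3[i])),
                     numeric(1))
      m <- max(vals)
      if (m > best) {
        best <- m
        i <- which(ok)[which.max(vals)]
        best_a <- c(a1, a2[i], a3[i])
      }
    }
  } else {
    for (a1 in g) for (a2 in g[g <= 1 - a1]) {
      a3 <- g[g <= min(C, 1 - a1 - a2)]
      a4 <- 1 - a1 - a2 - a3
      ok <- a4 >= 0 & a4 <= C
      if (!any(ok)) next
      vals <- vapply(which(ok), function(i) obj(c(a1, a2, a3[i], a4[i])),
                     numeric(1))
      m <- max(vals)
      if (m > best) {
        best <- m
        i <- which(ok)[which.max(vals)]
        best_a <- c(a1, a2, a3[i], a4[i])
      }
    }
  }
  list(objective = best, alpha = best_a)
}

# Small labeled binary dataset for IO round-trips.
tiny_dataset <- function(seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(3 * 5, 1, 0.4), 3, 5)
  binary_dataset(X, c("target", "target", "abnormal"))
}

# A domain-scale binary fixture: one or more Bernoulli clusters, reused by
# svdd/pipeline tests.
binary_cluster_fixture <- function(n = 120, n_clusters = 1, seed = 3) {
  generate_questionnaire(generator_config(
    n_target = n, n_abnormal = 0, n_clusters = n_clusters, seed = seed
  ))
}
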