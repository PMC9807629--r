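#' Build the AP similarity matrix from a sample matrix
#'
#' Similarity is the classical affinity-propagation choice, negative squared
#' Euclidean distance, with the preference value on the diagonal. The
#' preference controls how many exemplars (clusters) emerge: low preference,
#' few clusters.
#'
#' @param X Sample matrix.
#' @param preference Scalar placed on the diagonal; default is the median
#'   off-diagonal similarity.
#' @return A `similarity_matrix` (plain matrix with class attribute).
#' @export
similarity_matrix <- function(X, preference = NULL) {
  X <- as.matrix(X)
  S <- -.sqdist_cpp(X, X)
  off <- S[upper.tri(S)]
  preference <- preference %||% stats::median(off)
  diag(S) <- preference
  structure(S, class = c("similarity_matrix", "matrix"),
            preference = preference)
}

#' Affinity propagation clustering
#'
#' Exemplar-based clustering by damped responsibility/availability message
#' passing. Points are assigned to the exemplar with maximal similarity;
#' exemplars label themselves. The run is flagged unconverged when the
#' exemplar set keeps changing up to `max_iter` (callers may fall back to a
#' single cluster).
#'
#' @param S A [similarity_matrix()] (or plain matrix with the preference
#'   already on its diagonal).
#' @param damping Message damping factor in `[0.5, 1)`.
#' @param max_iter Maximum message-passing iterations.
#' @param conv_iter Consecutive iterations with an unchanged exemplar set
#'   required to declare convergence.
#' @return A `cluster_result`: `K`, `labels` (1-based cluster index),
#'   `exemplars` (sample indices), `preference`, `iterations`, `converged`,
#'   `mean_silhouette` (`NA` until scored).
#' @export
affinity_propagation <- function(S, damping = 0.9, max_iter = 1000,
                                 conv_iter = 100) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), nrow(S) >= 1)
  if (damping < 0.5 || damping >= 1) {
    stop("damping must lie in [0.5, 1)", call. = FALSE)
  }
  n <- nrow(S)
  if (n == 1L) {
    return(structure(list(
      K = 1L, labels = 1L, exemplars = 1L,
      preference = S[1, 1], iterations = 0L, converged = TRUE,
      mean_silhouette = NA_real_
    ), class = "cluster_result"))
  }
  res <- .ap_cluster_cpp(unclass(S), damping, as.integer(max_iter),
                         as.integer(conv_iter))
  structure(list(
    K = length(res$exemplars),
    labels = res$labels + 1L,
    exemplars = res$exemplars + 1L,
    preference = attr(S, "preference") %||% S[1, 1],
    iterations = res$iterations,
    converged = res$converged,
    mean_silhouette = NA_real_
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> K = %d, n = %d, preference = %.4g, %s, mean silhouette = %s\n",
    x$K, length(x$labels), x$preference,
    if (x$converged) sprintf("converged in %d iters", x$iterations)
    else "NOT converged",
    if (is.na(x$mean_silhouette)) "NA" else sprintf("%.4f", x$mean_silhouette)
  ))
  invisible(x)
}

#' Silhouette scores of a partition
#'
#' For each sample, `a(i)` is its mean Euclidean distance to the other
#' members of its own cluster and `b(i)` the minimum over other clusters of
#' the mean distance to that cluster; `s(i) = (b - a) / max(a, b)`, with the
#' convention `s(i) = 0` for singleton clusters. The mean silhouette scores
#' the whole partition (used to pick the AP preference).
#'
#' @param X Sample matrix, or `NULL` when `dist_sq` is supplied.
#' @param labels Integer cluster labels (>= 2 distinct values, each
#'   nonempty).
#' @param dist_sq Optional precomputed squared-distance matrix (reused
#'   across preference candidates).
#' @return List with `s` (per-sample scores in `[-1, 1]`) and `mean`.
#' @export
silhouette_score <- function(X, labels, dist_sq = NULL) {
  labels <- as.integer(factor(labels))
  K <- max(labels)
  if (K < 2L) stop("silhouette undefined for a single cluster", call. = FALSE)
  D <- if (is.null(dist_sq)) sqrt(.sqdist_cpp(as.matrix(X), as.matrix(X)))
       else sqrt(dist_sq)
  n <- length(labels)
  sizes <- tabulate(labels, K)
  # per-sample mean distance to each cluster via one matrix product
  M <- matrix(0, n, K)
  for (k in seq_len(K)) M[, k] <- rowSums(D[, labels == k, drop = FALSE])
  own <- sizes[labels]
  a <- ifelse(own > 1, M[cbind(seq_len(n), labels)] / (own - 1), 0)
  Mmean <- sweep(M, 2, sizes, "/")
  Mmean[cbind(seq_len(n), labels)] <- Inf
  b <- apply(Mmean, 1, min)
  s <- ifelse(own == 1, 0, (b - a) / pmax(a, b))
  s[is.nan(s)] <- 0 # coincident points: a = b = 0
  list(s = s, mean = mean(s))
}

#' Choose the AP preference by Latin hypercube search over silhouette
#'
#' Draws `n_candidates` preference values by Latin hypercube sampling,
#' stratified over `[min, median]` of the off-diagonal similarities (the
#' few-clusters to moderate-clusters regime), runs affinity propagation for
#' each, and returns the partition with the best mean silhouette. Candidates
#' that collapse to one cluster (silhouette undefined) or fail to converge
#' are excluded; if every candidate is excluded the K = 1 fallback is
#' returned, flagged, so the pipeline degenerates gracefully to a single
#' sphere.
#'
#' @param X Sample matrix.
#' @param n_candidates Number of LHS preference draws.
#' @param seed Integer seed for the LHS draw (and the subsample, if any).
#' @param damping,max_iter,conv_iter Passed to [affinity_propagation()].
#' @param max_n Message passing is quadratic in n, so for inputs larger than
#'   this the preference search runs on a seeded random subsample of
#'   `max_n` points and the remaining points are then assigned to the
#'   nearest exemplar (the silhouette is scored on the subsample).
#' @return The best `cluster_result`, with `mean_silhouette` filled in,
#'   plus `candidates` (data frame: preference, K, converged,
#'   mean_silhouette) attached.
#' @export
select_preference <- function(X, n_candidates = 10, seed = 1L,
                              damping = 0.9, max_iter = 1000,
                              conv_iter = 100, max_n = 1000) {
  stopifnot(n_candidates >= 1)
  X <- as.matrix(X)
  n_full <- nrow(X)
  sub <- NULL
  if (n_full > max_n) {
    sub <- with_seed(derive_seed(seed, "ap-subsample"),
                     sort(sample.int(n_full, max_n)))
    X_full <- X
    X <- X[sub, , drop = FALSE]
  }
  Dsq <- .sqdist_cpp(X, X)
  off <- -Dsq[upper.tri(Dsq)]
  lo <- min(off); hi <- stats::median(off)
  u <- with_seed(derive_seed(seed, "lhs-preference"),
                 as.numeric(lhs::randomLHS(n_candidates, 1)))
  prefs <- lo + u * (hi - lo)

  best <- NULL
  best_sil <- -Inf
  rows <- vector("list", n_candidates)
  for (i in seq_along(prefs)) {
    S <- -Dsq
    diag(S) <- prefs[i]
    attr(S, "preference") <- prefs[i]
    cr <- affinity_propagation(S, damping, max_iter, conv_iter)
    sil <- if (cr$K >= 2 && cr$converged) {
      silhouette_score(NULL, cr$labels, dist_sq = Dsq)$mean
    } else {
      -Inf # K = 1 (silhouette undefined) or unconverged: excluded
    }
    cr$mean_silhouette <- if (is.finite(sil)) sil else NA_real_
    rows[[i]] <- data.frame(preference = prefs[i], K = cr$K,
                            converged = cr$converged,
                            mean_silhouette = sil)
    if (sil > best_sil) {
      best_sil <- sil
      best <- cr
    }
  }
  if (is.null(best)) {
    # every candidate collapsed or failed: one cluster, flagged
    best <- structure(list(
      K = 1L, labels = rep(1L, n_full), exemplars = 1L,
      preference = NA_real_, iterations = 0L, converged = FALSE,
      mean_silhouette = NA_real_
    ), class = "cluster_result")
    attr(best, "candidates") <- do.call(rbind, rows)
    return(best)
  }
  if (!is.null(sub)) {
    # extend the subsample partition: exemplar indices back to the full
    # row space, every remaining point to its nearest exemplar
    ex_full <- sub[best$exemplars]
    Dex <- .sqdist_cpp(X_full, X_full[ex_full, , drop = FALSE])
    labels_full <- max.col(-Dex, ties.method = "first")
    labels_full[sub] <- best$labels
    labels_full[ex_full] <- seq_along(ex_full)
    best$labels <- labels_full
    best$exemplars <- ex_full
  }
  attr(best, "candidates") <- do.call(rbind, rows)
  best
}
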