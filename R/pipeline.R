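#' Confusion counts for one-class prediction
#'
#' Target samples predicted target/abnormal count as TP/FN; abnormal samples
#' predicted abnormal/target count as TN/FP.
#'
#' @param truth Character vector of `"target"` / `"abnormal"`.
#' @param predicted Character vector of the same length and alphabet.
#' @return A `confusion_counts` list with `TP`, `FN`, `FP`, `TN`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c("target", "abnormal")),
            all(predicted %in% c("target", "abnormal")))
  structure(list(
    TP = sum(truth == "target" & predicted == "target"),
    FN = sum(truth == "target" & predicted == "abnormal"),
    FP = sum(truth == "abnormal" & predicted == "target"),
    TN = sum(truth == "abnormal" & predicted == "abnormal")
  ), class = "confusion_counts")
}

#' Precision, recall and F-score
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2RP/(R+P)`. An undefined
#' denominator yields `NA` (an explicit undefined marker, never a silent 0),
#' except that `F = 0` when `P = R = 0`.
#'
#' @param counts A [confusion_counts()] (or list with TP/FN/FP/TN).
#' @return A `metric_set` list with `precision`, `recall`, `f_score`.
#' @export
metrics <- function(counts) {
  TP <- counts$TP; FN <- counts$FN; FP <- counts$FP
  P <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  R <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  F <- if (is.na(P) || is.na(R)) {
    NA_real_
  } else if (P == 0 && R == 0) {
    0
  } else {
    2 * R * P / (R + P)
  }
  structure(list(precision = P, recall = R, f_score = F),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> P = %.4f, R = %.4f, F = %.4f\n",
              x$precision, x$recall, x$f_score))
  invisible(x)
}

# Fit a sphere directly from a Gram matrix; diagK passed for the rbf
# shortcut diag = 1. Returns alpha, center_norm_sq, radius_sq, and the
# training squared distances.
.fit_from_gram <- function(K, C, sv_tol = 1e-6) {
  n <- nrow(K)
  if (n == 1L) {
    alpha <- 1
  } else {
    alpha <- .svdd_solve_dual_cpp(K, C, 1e-8, 0L)$alpha
  }
  cns <- drop(crossprod(alpha, K %*% alpha))
  d2 <- pmax(diag(K) - 2 * drop(K %*% alpha) + cns, 0)
  boundary <- alpha > sv_tol & alpha < C - sv_tol
  r2 <- if (any(boundary)) mean(d2[boundary]) else max(d2[alpha > sv_tol])
  list(alpha = alpha, center_norm_sq = cns, radius_sq = max(r2, 0),
       train_dist_sq = d2)
}

#' Configuration of the synthetic-outlier device used by the fitness
#'
#' The classifier trains on target samples only, yet the tuning fitness is
#' an F-score, which needs negatives. Artificial outliers are drawn
#' uniformly from the cluster's per-dimension bounding box expanded by
#' `margin` on each side; `per_fold = NULL` draws as many outliers as the
#' fold holds held-out targets. A real negative validation set can be
#' supplied instead via `negatives`.
#'
#' @param per_fold Outliers per fold (`NULL` = held-out target count).
#' @param margin Box expansion as a fraction of each dimension's range.
#' @param negatives Optional matrix of real negative samples used instead of
#'   synthetic outliers.
#' @return An `outlier_config` list.
#' @export
outlier_config <- function(per_fold = NULL, margin = 0.1, negatives = NULL) {
  structure(list(per_fold = per_fold, margin = margin,
                 negatives = negatives),
            class = "outlier_config")
}

# Build a cached cross-validated fitness closure over (C, sigma) for one
# cluster. Folds, synthetic outliers and (for rbf) the squared-distance
# blocks are computed once; each evaluation only exponentiates and solves
# the dual, which is what makes swarm search affordable.
make_cv_fitness <- function(X_cluster, n_folds = 5,
                            outliers = outlier_config(),
                            seed = 1L, kernel_kind = "rbf") {
  X <- as.matrix(X_cluster)
  n <- nrow(X)
  single_fold <- n < n_folds
  eff_folds <- if (single_fold) 1L else as.integer(n_folds)

  with_seed(derive_seed(seed, "cv-folds"), {
    fold_id <- if (single_fold) rep(1L, n)
               else sample(rep_len(seq_len(eff_folds), n))
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    pad <- (hi - lo) * outliers$margin
    blo <- lo - pad; bhi <- hi + pad
    folds <- lapply(seq_len(eff_folds), function(f) {
      val <- if (single_fold) seq_len(n) else which(fold_id == f)
      tr <- if (single_fold) seq_len(n) else which(fold_id != f)
      n_out <- outliers$per_fold %||% length(val)
      neg <- if (!is.null(outliers$negatives)) {
        as.matrix(outliers$negatives)
      } else {
        matrix(stats::runif(n_out * ncol(X), blo, bhi),
               n_out, ncol(X), byrow = TRUE)
      }
      list(tr = tr, val = val, neg = neg)
    })
  })

  cache <- lapply(folds, function(f) {
    if (kernel_kind != "rbf") return(NULL)
    Xtr <- X[f$tr, , drop = FALSE]
    Q <- rbind(X[f$val, , drop = FALSE], f$neg)
    list(D_tr = .sqdist_cpp(Xtr, Xtr), D_q = .sqdist_cpp(Q, Xtr))
  })

  # `nu` mode expresses the penalty relative to the training size of each
  # fold, C = 1/(nu * m): the same nu then transfers from CV folds to the
  # full-cluster refit, which an absolute C does not (its effect depends on
  # n through the sum(alpha) = 1 constraint).
  fit_fn <- function(C, sigma, nu = NULL) {
    fs <- vapply(seq_along(folds), function(fi) {
      f <- folds[[fi]]
      m <- length(f$tr)
      if (!is.null(nu)) C <- 1 / (nu * m)
      Ceff <- max(C, 1 / m)
      if (kernel_kind == "rbf") {
        K <- exp(-cache[[fi]]$D_tr / sigma^2)
        fit <- .fit_from_gram(K, Ceff)
        dq <- pmax(1 - 2 * drop(exp(-cache[[fi]]$D_q / sigma^2) %*%
                                  fit$alpha) + fit$center_norm_sq, 0)
      } else {
        Xtr <- X[f$tr, , drop = FALSE]
        Q <- rbind(X[f$val, , drop = FALSE], f$neg)
        K <- tcrossprod(Xtr)
        fit <- .fit_from_gram(K, Ceff)
        dq <- pmax(rowSums(Q^2) - 2 * drop(tcrossprod(Q, Xtr) %*%
                                             fit$alpha) +
                     fit$center_norm_sq, 0)
      }
      inside <- dq <= fit$radius_sq * (1 + 1e-9) + 1e-7
      nv <- length(f$val)
      truth <- c(rep("target", nv), rep("abnormal", nrow(f$neg)))
      pred <- ifelse(inside, "target", "abnormal")
      f1 <- metrics(confusion_counts(truth, pred))$f_score
      if (is.na(f1)) 0 else f1
    }, numeric(1))
    mean(fs)
  }
  attr(fit_fn, "single_fold") <- single_fold
  fit_fn
}

#' Cross-validated F-score fitness for SVDD parameters
#'
#' Splits the (target-only) cluster into `n_folds` folds; per fold a sphere
#' is fitted on the training part and validated on the held-out targets
#' (positives) plus synthetic box-uniform outliers (negatives); the F-scores
#' are averaged. Clusters smaller than `n_folds` fall back to a single
#' fold (fit and validate on all points), flagged via the
#' `"single_fold"` attribute.
#'
#' @param params Numeric `c(C, sigma)` on the natural scale.
#' @param X_cluster Matrix of the cluster's samples.
#' @param n_folds Number of folds (default 5).
#' @param outliers An [outlier_config()].
#' @param seed Integer seed fixing folds and outlier draws.
#' @param kernel_kind `"rbf"` or `"linear"`.
#' @return Mean F-score across folds, with attribute `single_fold`.
#' @export
cv_fitness <- function(params, X_cluster, n_folds = 5,
                       outliers = outlier_config(), seed = 1L,
                       kernel_kind = "rbf") {
  fn <- make_cv_fitness(X_cluster, n_folds, outliers, seed, kernel_kind)
  out <- fn(params[1], params[2])
  attr(out, "single_fold") <- attr(fn, "single_fold")
  out
}

#' Configuration for the self-adaptive multi-sphere classifier
#'
#' Bundles the per-stage settings of the divide-and-conquer fit: affinity
#' propagation (preference search), swarm optimization of each sub-sphere's
#' `(C, sigma)`, the cross-validated fitness, and cluster hygiene.
#'
#' @param ap List: `n_candidates`, `damping`, `max_iter`, `conv_iter` for
#'   [select_preference()].
#' @param pso List of [pso_config()] fields (bounds and seed are set
#'   internally).
#' @param n_folds Folds of the tuning fitness.
#' @param outliers An [outlier_config()].
#' @param min_cluster_size Clusters smaller than this are merged into the
#'   nearest exemplar's cluster before tuning.
#' @param fitness_max_n Tuning-fitness subsample cap: clusters larger than
#'   this are tuned on a seeded random subsample of this size (the final
#'   sphere is always fitted on the full cluster).
#' @param log10_nu_range,log10_sigma_range Log10-scale search box for the
#'   swarm. The penalty is tuned as `nu = 1/(C n)`, the fraction-of-outliers
#'   parameterization: `nu = 1` forces `C = 1/n` (every point may carry
#'   slack, a centroid-like sphere), small `nu` approaches the hard-margin
#'   sphere (`C >= 1` behaves identically to `C = 1` since `sum(alpha) = 1`).
#'   Tuning `nu` rather than `C` lets the tuned value transfer from CV folds
#'   to the full-cluster refit. An `NA` lower bound is replaced by
#'   `log10(1/(2 m))` for the smallest fold, which covers the whole
#'   effective `C` range.
#' @param seed Master seed for the fit.
#' @return An `sa_svdd_config` list.
#' @export
sa_svdd_config <- function(ap = list(), pso = list(), n_folds = 5,
                           outliers = outlier_config(),
                           min_cluster_size = 3, fitness_max_n = 400,
                           log10_nu_range = c(NA, 0),
                           log10_sigma_range = c(-2, 2),
                           seed = 1L) {
  ap_def <- list(n_candidates = 10, damping = 0.9, max_iter = 1000,
                 conv_iter = 100, max_n = 1000)
  ap_def[names(ap)] <- ap
  pso_def <- list(swarm_size = 20, n_iterations = 30, w = 0.729,
                  c1 = 1.49445, c2 = 1.49445, mutation_prob = 0.2,
                  stagnation_window = 5, mutation_scale = 0.1)
  pso_def[names(pso)] <- pso
  structure(list(ap = ap_def, pso = pso_def, n_folds = n_folds,
                 outliers = outliers, min_cluster_size = min_cluster_size,
                 fitness_max_n = fitness_max_n,
                 log10_nu_range = log10_nu_range,
                 log10_sigma_range = log10_sigma_range,
                 seed = as.integer(seed)),
            class = "sa_svdd_config")
}

# Merge clusters below min_size into the nearest other exemplar's cluster.
merge_small_clusters <- function(X, labels, exemplars, min_size) {
  repeat {
    sizes <- tabulate(labels, length(exemplars))
    K <- length(exemplars)
    if (K <= 1 || all(sizes >= min_size)) break
    k <- which.min(sizes)
    members <- which(labels == k)
    others <- setdiff(seq_len(K), k)
    Dex <- .sqdist_cpp(X[members, , drop = FALSE],
                       X[exemplars[others], , drop = FALSE])
    nearest <- others[max.col(-Dex, ties.method = "first")]
    labels[members] <- nearest
    exemplars <- exemplars[-k]
    labels <- ifelse(labels > k, labels - 1L, labels)
  }
  list(labels = labels, exemplars = exemplars)
}

#' Fit the self-adaptive multi-sphere one-class classifier
#'
#' The divide-and-conquer fit on target-class samples: (1) affinity
#' propagation with silhouette-selected preference partitions the training
#' set into K sub-clusters (clusters below `min_cluster_size` are merged
#' into the nearest exemplar's cluster); (2) per cluster, particle swarm
#' search over log10 `(C, sigma)` maximizes the cross-validated F-score
#' against synthetic outliers; (3) a kernel SVDD sphere is fitted on the
#' full cluster with the tuned parameters. Prediction is the union rule: a
#' sample is target iff it falls inside at least one sub-hypersphere.
#'
#' @param X Matrix of target-class samples (rows).
#' @param config An [sa_svdd_config()].
#' @return An `sa_svdd` model: `clusters`, `spheres` (one `svdd_model` per
#'   cluster), `params` (tuned C/sigma per cluster), `fitness` (tuned CV
#'   F-score per cluster), `config`.
#' @export
fit_sa_svdd <- function(X, config = sa_svdd_config()) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("fit_sa_svdd: empty input", call. = FALSE)
  seed <- config$seed

  cl <- select_preference(
    X, n_candidates = config$ap$n_candidates,
    seed = derive_seed(seed, "ap"),
    damping = config$ap$damping, max_iter = config$ap$max_iter,
    conv_iter = config$ap$conv_iter, max_n = config$ap$max_n
  )
  mg <- merge_small_clusters(X, cl$labels, cl$exemplars,
                             config$min_cluster_size)
  cl$labels <- mg$labels
  cl$exemplars <- mg$exemplars
  cl$K <- length(mg$exemplars)

  spheres <- vector("list", cl$K)
  params <- vector("list", cl$K)
  fitvals <- numeric(cl$K)
  for (k in seq_len(cl$K)) {
    Xk <- X[cl$labels == k, , drop = FALSE]
    tuned <- tune_sphere(Xk, config, label = as.character(k))
    spheres[[k]] <- tuned$sphere
    params[[k]] <- tuned$params
    fitvals[k] <- tuned$fitness
  }

  structure(list(clusters = cl, spheres = spheres, params = params,
                 fitness = fitvals, config = config),
            class = "sa_svdd")
}

# Swarm-tune (nu, sigma) on a (possibly subsampled) cluster and fit the
# final sphere on the full cluster with the tuned parameters.
tune_sphere <- function(Xk, config, label) {
  seed <- config$seed
  tune_idx <- if (nrow(Xk) > config$fitness_max_n) {
    with_seed(derive_seed(seed, paste0("tune-subsample-", label)),
              sample.int(nrow(Xk), config$fitness_max_n))
  } else {
    seq_len(nrow(Xk))
  }
  Xt <- Xk[tune_idx, , drop = FALSE]
  fit_fn <- make_cv_fitness(Xt, config$n_folds, config$outliers,
                            seed = derive_seed(seed, paste0("cv-", label)),
                            kernel_kind = "rbf")
  m_min <- max(2, floor(nrow(Xt) * (1 - 1 / config$n_folds)))
  nu_range <- config$log10_nu_range
  if (is.na(nu_range[1])) nu_range[1] <- log10(1 / (2 * m_min))
  bounds <- rbind(nu = nu_range, sigma = config$log10_sigma_range)
  pcfg <- do.call(pso_config, c(config$pso, list(
    bounds = bounds, seed = derive_seed(seed, paste0("pso-", label))
  )))
  res <- pso_optimize(function(p) fit_fn(NA, 10^p[2], nu = 10^p[1]), pcfg)
  nu_k <- 10^res$best_params[1]
  sigma_k <- 10^res$best_params[2]
  C_k <- max(1 / (nu_k * nrow(Xk)), 1 / nrow(Xk))
  list(sphere = fit_svdd(Xk, C_k, kernel_spec("rbf", sigma_k)),
       params = c(C = C_k, sigma = sigma_k, nu = min(nu_k, 1)),
       fitness = res$best_score)
}

#' Fit a swarm-tuned single-sphere SVDD classifier
#'
#' The plain one-hypersphere baseline: no clustering, no autoencoder — one
#' kernel sphere over all target samples, with `(C, sigma)` tuned by the
#' same swarm-optimized cross-validated F-score as the multi-sphere fit.
#' Useful as the reference the divide-and-conquer variants are compared
#' against.
#'
#' @param X Matrix of target-class samples.
#' @param config An [sa_svdd_config()] (AP settings are ignored).
#' @return An `sa_svdd` model with a single sphere.
#' @export
fit_tuned_svdd <- function(X, config = sa_svdd_config()) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("fit_tuned_svdd: empty input", call. = FALSE)
  tuned <- tune_sphere(X, config, label = "single")
  cl <- structure(list(
    K = 1L, labels = rep(1L, nrow(X)), exemplars = 1L,
    preference = NA_real_, iterations = 0L, converged = TRUE,
    mean_silhouette = NA_real_
  ), class = "cluster_result")
  structure(list(clusters = cl, spheres = list(tuned$sphere),
                 params = list(tuned$params), fitness = tuned$fitness,
                 config = config),
            class = "sa_svdd")
}

#' @export
print.sa_svdd <- function(x, ...) {
  cat(sprintf("<sa_svdd> K = %d spheres in %d dims, tuned CV F = %s\n",
              x$clusters$K, ncol(x$spheres[[1]]$support_vectors),
              paste(sprintf("%.3f", x$fitness), collapse = ", ")))
  invisible(x)
}

#' Predict with a multi-sphere model (union rule)
#'
#' @param object An `sa_svdd` model.
#' @param newdata Matrix of query points (or a [binary_dataset()]).
#' @param ... Unused.
#' @return Character vector `"target"` / `"abnormal"`; target iff the point
#'   is inside at least one sub-hypersphere.
#' @export
predict.sa_svdd <- function(object, newdata, ...) {
  Z <- if (inherits(newdata, "binary_dataset")) newdata$matrix
       else as.matrix(newdata)
  inside <- rep(FALSE, nrow(Z))
  for (m in object$spheres) {
    inside <- inside | (predict_sphere(m, Z) == "inside")
  }
  ifelse(inside, "target", "abnormal")
}

#' Stacked-autoencoder front end configuration
#'
#' @param hidden_sizes Hidden dimension of each autoencoder, front to back
#'   (the input size is taken from the data); e.g. `c(110, 90, 30)`.
#' @param activation,epochs,learning_rate,batch_size Training settings, see
#'   [train_layerwise()]. The default step size of 0.3 is calibrated for
#'   sigmoid units on sparse 0/1 inputs, where plain SGD with a timid step
#'   leaves the first autoencoder stuck near its initialization and the
#'   codes uninformative.
#' @return An `sae_config` list.
#' @export
sae_config <- function(hidden_sizes = c(110, 90, 30),
                       activation = "sigmoid", epochs = 60,
                       learning_rate = 0.3, batch_size = 32) {
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1))
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 activation = activation, epochs = epochs,
                 learning_rate = learning_rate, batch_size = batch_size),
            class = "sae_config")
}

#' Fit the stacked-autoencoder multi-sphere classifier
#'
#' Trains the stacked autoencoder on the target-class samples, embeds them
#' with the encoder half, and fits the multi-sphere classifier on the
#' low-dimensional codes. Prediction encodes internally, so queries are in
#' the raw feature space.
#'
#' @param X Matrix of target-class samples (raw feature space) or a
#'   [binary_dataset()] whose target rows are used.
#' @param sae An [sae_config()].
#' @param sa An [sa_svdd_config()]; its seed drives the whole fit.
#' @return An `sae_svdd` model: `encoder` (trained `encoder_stack`) and
#'   `core` (`sa_svdd` fitted on codes).
#' @export
fit_sae_svdd <- function(X, sae = sae_config(), sa = sa_svdd_config()) {
  if (inherits(X, "binary_dataset")) {
    X <- X$matrix[X$labels == "target", , drop = FALSE]
  }
  X <- as.matrix(X)
  stack <- build_sae(c(ncol(X), sae$hidden_sizes),
                     activation = sae$activation,
                     seed = derive_seed(sa$seed, "sae"))
  stack <- train_layerwise(stack, X, epochs = sae$epochs,
                           learning_rate = sae$learning_rate,
                           batch_size = sae$batch_size)
  codes <- sae_encode(stack, X)
  core <- fit_sa_svdd(codes, sa)
  structure(list(encoder = stack, core = core), class = "sae_svdd")
}

#' @export
print.sae_svdd <- function(x, ...) {
  cat(sprintf("<sae_svdd> encoder %s; ",
              paste(x$encoder$layer_sizes, collapse = " -> ")))
  print(x$core)
  invisible(x)
}

#' @rdname predict.sa_svdd
#' @export
predict.sae_svdd <- function(object, newdata, ...) {
  Z <- if (inherits(newdata, "binary_dataset")) newdata$matrix
       else as.matrix(newdata)
  predict(object$core, sae_encode(object$encoder, Z))
}

#' Evaluate a fitted model on a labeled dataset
#'
#' @param model An `sa_svdd` or `sae_svdd` model.
#' @param data A labeled [binary_dataset()].
#' @return List with `confusion` ([confusion_counts()]) and `metrics`
#'   ([metrics()]).
#' @export
evaluate_model <- function(model, data) {
  stopifnot(inherits(data, "binary_dataset"))
  pred <- predict(model, data$matrix)
  cc <- confusion_counts(data$labels, pred)
  list(confusion = cc, metrics = metrics(cc))
}
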