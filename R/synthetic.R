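#' Configuration for the synthetic questionnaire generator
#'
#' Describes an imbalanced sparse binary survey: the target (healthy)
#' class is a mixture of Bernoulli-profile clusters — each cluster elevates a
#' disjoint "signature" subset of options above the background selection rate,
#' the way a subpopulation consistently picks particular answers — while the
#' abnormal class follows the background profile with a designated set of
#' risk options elevated to a higher selection rate.
#'
#' Defaults emulate the scale of a real antenatal-depression survey: 147
#' binary option columns and a roughly 93%/7% target/abnormal imbalance, with
#' risk-option rates 0.35 (abnormal) vs 0.12 (target) mirroring the observed
#' top risk factor (138/407 vs 646/5259 selection fractions).
#'
#' @param n_target,n_abnormal Class sizes.
#' @param n_features Number of binary option columns.
#' @param n_clusters Number of target sub-clusters (>= 1).
#' @param base_rate Background Bernoulli selection probability, in (0, 1).
#' @param cluster_profiles Optional `n_clusters x n_features` probability
#'   matrix; if `NULL`, profiles are auto-generated by perturbing
#'   `base_rate` upward by `signature_amplitude` on `n_signature` disjoint
#'   randomly chosen features per cluster.
#' @param n_signature Signature features per auto-generated cluster profile.
#' @param signature_amplitude Amount added to `base_rate` on signature
#'   features (clipped below 1).
#' @param risk_options Feature indices acting as risk options; `NULL` draws
#'   `n_risk` of them at random outside every signature set.
#' @param n_risk Number of risk options when `risk_options` is `NULL`.
#' @param risk_rate_abnormal,risk_rate_target Selection probability of risk
#'   options in each class; enrichment requires
#'   `risk_rate_abnormal > risk_rate_target`.
#' @param mixing Cluster mixing weights (default uniform).
#' @param seed Integer seed; all randomness flows from it through
#'   [derive_seed()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_target = 5259, n_abnormal = 407,
                             n_features = 147, n_clusters = 3,
                             base_rate = 0.10,
                             cluster_profiles = NULL,
                             n_signature = 25, signature_amplitude = 0.65,
                             risk_options = NULL, n_risk = 8,
                             risk_rate_abnormal = 0.35,
                             risk_rate_target = 0.12,
                             mixing = NULL, seed = 1L) {
  stopifnot(
    n_target >= 1, n_abnormal >= 0, n_features >= 1, n_clusters >= 1,
    base_rate > 0, base_rate < 1,
    risk_rate_abnormal > 0, risk_rate_abnormal < 1,
    risk_rate_target > 0, risk_rate_target < 1
  )
  if (risk_rate_abnormal <= risk_rate_target) {
    stop("risk_rate_abnormal must exceed risk_rate_target (enrichment)",
         call. = FALSE)
  }
  if (n_clusters > n_target) {
    stop("n_clusters cannot exceed n_target", call. = FALSE)
  }
  if (!is.null(cluster_profiles)) {
    cluster_profiles <- as.matrix(cluster_profiles)
    stopifnot(nrow(cluster_profiles) == n_clusters,
              ncol(cluster_profiles) == n_features,
              all(cluster_profiles > 0 & cluster_profiles < 1))
  }
  mixing <- mixing %||% rep(1 / n_clusters, n_clusters)
  stopifnot(length(mixing) == n_clusters, all(mixing > 0))
  structure(list(
    n_target = as.integer(n_target), n_abnormal = as.integer(n_abnormal),
    n_features = as.integer(n_features), n_clusters = as.integer(n_clusters),
    base_rate = base_rate, cluster_profiles = cluster_profiles,
    n_signature = as.integer(n_signature),
    signature_amplitude = signature_amplitude,
    risk_options = risk_options, n_risk = as.integer(n_risk),
    risk_rate_abnormal = risk_rate_abnormal,
    risk_rate_target = risk_rate_target,
    mixing = mixing / sum(mixing), seed = as.integer(seed)
  ), class = "generator_config")
}

#' Generate a synthetic imbalanced questionnaire dataset
#'
#' Target rows are drawn from the cluster mixture of Bernoulli profiles;
#' abnormal rows use the background profile with the risk options elevated to
#' `risk_rate_abnormal` (risk options sit at `risk_rate_target` in every
#' target profile). The ground truth — per-target-row cluster assignment, the
#' risk option set, and the profile matrix — is returned alongside so every
#' downstream stage (clustering, classification, option ranking) can be
#' scored without external data.
#'
#' @param config A [generator_config()].
#' @return List with `data` (a [binary_dataset()], target rows first) and
#'   `truth` (list: `cluster` per target row, `risk_options`, `profiles`,
#'   `abnormal_profile`).
#' @export
generate_questionnaire <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  p <- cfg$n_features

  structure_seed <- derive_seed(cfg$seed, "structure")
  with_seed(structure_seed, {
    risk <- cfg$risk_options
    if (is.null(risk)) risk <- sample.int(p, cfg$n_risk)
    risk <- sort(as.integer(risk))
    profiles <- cfg$cluster_profiles
    if (is.null(profiles)) {
      profiles <- matrix(cfg$base_rate, cfg$n_clusters, p)
      pool <- setdiff(seq_len(p), risk)
      need <- cfg$n_clusters * cfg$n_signature
      if (need > length(pool)) {
        stop("not enough non-risk features for disjoint cluster signatures",
             call. = FALSE)
      }
      chosen <- sample(pool, need)
      for (k in seq_len(cfg$n_clusters)) {
        sig <- chosen[(k - 1) * cfg$n_signature + seq_len(cfg$n_signature)]
        profiles[k, sig] <- min(cfg$base_rate + cfg$signature_amplitude,
                                0.995)
      }
    }
    profiles[, risk] <- cfg$risk_rate_target
  })

  abn_profile <- rep(cfg$base_rate, p)
  abn_profile[risk] <- cfg$risk_rate_abnormal

  with_seed(derive_seed(cfg$seed, "draw"), {
    z <- sample.int(cfg$n_clusters, cfg$n_target, replace = TRUE,
                    prob = cfg$mixing)
    Xt <- matrix(stats::rbinom(cfg$n_target * p, 1L,
                               t(profiles)[, z]), cfg$n_target, p,
                 byrow = TRUE)
    Xa <- if (cfg$n_abnormal > 0) {
      matrix(stats::rbinom(cfg$n_abnormal * p, 1L, rep(abn_profile,
                                                       cfg$n_abnormal)),
             cfg$n_abnormal, p, byrow = TRUE)
    } else {
      matrix(0, 0, p)
    }
  })

  X <- rbind(Xt, Xa)
  labels <- c(rep("target", cfg$n_target), rep("abnormal", cfg$n_abnormal))
  colnames(X) <- sprintf("opt%03d", seq_len(p))
  list(
    data = binary_dataset(X, labels),
    truth = list(cluster = z, risk_options = risk, profiles = profiles,
                 abnormal_profile = abn_profile)
  )
}
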