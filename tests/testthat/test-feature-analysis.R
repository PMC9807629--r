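test_that("imp_tfidf reproduces the published per-option scores", {
  counts <- antenatal_top10_counts()
  imp <- imp_tfidf(counts$p_t, counts$n_t, counts$N_p[1], counts$N[1])
  expect_equal(round(imp, 4),
               c(0.3195, 0.2537, 0.2483, 0.2380, 0.2133,
                 0.2042, 0.2005, 0.1956, 0.1864, 0.1826))
  expect_equal(imp_tfidf(0, 500, 407, 5666), 0)
})

test_that("info_gain reproduces the published values and basic identities", {
  counts <- antenatal_top10_counts()
  ig <- info_gain(counts$p_t, counts$n_t, counts$N_p[1], counts$N[1])
  expect_equal(round(ig[1], 4), 0.0044)
  expect_equal(round(ig[9], 4), 0.0029)
  # full column, same source
  expect_equal(round(ig, 4),
               c(0.0044, 0.0032, 0.0022, 0.0014, 0.0015,
                 0.0009, 0.0014, 0.0012, 0.0029, 0.0025))
  # class-independent split carries no information
  expect_equal(info_gain(p_t = 40, n_t = round(40 / 407 * 5259),
                         N_p = 407, N = 5666),
               0, tolerance = 1e-6)
  expect_true(all(ig >= 0))
})

test_that("imp_tfidf is monotone in p_t and n_t and base-invariant in rank", {
  base <- imp_tfidf(50, 200, 407, 5666)
  expect_gt(imp_tfidf(51, 200, 407, 5666), base)
  expect_lt(imp_tfidf(50, 201, 407, 5666), base)
  # changing the base rescales by a constant
  p <- c(10, 50, 90); n <- c(400, 200, 30)
  r10 <- imp_tfidf(p, n, 407, 5666, log_base = 10)
  r2 <- imp_tfidf(p, n, 407, 5666, log_base = 2)
  expect_equal(r2 / r10, rep(log(10) / log(2), 3))
  g10 <- info_gain(p, n, 407, 5666, log_base = 10)
  g2 <- info_gain(p, n, 407, 5666, log_base = 2)
  expect_equal(g2 / g10, rep(log(10) / log(2), 3))
})

test_that("classic_tfidf matches hand values and guards its preconditions", {
  expect_equal(classic_tfidf(3, 10, 100, 9), 0.3)
  expect_equal(classic_tfidf(0, 10, 100, 9), 0)
  expect_equal(classic_tfidf(10, 10, 100, 99), 0)
  expect_error(classic_tfidf(3, 0, 100, 9), "doc_length")
})

test_that("rank_options orders the published counts correctly", {
  counts <- antenatal_top10_counts()
  # rebuild a dataset realizing the published counts plus filler options
  N <- counts$N[1]; N_p <- counts$N_p[1]
  n_norm <- N - N_p
  build_col <- function(p, n) c(rep(1, p), rep(0, N_p - p),
                                rep(1, n), rep(0, n_norm - n))
  X <- vapply(seq_len(nrow(counts)),
              function(i) build_col(counts$p_t[i], counts$n_t[i]),
              numeric(N))
  # filler options with mid-pack scores
  set.seed(4)
  fill <- vapply(1:20, function(i) build_col(30, 1500), numeric(N))
  X <- cbind(X, fill)
  colnames(X) <- c(sprintf("top%02d", 1:10), sprintf("fill%02d", 1:20))
  d <- binary_dataset(X, c(rep("abnormal", N_p), rep("target", n_norm)))
  rk <- rank_options(d, k = 10)
  expect_equal(rk$ranking$option, sprintf("top%02d", 1:10))
  expect_equal(rk$ranking$p_t, counts$p_t)
  expect_equal(rk$ranking$n_t, counts$n_t)
  # k larger than the option count returns everything
  expect_equal(nrow(rank_options(d, k = 999)$ranking), 30)
  # duplicating every row: scores match direct recomputation from the
  # doubled counts (the +1 smoothing keeps them from being exactly equal to
  # the originals) and the ranking order is unchanged
  d2 <- binary_dataset(rbind(X, X), rep(d$labels, 2))
  rk2 <- rank_options(d2, k = 10)
  expect_equal(rk2$ranking$option, rk$ranking$option)
  expect_equal(rk2$ranking$imp_tfidf,
               imp_tfidf(2 * counts$p_t, 2 * counts$n_t, 2 * N_p, 2 * N))
  expect_equal(rk2$ranking$info_gain,
               info_gain(2 * counts$p_t, 2 * counts$n_t, 2 * N_p, 2 * N))
})

test_that("rank_options recovers designated risk options on synthetic data", {
  hits <- vapply(1:20, function(s) {
    sim <- generate_questionnaire(generator_config(
      n_target = 2000, n_abnormal = 150, n_clusters = 3,
      n_risk = 8, seed = s
    ))
    rk <- rank_options(sim$data, k = 16)
    found <- sum(sim$data$feature_names[sim$truth$risk_options] %in%
                   rk$ranking$option)
    found == 8
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("rank_options refuses single-class data", {
  d <- binary_dataset(matrix(rbinom(40, 1, 0.3), 10, 4),
                      rep("target", 10))
  expect_error(rank_options(d), "both classes")
})
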