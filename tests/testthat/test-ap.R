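test_that("degenerate inputs: identical points and a single point give K = 1", {
  X <- matrix(1, 6, 2)
  cr <- affinity_propagation(similarity_matrix(X))
  expect_equal(cr$K, 1)
  expect_equal(unique(cr$labels), 1L)
  one <- affinity_propagation(similarity_matrix(matrix(c(2, 3), 1, 2)))
  expect_equal(one$K, 1)
  expect_equal(one$exemplars, 1L)
})

test_that("two separated blobs: K = 2 with perfect label agreement", {
  fx <- two_blob_fixture()
  cr <- affinity_propagation(similarity_matrix(fx$X))
  expect_true(cr$converged)
  expect_equal(cr$K, 2)
  expect_equal(length(unique(paste(cr$labels, fx$truth))), 2)
  # every exemplar labels itself
  expect_equal(cr$labels[cr$exemplars], seq_len(cr$K))
  # assignment is locally optimal: each point sits with its most similar exemplar
  S <- similarity_matrix(fx$X)
  for (i in seq_len(nrow(fx$X))) {
    best <- which.max(S[i, cr$exemplars])
    if (!i %in% cr$exemplars) expect_equal(cr$labels[i], best)
  }
})

test_that("message passing agrees with the scikit-learn reference", {
  fx <- two_blob_fixture()
  S <- similarity_matrix(fx$X) # preference = median similarity
  cr <- affinity_propagation(S, damping = 0.9)
  csv <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  write.table(fx$X, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from sklearn.cluster import AffinityPropagation\n",
    "X = np.loadtxt('%s', delimiter=',')\n",
    "ap = AffinityPropagation(damping=0.9, preference=%.10f,\n",
    "                         random_state=0).fit(X)\n",
    "np.savetxt('%s', ap.labels_, fmt='%%d')\n"), csv, attr(S, "preference"),
    out)
  pf <- tempfile(fileext = ".py")
  writeLines(script, pf)
  res <- system2("python", pf, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  ref <- as.integer(readLines(out))
  expect_equal(length(unique(ref)), cr$K)
  # identical partitions up to label renaming
  expect_equal(length(unique(paste(cr$labels, ref))), cr$K)
})

test_that("silhouette matches the hand-computed 4-point fixture", {
  X <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  s <- silhouette_score(X, c(1, 1, 2, 2))
  expect_equal(s$mean, 0.99, tolerance = 1e-4)
  expect_true(all(s$s >= -1 & s$s <= 1))
  expect_error(silhouette_score(X, rep(1, 4)), "single cluster")
})

test_that("silhouette singleton convention and agreement with cluster::silhouette", {
  set.seed(14)
  X <- matrix(rnorm(40), 20, 2)
  labels <- c(rep(1, 10), rep(2, 9), 3) # cluster 3 is a singleton
  s <- silhouette_score(X, labels)
  expect_equal(s$s[20], 0)
  ref <- cluster::silhouette(labels, dist(X))
  # cluster::silhouette uses the same convention; compare all points
  expect_equal(s$s, unname(ref[, "sil_width"]), tolerance = 1e-8)
})

test_that("select_preference searches [min, median] and returns the silhouette max", {
  fx <- two_blob_fixture()
  best <- select_preference(fx$X, n_candidates = 8, seed = 1)
  cand <- attr(best, "candidates")
  D <- -as.matrix(dist(fx$X))^2
  off <- D[upper.tri(D)]
  expect_true(all(cand$preference >= min(off) - 1e-9))
  expect_true(all(cand$preference <= median(off) + 1e-9))
  expect_equal(best$K, 2)
  expect_equal(length(unique(paste(best$labels, fx$truth))), 2)
  finite <- cand$mean_silhouette[is.finite(cand$mean_silhouette)]
  expect_equal(best$mean_silhouette, max(finite))
  # determinism
  best2 <- select_preference(fx$X, n_candidates = 8, seed = 1)
  expect_identical(attr(best2, "candidates"), cand)
  expect_identical(best2$labels, best$labels)
})

test_that("subsampled preference search still recovers blob structure", {
  fx <- two_blob_fixture(n_per = 40, seed = 3)
  best <- select_preference(fx$X, n_candidates = 6, seed = 2, max_n = 30)
  expect_equal(best$K, 2)
  expect_equal(length(best$labels), 80)
  expect_equal(length(unique(paste(best$labels, fx$truth))), 2)
  expect_equal(best$labels[best$exemplars], seq_len(best$K))
})
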