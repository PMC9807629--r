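test_that("read_libsvm parses sparse lines, maps 1-based indices, binarizes", {
  f <- withr::local_tempfile(fileext = ".libsvm")
  writeLines(c("+1 1:1 3:1", "-1 2:5", "+1 7:0.5"), f)
  d <- read_libsvm(f)
  expect_s3_class(d, "binary_dataset")
  expect_equal(d$n_features, 7) # width = max index seen
  expect_equal(unname(d$matrix[1, ]), c(1, 0, 1, 0, 0, 0, 0))
  expect_equal(d$labels, c("target", "abnormal", "target"))
  expect_equal(unname(d$matrix[2, 2]), 1) # 5 binarized by != 0
  # raw values preserved when binarize = FALSE
  raw <- read_libsvm(f, binarize = FALSE)
  expect_equal(unname(raw$matrix[2, 2]), 5)
})

test_that("read_libsvm rejects malformed and empty input with line numbers", {
  f <- withr::local_tempfile(fileext = ".libsvm")
  writeLines(c("+1 1:1", "-1 zap"), f)
  expect_error(read_libsvm(f), "line 2")
  writeLines(character(0), f)
  expect_error(read_libsvm(f), "empty")
  expect_error(read_libsvm(file.path(tempdir(), "nope.libsvm")), "not found")
})

test_that("libsvm write/read round-trips bit-exactly", {
  d <- tiny_dataset()
  f <- withr::local_tempfile(fileext = ".libsvm")
  write_libsvm(d, f)
  d2 <- read_libsvm(f, n_features = d$n_features)
  expect_equal(unname(d2$matrix), unname(d$matrix))
  expect_equal(d2$labels, d$labels)
})

test_that("read_questionnaire drops ids, one-hot expands, passes binaries", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    id = c("a", "b", "c", "d"),
    smoker = c(1, 0, 1, 0),
    mood = c("low", "mid", "high", "mid"),
    status = c("dep", "ok", "ok", "ok")
  )
  write.csv(df, f, row.names = FALSE)
  d <- read_questionnaire(f, label_column = "status", abnormal_value = "dep",
                          id_columns = "id")
  expect_equal(d$labels, c("abnormal", "target", "target", "target"))
  expect_true("smoker" %in% d$feature_names)      # binary passthrough
  expect_equal(sum(grepl("^mood=", d$feature_names)), 3) # 3-level one-hot
  onehot <- d$matrix[, grepl("^mood=", d$feature_names)]
  expect_equal(unname(rowSums(onehot)), rep(1, 4)) # exactly one set per row
  expect_false("id" %in% d$feature_names)
  expect_error(read_questionnaire(f, label_column = "nope",
                                  abnormal_value = "dep"), "label column")
})

test_that("read_questionnaire encodes missing answers as all-zero and names free text", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("q1,label", "yes,ok", "NA,ok", "no,dep"), f)
  d <- read_questionnaire(f, "label", "dep")
  expect_equal(unname(rowSums(d$matrix)), c(1, 0, 1))
  f2 <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(essay = paste0("text", 1:30), label = rep("ok", 30))
  write.csv(df, f2, row.names = FALSE)
  expect_error(read_questionnaire(f2, "label", "dep"), "essay")
})

test_that("split takes floor of the target fraction and no abnormals in train", {
  set.seed(9)
  n_t <- 5259; n_a <- 407
  X <- matrix(rbinom((n_t + n_a) * 3, 1, 0.3), ncol = 3)
  d <- binary_dataset(X, c(rep("target", n_t), rep("abnormal", n_a)))
  sp <- split_dataset(d, split_spec(0.8, seed = 7))
  expect_equal(sum(sp$train$labels == "target"), floor(0.8 * n_t)) # 4207
  expect_equal(sum(sp$train$labels == "abnormal"), 0)
  expect_equal(sum(sp$test$labels == "abnormal"), n_a)
  expect_equal(sum(sp$test$labels == "target"), floor(0.2 * n_t))
})

test_that("split is seed-reproducible with disjoint partitions", {
  d <- binary_dataset(matrix(rbinom(600, 1, 0.5), 100, 6),
                      c(rep("target", 80), rep("abnormal", 20)))
  a <- split_dataset(d, split_spec(0.7, 0.3, 1, seed = 5))
  b <- split_dataset(d, split_spec(0.7, 0.3, 1, seed = 5))
  expect_identical(a$train$matrix, b$train$matrix)
  expect_identical(a$test$matrix, b$test$matrix)
  # boundary: everything to train, empty test
  all_in <- split_dataset(d, split_spec(1, 0, 0, seed = 5))
  expect_equal(all_in$train$n_samples, 80)
  expect_equal(all_in$test$n_samples, 0)
  expect_error(split_spec(0.9, 0.2), "<= 1")
})

test_that("binary_dataset enforces its invariants", {
  expect_error(binary_dataset(matrix(c(0, 2), 1), "target"), "0 or 1")
  expect_error(binary_dataset(matrix(0, 2, 2), "target"), "length")
  expect_error(binary_dataset(matrix(0, 1, 2), "target",
                              feature_names = c("a", "a")), "unique")
  expect_error(binary_dataset(matrix(0, 1, 1), "other"), "labels")
})
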