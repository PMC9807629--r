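test_that("build_sae produces the requested shapes and seeded init", {
  st <- build_sae(c(147, 110, 90, 30), seed = 4)
  expect_equal(length(st$layers), 3)
  expect_equal(dim(st$layers[[1]]$W1), c(147, 110))
  expect_equal(dim(st$layers[[2]]$W1), c(110, 90))
  expect_equal(dim(st$layers[[3]]$W1), c(90, 30))
  expect_equal(dim(st$layers[[3]]$W2), c(30, 90)) # mirrored decode
  sq <- build_sae(c(5, 5), seed = 1)
  expect_equal(dim(sq$layers[[1]]$W1), c(5, 5))
  st2 <- build_sae(c(147, 110, 90, 30), seed = 4)
  expect_identical(st$layers, st2$layers)
  expect_error(build_sae(c(10)), "hidden")
  expect_error(build_sae(c(10, 0)), "hidden")
})

test_that("layer-wise training reduces reconstruction loss per layer", {
  set.seed(2)
  X <- matrix(rbinom(200 * 20, 1, 0.3), 200, 20)
  st <- build_sae(c(20, 12, 6), seed = 7)
  st <- train_layerwise(st, X, epochs = 20, learning_rate = 0.3,
                        batch_size = 32)
  for (h in st$loss_history) {
    expect_lt(tail(h, 1), h[1])
  }
  # round-trip error after training is no worse than at initialization
  st0 <- build_sae(c(20, 12, 6), seed = 7)
  err0 <- mean((sae_reconstruct(st0, X) - X)^2)
  err1 <- mean((sae_reconstruct(st, X) - X)^2)
  expect_lt(err1, err0)
})

test_that("a linear autoencoder recovers a rank-2 subspace", {
  set.seed(1)
  B <- matrix(rnorm(40), 20, 2)
  W <- matrix(rnorm(10), 2, 5)
  X <- B %*% W
  st <- build_sae(c(5, 2), activation = "linear", seed = 2)
  st <- train_layerwise(st, X, epochs = 500, learning_rate = 0.05,
                        batch_size = 8)
  expect_lt(mean((sae_reconstruct(st, X) - X)^2), 1e-3)
})

test_that("zero epochs leave weights unchanged; training is seed-reproducible", {
  set.seed(3)
  X <- matrix(rbinom(50 * 8, 1, 0.4), 50, 8)
  st0 <- build_sae(c(8, 4), seed = 9)
  st <- train_layerwise(st0, X, epochs = 0)
  expect_identical(st$layers, st0$layers)
  a <- train_layerwise(st0, X, epochs = 5, learning_rate = 0.2)
  b <- train_layerwise(st0, X, epochs = 5, learning_rate = 0.2)
  expect_identical(a$loss_history, b$loss_history)
  expect_identical(a$layers, b$layers)
})

test_that("encode applies only the encoder half, batch equals row-by-row", {
  set.seed(6)
  X <- matrix(rbinom(30 * 147, 1, 0.2), 30, 147)
  st <- build_sae(c(147, 110, 90, 30), seed = 5)
  st <- train_layerwise(st, X, epochs = 2, learning_rate = 0.3)
  co <- sae_encode(st, X)
  expect_equal(dim(co), c(30, 30))
  rowwise <- t(vapply(seq_len(nrow(X)),
                      function(i) drop(sae_encode(st, X[i, ])),
                      numeric(30)))
  expect_equal(co, rowwise, tolerance = 1e-12)
  # identical rows encode identically
  X2 <- X[c(1, 1), ]
  co2 <- sae_encode(st, X2)
  expect_identical(co2[1, ], co2[2, ])
  expect_error(sae_encode(st, matrix(0, 2, 10)), "dimension")
})

test_that("training aborts with a diagnostic on divergence", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6, 0, 50), 40, 6) # wild scale + linear act
  st <- build_sae(c(6, 3), activation = "linear", seed = 1)
  expect_error(
    train_layerwise(st, X, epochs = 50, learning_rate = 5),
    "loss"
  )
})
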