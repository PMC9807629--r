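#' Build a stacked autoencoder
#'
#' Constructs one autoencoder per consecutive pair of `layer_sizes`; the
#' stack is symmetric, each layer holding encode weights `W1, b1`
#' (input -> hidden) and decode weights `W2, b2` (hidden -> input). Weights
#' are initialized by a seeded uniform Glorot-style scheme
#' `U(-r, r), r = sqrt(6 / (fan_in + fan_out))`; offsets start at zero.
#' Layer sizes need not decrease, although dimensionality reduction is the
#' intended use (e.g. `c(147, 110, 90, 30)`).
#'
#' @param layer_sizes Integer vector: input dimension followed by the hidden
#'   dimension of each autoencoder (>= 1 hidden layer, all sizes positive).
#' @param activation `"sigmoid"` (default) or `"linear"`.
#' @param seed Integer seed for the initialisation.
#' @return An `encoder_stack`.
#' @export
build_sae <- function(layer_sizes, activation = c("sigmoid", "linear"),
                      seed = 1L) {
  activation <- match.arg(activation)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("layer_sizes needs an input size plus >= 1 positive hidden size",
         call. = FALSE)
  }
  n_layers <- length(layer_sizes) - 1L
  layers <- with_seed(derive_seed(seed, "sae-init"), {
    lapply(seq_len(n_layers), function(l) {
      nin <- layer_sizes[l]; nout <- layer_sizes[l + 1L]
      r <- sqrt(6 / (nin + nout))
      list(
        W1 = matrix(stats::runif(nin * nout, -r, r), nin, nout),
        b1 = numeric(nout),
        W2 = matrix(stats::runif(nin * nout, -r, r), nout, nin),
        b2 = numeric(nin)
      )
    })
  })
  structure(list(layer_sizes = layer_sizes, layers = layers,
                 activation = activation, seed = as.integer(seed),
                 trained = FALSE, loss_history = NULL),
            class = "encoder_stack")
}

sae_act <- function(stack, z) {
  if (stack$activation == "sigmoid") 1 / (1 + exp(-z)) else z
}

sae_act_grad <- function(stack, a) {
  if (stack$activation == "sigmoid") a * (1 - a) else 1
}

#' Greedy layer-wise training of a stacked autoencoder
#'
#' Each autoencoder is trained front-to-back to reconstruct its own input —
#' the frozen code of the previous layer — by mini-batch stochastic gradient
#' descent on the mean squared reconstruction error. Later layers consume
#' the earlier layers' codes; nothing is fine-tuned end-to-end (no labels
#' exist in one-class training).
#'
#' @param stack An [build_sae()] result.
#' @param X Training matrix; columns must match the input size.
#' @param epochs Passes over the data per layer.
#' @param learning_rate SGD step size.
#' @param batch_size Mini-batch size.
#' @return The trained `encoder_stack` with `loss_history` (per layer, mean
#'   reconstruction MSE per epoch, the first entry being the loss at
#'   initialization).
#' @export
train_layerwise <- function(stack, X, epochs = 100, learning_rate = 0.01,
                            batch_size = 32) {
  stopifnot(inherits(stack, "encoder_stack"))
  X <- as.matrix(X)
  if (ncol(X) != stack$layer_sizes[1]) {
    stop("train_layerwise: input dimension mismatch", call. = FALSE)
  }
  n <- nrow(X)
  input <- X
  history <- vector("list", length(stack$layers))
  with_seed(derive_seed(stack$seed, "sae-train"), {
    for (l in seq_along(stack$layers)) {
      ly <- stack$layers[[l]]
      losses <- numeric(epochs + 1)
      code0 <- sae_act(stack, sweep(input %*% ly$W1, 2, ly$b1, "+"))
      rec0 <- sae_act(stack, sweep(code0 %*% ly$W2, 2, ly$b2, "+"))
      losses[1] <- mean((rec0 - input)^2)
      if (epochs > 0) {
        for (ep in seq_len(epochs)) {
          ord <- sample.int(n)
          for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
            xb <- input[b, , drop = FALSE]
            m <- length(b)
            h <- sae_act(stack, sweep(xb %*% ly$W1, 2, ly$b1, "+"))
            r <- sae_act(stack, sweep(h %*% ly$W2, 2, ly$b2, "+"))
            # backprop of the MSE 1/(m*p) * sum (r - x)^2
            dr <- 2 * (r - xb) / (m * ncol(xb)) * sae_act_grad(stack, r)
            gW2 <- crossprod(h, dr)
            gb2 <- colSums(dr)
            dh <- tcrossprod(dr, ly$W2) * sae_act_grad(stack, h)
            gW1 <- crossprod(xb, dh)
            gb1 <- colSums(dh)
            ly$W2 <- ly$W2 - learning_rate * gW2
            ly$b2 <- ly$b2 - learning_rate * gb2
            ly$W1 <- ly$W1 - learning_rate * gW1
            ly$b1 <- ly$b1 - learning_rate * gb1
          }
          code <- sae_act(stack, sweep(input %*% ly$W1, 2, ly$b1, "+"))
          rec <- sae_act(stack, sweep(code %*% ly$W2, 2, ly$b2, "+"))
          losses[ep + 1] <- mean((rec - input)^2)
          if (!is.finite(losses[ep + 1])) {
            stop(sprintf(
              "NaN/Inf reconstruction loss in layer %d epoch %d; reduce the learning rate",
              l, ep), call. = FALSE)
          }
        }
      }
      stack$layers[[l]] <- ly
      history[[l]] <- losses
      input <- sae_act(stack, sweep(input %*% ly$W1, 2, ly$b1, "+"))
    }
  })
  stack$trained <- TRUE
  stack$loss_history <- history
  stack
}

#' Encode samples with the encoder half of the stack
#'
#' Applies only the front-to-back encode maps; the output dimension is the
#' last hidden size. Deterministic: batch encoding equals row-by-row
#' encoding.
#'
#' @param stack An `encoder_stack`.
#' @param X Matrix (or vector, taken as one row) with `layer_sizes[1]`
#'   columns.
#' @return Code matrix with `tail(layer_sizes, 1)` columns.
#' @export
sae_encode <- function(stack, X) {
  stopifnot(inherits(stack, "encoder_stack"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != stack$layer_sizes[1]) {
    stop("sae_encode: input dimension mismatch", call. = FALSE)
  }
  a <- X
  for (ly in stack$layers) {
    a <- sae_act(stack, sweep(a %*% ly$W1, 2, ly$b1, "+"))
  }
  a
}

#' Reconstruct samples through the full encode/decode stack
#'
#' Encodes front-to-back then decodes back-to-front through the mirrored
#' decode halves; used to monitor reconstruction quality.
#'
#' @param stack An `encoder_stack`.
#' @param X Input matrix.
#' @return Reconstruction matrix, same shape as `X`.
#' @export
sae_reconstruct <- function(stack, X) {
  stopifnot(inherits(stack, "encoder_stack"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  a <- as.matrix(X)
  for (ly in stack$layers) {
    a <- sae_act(stack, sweep(a %*% ly$W1, 2, ly$b1, "+"))
  }
  for (ly in rev(stack$layers)) {
    a <- sae_act(stack, sweep(a %*% ly$W2, 2, ly$b2, "+"))
  }
  a
}

#' @export
print.encoder_stack <- function(x, ...) {
  cat(sprintf("<encoder_stack> %s, activation = %s, %s\n",
              paste(x$layer_sizes, collapse = " -> "), x$activation,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}
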