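# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages (splitting, generator, LHS, PSO, SAE initialisation,
#' cross-validation folds) draw their own seed from a single master seed via
#' this function, so each stage is independently reproducible and changing one
#' stage's label does not disturb another's stream.
#'
#' The scheme is `(seed * 48271 + hash(label)) mod (2^31 - 2) + 1`, where
#' `hash` sums the UTF-8 code points of the label weighted by position.
#'
#' @param seed Integer master seed.
#' @param label Character tag naming the consuming stage.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  m <- 2147483646
  as.integer(((abs(seed) %% m) * 48271 + h) %% m + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
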