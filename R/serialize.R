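SAESVDD_FORMAT_VERSION <- "saesvdd-model/1"

.sphere_to_list <- function(m) {
  keep <- m$alphas > 1e-12 # zero-alpha points never affect the decision
  list(
    support_vectors = unname(m$support_vectors[keep, , drop = FALSE]),
    alphas = m$alphas[keep],
    C = m$C,
    kernel = list(kind = m$kernel$kind, sigma = m$kernel$sigma),
    radius_sq = m$radius_sq,
    center_norm_sq = m$center_norm_sq
  )
}

# rows: list of equal-length numeric lists (a JSON 2-d array) -> matrix
.as_matrix <- function(rows) {
  do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
}

.sphere_from_list <- function(s) {
  structure(list(
    support_vectors = .as_matrix(s$support_vectors),
    alphas = as.numeric(unlist(s$alphas)),
    C = as.numeric(s$C),
    kernel = kernel_spec(s$kernel$kind, as.numeric(s$kernel$sigma %||% 1)),
    radius_sq = as.numeric(s$radius_sq),
    center_norm_sq = as.numeric(s$center_norm_sq),
    objective = NA_real_
  ), class = "svdd_model")
}

.core_to_list <- function(core) {
  list(
    K = core$clusters$K,
    exemplars = core$clusters$exemplars,
    preference = core$clusters$preference,
    mean_silhouette = core$clusters$mean_silhouette,
    spheres = lapply(core$spheres, .sphere_to_list),
    params = lapply(core$params, as.list),
    fitness = core$fitness
  )
}

.core_from_list <- function(x) {
  cl <- structure(list(
    K = as.integer(x$K), labels = NULL,
    exemplars = as.integer(unlist(x$exemplars)),
    preference = as.numeric(x$preference %||% NA),
    iterations = NA_integer_, converged = NA,
    mean_silhouette = as.numeric(x$mean_silhouette %||% NA)
  ), class = "cluster_result")
  structure(list(
    clusters = cl,
    spheres = lapply(x$spheres, .sphere_from_list),
    params = lapply(x$params, function(p) {
      out <- c(C = as.numeric(p$C), sigma = as.numeric(p$sigma))
      if (!is.null(p$nu)) out <- c(out, nu = as.numeric(p$nu))
      out
    }),
    fitness = as.numeric(unlist(x$fitness)),
    config = NULL
  ), class = "sa_svdd")
}

#' Save a fitted model to a self-describing JSON archive
#'
#' The archive records a format version, the model kind, encoder weights
#' (for the autoencoder variant), and per-sphere support vectors, dual
#' coefficients, penalty, kernel, squared radius and cluster metadata.
#' Loading an archive written by this function reproduces the model's
#' predictions exactly; points whose dual coefficient is zero are dropped on
#' save since they never contribute to the decision function.
#'
#' @param model An `sa_svdd` or `sae_svdd` model.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  payload <- if (inherits(model, "sae_svdd")) {
    list(
      format_version = SAESVDD_FORMAT_VERSION,
      kind = "sae_svdd",
      encoder = list(
        layer_sizes = model$encoder$layer_sizes,
        activation = model$encoder$activation,
        layers = lapply(model$encoder$layers, function(ly) {
          list(W1 = unname(ly$W1), b1 = ly$b1,
               W2 = unname(ly$W2), b2 = ly$b2)
        })
      ),
      core = .core_to_list(model$core)
    )
  } else if (inherits(model, "sa_svdd")) {
    list(format_version = SAESVDD_FORMAT_VERSION,
         kind = "sa_svdd",
         core = .core_to_list(model))
  } else {
    stop("save_model: unsupported model class", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' @param path Path to the JSON archive.
#' @return The reconstructed `sa_svdd` or `sae_svdd` model.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) {
                  stop("cannot parse model archive: ", conditionMessage(e),
                       call. = FALSE)
                })
  if (!identical(x$format_version, SAESVDD_FORMAT_VERSION)) {
    stop(sprintf("model format version mismatch: found '%s', expected '%s'",
                 x$format_version %||% "<missing>",
                 SAESVDD_FORMAT_VERSION), call. = FALSE)
  }
  if (identical(x$kind, "sae_svdd")) {
    layers <- lapply(x$encoder$layers, function(ly) {
      list(W1 = .as_matrix(ly$W1), b1 = as.numeric(unlist(ly$b1)),
           W2 = .as_matrix(ly$W2), b2 = as.numeric(unlist(ly$b2)))
    })
    stack <- structure(list(
      layer_sizes = as.integer(unlist(x$encoder$layer_sizes)),
      layers = layers, activation = x$encoder$activation,
      seed = NA_integer_, trained = TRUE, loss_history = NULL
    ), class = "encoder_stack")
    structure(list(encoder = stack, core = .core_from_list(x$core)),
              class = "sae_svdd")
  } else if (identical(x$kind, "sa_svdd")) {
    .core_from_list(x$core)
  } else {
    stop("unknown model kind in archive: ",
         if (is.null(x$kind)) "<missing>" else x$kind, call. = FALSE)
  }
}
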