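#' Labeled binary sample matrix
#'
#' The container every stage of the pipeline consumes: a samples x features
#' matrix of 0/1 answer indicators plus a per-sample class label, `"target"`
#' for the majority (healthy) class and `"abnormal"` for the minority class
#' (e.g. respondents screened as depressed or anxious).
#'
#' @param x Numeric matrix of 0/1 values, one row per respondent and one
#'   column per questionnaire option.
#' @param labels Character vector (or factor) of `"target"` / `"abnormal"`,
#'   one per row of `x`.
#' @param feature_names Optional unique column names; defaults to existing
#'   column names or `V1..Vp`.
#' @return An object of class `binary_dataset` with elements `matrix`,
#'   `labels`, `feature_names`, `n_samples`, `n_features`.
#' @examples
#' d <- binary_dataset(matrix(c(1, 0, 0, 1), 2), c("target", "abnormal"))
#' d$n_features
#' @export
binary_dataset <- function(x, labels, feature_names = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (is.null(feature_names)) {
    feature_names <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  }
  colnames(x) <- feature_names
  obj <- structure(
    list(
      matrix = x,
      labels = labels,
      feature_names = feature_names,
      n_samples = nrow(x),
      n_features = ncol(x)
    ),
    class = "binary_dataset"
  )
  validate_binary_dataset(obj)
}

validate_binary_dataset <- function(d) {
  stopifnot(inherits(d, "binary_dataset"))
  if (!all(d$matrix %in% c(0, 1))) {
    stop("binary_dataset: every cell must be 0 or 1", call. = FALSE)
  }
  if (length(d$labels) != d$n_samples) {
    stop("binary_dataset: labels length must equal n_samples", call. = FALSE)
  }
  if (!all(d$labels %in% c("target", "abnormal"))) {
    stop("binary_dataset: labels must be 'target' or 'abnormal'", call. = FALSE)
  }
  if (anyDuplicated(d$feature_names) || length(d$feature_names) != d$n_features) {
    stop("binary_dataset: feature_names must be unique, one per column",
         call. = FALSE)
  }
  d
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat(sprintf(
    "<binary_dataset> %d samples x %d features (%d target, %d abnormal)\n",
    x$n_samples, x$n_features,
    sum(x$labels == "target"), sum(x$labels == "abnormal")
  ))
  invisible(x)
}

#' Subset a binary dataset by row index
#'
#' @param d A [binary_dataset()].
#' @param idx Integer row indices.
#' @return A `binary_dataset` with the selected rows.
#' @export
dataset_subset <- function(d, idx) {
  stopifnot(inherits(d, "binary_dataset"))
  binary_dataset(d$matrix[idx, , drop = FALSE], d$labels[idx], d$feature_names)
}
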