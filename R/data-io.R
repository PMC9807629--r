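#' Read a LIBSVM sparse-format file
#'
#' Parses the space-separated `"<label> <index>:<value> ..."` sparse format
#' used by the LIBSVM repository. Indices are 1-based in the file and map to
#' columns 1..max(index); by default values are binarized by `value != 0`,
#' matching the sparse 0/1 encoding the classifier consumes.
#'
#' @param path Path to the file.
#' @param target_labels Label tokens mapped to the target class; every other
#'   label becomes abnormal. Defaults to `"+1"`/`"1"`.
#' @param n_features Force the feature count (columns beyond the max index
#'   seen); `NULL` uses the maximum index in the file.
#' @param binarize If `TRUE` (default) coerce values to 0/1 by `!= 0`;
#'   if `FALSE` raw values are kept and the result is a plain list with the
#'   same fields (not a valid 0/1 `binary_dataset`).
#' @return A [binary_dataset()] (or a plain list when `binarize = FALSE`).
#' @export
read_libsvm <- function(path, target_labels = c("+1", "1"),
                        n_features = NULL, binarize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty LIBSVM file: ", path, call. = FALSE)

  labs <- character(length(lines))
  ij <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    labs[i] <- tok[1]
    if (length(tok) > 1L) {
      parts <- strsplit(tok[-1], ":", fixed = TRUE)
      bad <- vapply(parts, length, 1L) != 2L
      if (any(bad)) {
        stop(sprintf("malformed LIBSVM entry on line %d: '%s'",
                     i, tok[-1][bad][1]), call. = FALSE)
      }
      idx <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
      val <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
      if (anyNA(idx) || anyNA(val) || any(idx < 1L)) {
        stop(sprintf("malformed LIBSVM entry on line %d", i), call. = FALSE)
      }
      ij[[i]] <- cbind(i = i, j = idx, v = val)
    } else {
      ij[[i]] <- cbind(i = integer(0), j = integer(0), v = numeric(0))
    }
  }
  trip <- do.call(rbind, ij)
  p <- n_features %||% if (nrow(trip)) max(trip[, "j"]) else 0L
  X <- matrix(0, length(lines), p)
  if (nrow(trip)) X[trip[, c("i", "j"), drop = FALSE]] <- trip[, "v"]
  labels <- ifelse(labs %in% target_labels, "target", "abnormal")
  if (binarize) {
    X <- (X != 0) * 1
    binary_dataset(X, labels)
  } else {
    colnames(X) <- paste0("V", seq_len(ncol(X)))
    list(matrix = X, labels = labels, feature_names = colnames(X),
         n_samples = nrow(X), n_features = ncol(X))
  }
}

#' Write a dataset in LIBSVM sparse format
#'
#' @param d A [binary_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_libsvm <- function(d, path) {
  stopifnot(inherits(d, "binary_dataset"))
  lines <- vapply(seq_len(d$n_samples), function(i) {
    j <- which(d$matrix[i, ] != 0)
    lab <- if (d$labels[i] == "target") "+1" else "-1"
    if (length(j) == 0L) lab
    else paste(lab, paste0(j, ":", format(d$matrix[i, j], trim = TRUE),
                           collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a questionnaire table (CSV/TSV) into a binary dataset
#'
#' Applies the pre-processing workflow for raw survey tables: identifier
#' columns are dropped (denoising), every retained categorical column is
#' one-hot expanded so each resulting column is a 0/1 option indicator
#' (binarization), already-binary 0/1 columns pass through unchanged, and the
#' label column is mapped to target/abnormal. Missing answers encode as
#' all-zero across the question's derived columns.
#'
#' @param path CSV (default) or TSV file with a header row.
#' @param label_column Name of the class label column.
#' @param abnormal_value Value in `label_column` marking the abnormal class;
#'   everything else (non-missing) is target. Label polarity is never
#'   inferred.
#' @param id_columns Character vector of identifier columns to drop.
#' @param sep Field separator; `","` or `"\t"`.
#' @param max_levels A non-binary column with more distinct values than this
#'   is refused as free text rather than silently exploded.
#' @return A [binary_dataset()]; derived columns are named
#'   `<question>=<level>`.
#' @export
read_questionnaire <- function(path, label_column, abnormal_value,
                               id_columns = character(), sep = ",",
                               max_levels = 20L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!label_column %in% names(df)) {
    stop("label column not found: ", label_column, call. = FALSE)
  }
  labels <- ifelse(is.na(df[[label_column]]), NA_character_,
                   ifelse(df[[label_column]] == abnormal_value,
                          "abnormal", "target"))
  if (anyNA(labels)) stop("missing values in label column", call. = FALSE)
  keep <- setdiff(names(df), c(label_column, id_columns))
  if (length(keep) == 0L) stop("no feature columns remain", call. = FALSE)

  blocks <- lapply(keep, function(nm) {
    col <- df[[nm]]
    if (is.numeric(col) && all(col %in% c(0, 1) | is.na(col))) {
      m <- matrix(ifelse(is.na(col), 0, col), ncol = 1,
                  dimnames = list(NULL, nm))
      return(m)
    }
    lev <- sort(unique(col[!is.na(col)]))
    if (length(lev) > max_levels) {
      stop(sprintf("column '%s' has %d distinct values; not categorizable",
                   nm, length(lev)), call. = FALSE)
    }
    m <- vapply(lev, function(v) as.numeric(!is.na(col) & col == v),
                numeric(nrow(df)))
    if (!is.matrix(m)) m <- matrix(m, nrow = nrow(df))
    colnames(m) <- paste0(nm, "=", lev)
    m
  })
  X <- do.call(cbind, blocks)
  binary_dataset(X, labels)
}

#' Train/test split specification
#'
#' The pre-processing workflow trains on target-class samples only: the
#' training set takes a fraction of the targets, the test set takes the
#' remaining target fraction plus a fraction of the abnormal samples
#' (defaults: 80% of targets train; 20% of targets and all abnormals test).
#'
#' @param train_target_fraction Fraction of target samples in the training
#'   set, in (0, 1].
#' @param test_target_fraction Fraction of target samples in the test set.
#' @param test_abnormal_fraction Fraction of abnormal samples in the test
#'   set.
#' @param seed Integer seed; sampling is without replacement and reproducible.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_target_fraction = 0.8,
                       test_target_fraction = 1 - train_target_fraction,
                       test_abnormal_fraction = 1,
                       seed = 1L) {
  stopifnot(
    train_target_fraction > 0, train_target_fraction <= 1,
    test_target_fraction >= 0, test_target_fraction <= 1,
    test_abnormal_fraction >= 0, test_abnormal_fraction <= 1
  )
  if (train_target_fraction + test_target_fraction > 1 + 1e-12) {
    stop("train_target_fraction + test_target_fraction must be <= 1",
         call. = FALSE)
  }
  structure(list(train_target_fraction = train_target_fraction,
                 test_target_fraction = test_target_fraction,
                 test_abnormal_fraction = test_abnormal_fraction,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a dataset into a target-only training set and a mixed test set
#'
#' @param d A [binary_dataset()] with at least one target sample.
#' @param spec A [split_spec()].
#' @return List with `train` and `test` datasets; `train` contains
#'   `floor(train_target_fraction * n_target)` target rows and no abnormal
#'   rows; partitions are disjoint.
#' @export
split_dataset <- function(d, spec = split_spec()) {
  stopifnot(inherits(d, "binary_dataset"), inherits(spec, "split_spec"))
  tgt <- which(d$labels == "target")
  abn <- which(d$labels == "abnormal")
  if (length(tgt) == 0L) stop("no target samples to split", call. = FALSE)
  n_train <- floor(spec$train_target_fraction * length(tgt))
  n_test_t <- floor(spec$test_target_fraction * length(tgt))
  n_test_a <- floor(spec$test_abnormal_fraction * length(abn))
  with_seed(derive_seed(spec$seed, "split"), {
    tgt_perm <- sample(tgt)
    abn_sel <- if (length(abn)) sample(abn, n_test_a) else integer(0)
  })
  train_idx <- sort(tgt_perm[seq_len(n_train)])
  test_idx <- sort(c(
    if (n_test_t > 0) tgt_perm[n_train + seq_len(n_test_t)] else integer(0),
    abn_sel
  ))
  list(train = dataset_subset(d, train_idx),
       test = dataset_subset(d, test_idx))
}
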