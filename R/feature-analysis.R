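#' Improved TF-IDF importance of a questionnaire option
#'
#' `imp(t) = (p_t / N_p) * log(N / (1 + n_t))`: the option's selection
#' frequency among abnormal-class respondents, discounted by its prevalence
#' among normal respondents. The default log base is 10, which is the base
#' that reproduces the published per-option scores this statistic was
#' validated against; changing the base rescales all scores by a constant,
#' so the ranking is base-invariant.
#'
#' @param p_t Count of abnormal respondents selecting option `t`
#'   (`0 <= p_t <= N_p`).
#' @param n_t Count of normal respondents selecting `t`
#'   (`0 <= n_t <= N - N_p`).
#' @param N_p Number of abnormal respondents (> 0).
#' @param N Total respondents.
#' @param log_base Logarithm base (default 10).
#' @return The importance score (vectorized over `p_t`/`n_t`).
#' @export
imp_tfidf <- function(p_t, n_t, N_p, N, log_base = 10) {
  if (N_p <= 0) stop("imp_tfidf: N_p must be positive", call. = FALSE)
  stopifnot(all(p_t >= 0), all(p_t <= N_p), all(n_t >= 0),
            all(n_t <= N - N_p))
  (p_t / N_p) * log(N / (1 + n_t), base = log_base)
}

# Entropy of a count vector in the given log base; 0 * log 0 == 0.
.entropy <- function(counts, log_base) {
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = log_base))
}

#' Information gain of the binary selected/not-selected split
#'
#' Reduction in class entropy (target vs abnormal) achieved by splitting the
#' sample set on whether option `t` was selected:
#' `Gain = Ent(D) - sum_v |D_v|/|D| * Ent(D_v)` over the two branches, with
#' the convention `0 * log 0 = 0`; an empty branch contributes 0 (weight 0).
#' Default base 10, matching [imp_tfidf()].
#'
#' @inheritParams imp_tfidf
#' @return The information gain (vectorized; always >= 0 up to rounding).
#' @export
info_gain <- function(p_t, n_t, N_p, N, log_base = 10) {
  stopifnot(N_p > 0, N > N_p, length(p_t) == length(n_t),
            all(p_t >= 0), all(p_t <= N_p),
            all(n_t >= 0), all(n_t <= N - N_p))
  vapply(seq_along(p_t), function(i) {
    pt <- p_t[i]; nt <- n_t[i]
    ent_d <- .entropy(c(N_p, N - N_p), log_base)
    sel <- pt + nt
    not <- N - sel
    w_sel <- if (sel > 0) sel / N * .entropy(c(pt, nt), log_base) else 0
    w_not <- if (not > 0) {
      not / N * .entropy(c(N_p - pt, N - N_p - nt), log_base)
    } else 0
    ent_d - w_sel - w_not
  }, numeric(1))
}

#' Classic TF-IDF of a word in a document
#'
#' `(f / doc_length) * log(N_docs / (1 + n_docs_with_t))`. Provided as the
#' reference formula the improved option statistic derives from; no corpus
#' pipeline is built around it.
#'
#' @param term_freq Occurrences of the word in the document.
#' @param doc_length Total words in the document (> 0).
#' @param N_docs Corpus size (> 0).
#' @param n_docs_with_t Documents containing the word.
#' @param log_base Logarithm base (default 10).
#' @return The TF-IDF score.
#' @export
classic_tfidf <- function(term_freq, doc_length, N_docs, n_docs_with_t,
                          log_base = 10) {
  if (doc_length <= 0) stop("classic_tfidf: doc_length must be positive",
                            call. = FALSE)
  if (N_docs <= 0) stop("classic_tfidf: N_docs must be positive",
                        call. = FALSE)
  (term_freq / doc_length) * log(N_docs / (1 + n_docs_with_t),
                                 base = log_base)
}

#' Rank questionnaire options by improved TF-IDF
#'
#' Tallies, per option column, how many abnormal (`p_t`) and normal (`n_t`)
#' respondents selected it, computes the improved TF-IDF and the information
#' gain of each option, and returns the top `k` by decreasing importance
#' (ties broken by column order), along with the averages of both statistics
#' over all options.
#'
#' @param data A labeled [binary_dataset()] containing both classes.
#' @param k How many top options to return (clamped to the option count).
#' @param log_base Logarithm base for both statistics.
#' @return List with `ranking` (data frame: `option`, `p_t`, `n_t`,
#'   `imp_tfidf`, `info_gain`, top `k` rows), `all` (same for every option,
#'   sorted), `avg_imp_tfidf`, `avg_info_gain`, `N`, `N_p`.
#' @export
rank_options <- function(data, k = 10, log_base = 10) {
  stopifnot(inherits(data, "binary_dataset"))
  abn <- data$labels == "abnormal"
  if (!any(abn) || all(abn)) {
    stop("rank_options: both classes must be present", call. = FALSE)
  }
  N <- data$n_samples
  N_p <- sum(abn)
  p_t <- colSums(data$matrix[abn, , drop = FALSE])
  n_t <- colSums(data$matrix[!abn, , drop = FALSE])
  imp <- imp_tfidf(p_t, n_t, N_p, N, log_base)
  ig <- info_gain(p_t, n_t, N_p, N, log_base)
  ord <- order(-imp, seq_along(imp))
  all_df <- data.frame(option = data$feature_names[ord],
                       p_t = p_t[ord], n_t = n_t[ord],
                       imp_tfidf = imp[ord], info_gain = ig[ord],
                       row.names = NULL)
  k <- min(k, nrow(all_df))
  list(ranking = all_df[seq_len(k), , drop = FALSE],
       all = all_df,
       avg_imp_tfidf = mean(imp),
       avg_info_gain = mean(ig),
       N = N, N_p = N_p)
}
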