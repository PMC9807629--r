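#' Published per-option counts from an antenatal-depression survey
#'
#' Selection counts for the ten questionnaire options most associated with
#' the abnormal class in a published antenatal depression and anxiety survey
#' of 5666 pregnant women (407 screened abnormal): `p_t` abnormal and `n_t`
#' normal respondents selecting each option, with the class totals. These
#' counts are the desk-scale input for [imp_tfidf()] and [info_gain()] and
#' for the worked examples in the package documentation.
#'
#' @return Data frame with columns `rank`, `option`, `p_t`, `n_t`, `N_p`,
#'   `N`.
#' @examples
#' counts <- antenatal_top10_counts()
#' imp_tfidf(counts$p_t, counts$n_t, counts$N_p[1], counts$N[1])
#' @export
antenatal_top10_counts <- function() {
  utils::read.csv(system.file("extdata", "antenatal_top10_counts.csv",
                              package = "saesvdd"),
                  stringsAsFactors = FALSE)
}
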