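#' Derive an HRDsum classification cutoff from deficient samples
#'
#' The cutoff is the given percentile (default the fifth) of the HRDsum
#' scores of samples with known BRCA1/2 deficiencies, computed with linear
#' interpolation between order statistics and rounded to the nearest
#' integer. The unrounded percentile is attached as attribute
#' `"unrounded"` since the rounding convention behind the published integer
#' cutoff is not fully determined.
#'
#' @param scores Tibble `sample, summary_hrdsum` (or any score column named
#'   via `score_col`).
#' @param deficient_ids Character vector of deficient sample ids.
#' @param percentile Percentile in \[0, 100\] (default 5).
#' @param score_col Name of the score column (default `"summary_hrdsum"`).
#' @return Integer cutoff with attribute `"unrounded"`.
#' @export
derive_cutoff <- function(scores, deficient_ids, percentile = 5,
                          score_col = "summary_hrdsum") {
  x <- scores[[score_col]][scores$sample %in% deficient_ids]
  if (length(x) == 0)
    abort("no deficient samples found in the score table")
  q <- unname(quantile(x, percentile / 100, type = 7))
  structure(round(q), unrounded = q)
}

#' Classify samples by HRDsum score
#'
#' A sample is `"high"` (HRD) when its score is greater than or equal to
#' the cutoff (the published rule is inclusive), `"low"` otherwise.
#'
#' @param scores Tibble with a `sample` column and the score column.
#' @param cutoff Numeric cutoff (e.g. from [derive_cutoff()]).
#' @param score_col Name of the score column (default `"summary_hrdsum"`).
#' @return Input tibble with an added `hrdsum_class` column
#'   (`"high"`/`"low"`, `NA` where the score is missing).
#' @export
classify_hrdsum <- function(scores, cutoff, score_col = "summary_hrdsum") {
  if (!is.finite(cutoff)) abort("cutoff must be finite")
  scores %>%
    mutate(hrdsum_class = dplyr::if_else(.data[[score_col]] >= cutoff,
                                         "high", "low"))
}

#' Classify samples by CHORD HRD probability
#'
#' MSI samples are excluded from CHORD classification (their abundance of
#' repeat-region indels dominates the mutation-context signal); otherwise a
#' sample is `"HRD"` when its HRD probability is strictly greater than 0.4
#' and `"HRP"` (HR-proficient) when it is at most 0.4.
#'
#' @param probs Tibble with columns `sample`, `chord_p` (probability in
#'   \[0, 1\]) and logical `msi`.
#' @param cutoff Probability cutoff (default 0.4, strict `>`).
#' @return Input tibble with an added `chord_class` column
#'   (`"HRD"`, `"HRP"`, `"MSI-excluded"`).
#' @export
classify_chord <- function(probs, cutoff = 0.4) {
  if (any(probs$chord_p < 0 | probs$chord_p > 1, na.rm = TRUE))
    abort("chord_p must lie in [0, 1]")
  probs %>%
    mutate(chord_class = case_when(
      .data$msi ~ "MSI-excluded",
      .data$chord_p > cutoff ~ "HRD",
      .data$chord_p <= cutoff ~ "HRP"
    ))
}
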