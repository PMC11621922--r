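#' Build a feature table with central sample exclusions
#'
#' Wraps a samples-by-features tibble together with the sample metadata
#' flags that drive the analysis-wide exclusion rule: noncancerous and MSI
#' cell lines are excluded from all association and enrichment scans.
#'
#' @param features Tibble with a `sample` column and numeric/logical
#'   feature columns.
#' @param metadata Tibble `sample, noncancerous, msi` (and optionally
#'   `tissue`); samples missing from `metadata` are treated as cancerous
#'   and microsatellite-stable.
#' @return The features of the retained (non-excluded) samples, with
#'   metadata columns joined.
#' @export
feature_table <- function(features, metadata = NULL) {
  out <- as_tibble(features)
  if (!is.null(metadata)) {
    out <- out %>%
      left_join(as_tibble(metadata), by = "sample") %>%
      mutate(noncancerous = dplyr::coalesce(.data$noncancerous, FALSE),
             msi = dplyr::coalesce(.data$msi, FALSE)) %>%
      filter(!.data$noncancerous, !.data$msi)
  }
  out
}

#' One-tailed Fisher enrichment of gene deficiencies among HRD samples
#'
#' For each gene deficient in at least one HRD-classified sample (the
#' inclusion rule), tests enrichment of deficiency among HRD samples with a
#' one-tailed (greater) Fisher exact test on the 2x2 table of deficiency
#' status versus HRD label, then adjusts p-values across the included genes
#' with Benjamini-Hochberg.
#'
#' @param deficiency Tibble `sample, gene, deficient` (logical), or a
#'   logical genes-x-samples matrix with dimnames.
#' @param hrd_labels Tibble `sample, hrd` (logical), aligned by sample id.
#' @return Tibble `gene, n_def_hrd, n_def_hrp, n_prof_hrd, n_prof_hrp,
#'   odds_ratio, p_one_tailed, q_bh` sorted by p.
#' @export
fisher_enrichment <- function(deficiency, hrd_labels) {
  if (is.matrix(deficiency)) {
    deficiency <- as_tibble(as.data.frame.table(deficiency,
                                                stringsAsFactors = FALSE)) %>%
      rename(gene = "Var1", sample = "Var2", deficient = "Freq")
  }
  dat <- inner_join(deficiency, hrd_labels, by = "sample")
  res <- dat %>%
    group_by(.data$gene) %>%
    summarise(
      n_def_hrd = sum(.data$deficient & .data$hrd),
      n_def_hrp = sum(.data$deficient & !.data$hrd),
      n_prof_hrd = sum(!.data$deficient & .data$hrd),
      n_prof_hrp = sum(!.data$deficient & !.data$hrd),
      .groups = "drop") %>%
    filter(.data$n_def_hrd >= 1)
  if (nrow(res) == 0)
    abort("no genes are deficient in at least one HRD sample")
  tests <- purrr::pmap_dfr(
    res[c("n_def_hrd", "n_def_hrp", "n_prof_hrd", "n_prof_hrp")],
    function(n_def_hrd, n_def_hrp, n_prof_hrd, n_prof_hrp) {
      m <- matrix(c(n_def_hrd, n_def_hrp, n_prof_hrd, n_prof_hrp),
                  nrow = 2, byrow = TRUE)
      ft <- fisher.test(m, alternative = "greater")
      tibble(odds_ratio = unname(ft$estimate), p_one_tailed = ft$p.value)
    })
  res %>%
    dplyr::bind_cols(tests) %>%
    mutate(q_bh = bh_adjust(.data$p_one_tailed)) %>%
    arrange(.data$p_one_tailed)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values (monotone in the sorted order, capped at 1).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (`NA` passed
#'   through).
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Pearson correlation scan of a score against every feature
#'
#' Computes the Pearson correlation (and its two-sided t-test p-value on
#' n-2 degrees of freedom) between a per-sample score and every numeric
#' feature column, on pairwise-complete samples per feature. Constant
#' features (zero variance) are reported with `NA` statistics and excluded
#' from the BH adjustment.
#'
#' @param scores Tibble `sample, score` (name the score column via
#'   `score_col`).
#' @param features Feature tibble with a `sample` column (pre-filtered via
#'   [feature_table()] so exclusions are applied centrally).
#' @param score_col Name of the score column (default `"summary_hrdsum"`).
#' @param min_n Minimum paired observations per feature (default 3).
#' @return Tibble `feature, r, p, q_bh, n_used` sorted by p.
#' @export
correlate_scan <- function(scores, features,
                           score_col = "summary_hrdsum", min_n = 3) {
  dat <- inner_join(scores, features, by = "sample")
  s <- dat[[score_col]]
  feat_cols <- setdiff(names(features), c("sample", "noncancerous", "msi",
                                          "tissue"))
  feat_cols <- feat_cols[purrr::map_lgl(dat[feat_cols], is.numeric)]
  res <- purrr::map_dfr(feat_cols, function(f) {
    x <- dat[[f]]
    ok <- !is.na(x) & !is.na(s)
    n <- sum(ok)
    if (n < min_n || sd(x[ok]) == 0 || sd(s[ok]) == 0)
      return(tibble(feature = f, r = NA_real_, p = NA_real_, n_used = n))
    ct <- cor.test(s[ok], x[ok], method = "pearson")
    tibble(feature = f, r = unname(ct$estimate), p = ct$p.value, n_used = n)
  })
  res$q_bh <- NA_real_
  testable <- !is.na(res$p)
  res$q_bh[testable] <- bh_adjust(res$p[testable])
  arrange(select(res, "feature", "r", "p", "q_bh", "n_used"), .data$p)
}

#' Quartile-binned Kruskal-Wallis association
#'
#' Bins samples into quartiles of the score (interpolated breaks; samples
#' exactly at a break go to the lower bin) and tests for differences in
#' the response across bins with a Kruskal-Wallis test (ties-corrected H,
#' chi-square p on number-of-groups minus 1 df). Degenerate breaks collapse
#' bins.
#'
#' @param scores Numeric score vector.
#' @param response Numeric response vector, aligned with `scores`
#'   (`NA` pairs dropped).
#' @param n_bins Number of score bins (default 4).
#' @return Tibble `statistic, p, df, n_used, n_bins`.
#' @export
quartile_kruskal <- function(scores, response, n_bins = 4) {
  ok <- !is.na(scores) & !is.na(response)
  scores <- scores[ok]; response <- response[ok]
  if (dplyr::n_distinct(scores) < n_bins)
    abort("need at least as many distinct score values as bins")
  breaks <- unique(quantile(scores, probs = seq(0, 1, length.out = n_bins + 1),
                            type = 7))
  # right-closed intervals: values exactly at a break fall in the lower bin
  bin <- cut(scores, breaks = breaks, include.lowest = TRUE, right = TRUE)
  bin <- droplevels(bin)
  if (nlevels(bin) < 2)
    abort("fewer than 2 non-empty score bins")
  if (dplyr::n_distinct(response) == 1) {
    # constant response: equal ranks everywhere, H = 0 by definition (the
    # ties-corrected formula is 0/0 here)
    return(tibble(statistic = 0, p = 1, df = nlevels(bin) - 1L,
                  n_used = length(response), n_bins = nlevels(bin)))
  }
  kt <- kruskal.test(response, bin)
  tibble(statistic = unname(kt$statistic), p = kt$p.value,
         df = unname(kt$parameter), n_used = length(response),
         n_bins = nlevels(bin))
}

#' CRISPR screen gene scores from guide counts
#'
#' Per replicate, the guide-level log2 fold change of endpoint over initial
#' counts (each plus a pseudocount of 1) is computed and centered by the
#' replicate's median log fold change; centered values are averaged across
#' replicates per guide, and the gene score is the median of its guides.
#'
#' @param counts_initial,counts_endpoint Integer matrices
#'   (guides x replicates) with matching dimensions and guide rownames.
#' @param guide_to_gene Named character vector mapping guide id to gene.
#' @param pseudocount Added to all counts before the ratio (default 1).
#' @return Tibble `gene, score, n_guides` sorted by gene.
#' @export
crispr_gene_scores <- function(counts_initial, counts_endpoint,
                               guide_to_gene, pseudocount = 1) {
  if (!all(dim(counts_initial) == dim(counts_endpoint)))
    abort("count matrices must have identical dimensions")
  if (any(counts_initial < 0) || any(counts_endpoint < 0))
    abort("counts must be non-negative")
  guides <- rownames(counts_initial)
  if (is.null(guides)) guides <- as.character(seq_len(nrow(counts_initial)))
  miss <- setdiff(guides, names(guide_to_gene))
  if (length(miss) > 0)
    abort(paste0("guides missing from guide_to_gene mapping: ",
                 paste(utils::head(miss, 5), collapse = ", ")))
  lfc <- log2((counts_endpoint + pseudocount) /
                (counts_initial + pseudocount))
  centered <- sweep(lfc, 2, apply(lfc, 2, median), "-")
  guide_score <- rowMeans(centered)
  tibble(guide = guides, gene = unname(guide_to_gene[guides]),
         guide_score = guide_score) %>%
    group_by(.data$gene) %>%
    summarise(score = median(.data$guide_score), n_guides = n(),
              .groups = "drop") %>%
    arrange(.data$gene)
}
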