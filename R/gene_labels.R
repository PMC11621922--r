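#' Lower-quartile expression threshold
#'
#' The 25th percentile of an expression vector (log2(TPM+1) scale), under
#' the same linear-interpolation convention as [derive_cutoff()]. Used as
#' the "expressed above the lower quartile" threshold in proficiency and
#' silencing calls.
#'
#' @param expression Numeric vector with at least 4 values.
#' @return The interpolated 25th percentile.
#' @export
expression_lower_quartile <- function(expression) {
  expression <- expression[!is.na(expression)]
  if (length(expression) < 4)
    abort("need at least 4 expression values for a lower quartile")
  unname(quantile(expression, 0.25, type = 7))
}

clinvar_pathogenic <- function(sig) {
  s <- tolower(ifelse(is.na(sig), "", sig))
  stringr::str_detect(s, "pathogenic") &
    !stringr::str_detect(s, "conflicting") &
    !stringr::str_detect(s, "benign")
}

#' Gene deficiency call for one sample/gene
#'
#' A gene is deficient when it carries a homozygous mutation (allele
#' frequency strictly above 0.85) annotated as pathogenic by ClinVar and/or
#' predicted to have HIGH impact, or when it contains a deep (homozygous)
#' deletion.
#'
#' @param mutations Tibble of mutation records for one sample/gene with
#'   columns `allele_frequency`, `clinvar_significance`, `impact`
#'   (zero rows allowed).
#' @param deep_deletion Logical flag.
#' @param af_homozygous Homozygosity threshold on allele frequency
#'   (default 0.85, strict `>`).
#' @return Logical.
#' @export
label_deficient <- function(mutations, deep_deletion,
                            af_homozygous = 0.85) {
  if (isTRUE(deep_deletion)) return(TRUE)
  if (nrow(mutations) == 0) return(FALSE)
  damaging <- clinvar_pathogenic(mutations$clinvar_significance) |
    (!is.na(mutations$impact) & mutations$impact == "HIGH")
  any(mutations$allele_frequency > af_homozygous & damaging)
}

#' Gene proficiency call for one sample/gene
#'
#' Proficient means: no mutations at all in the provided mutation table
#' (the rule is unqualified, so silent variants also disqualify), no deep
#' deletion, and expression strictly above the lower-quartile threshold.
#'
#' @inheritParams label_deficient
#' @param expression log2(TPM+1) expression of the gene in the sample.
#' @param expr_lower_quartile Expression threshold (strict `>`); e.g. 3.8
#'   for BRCA1 and 2.07 for BRCA2 on the CCLE scale.
#' @return Logical.
#' @export
label_proficient <- function(mutations, deep_deletion, expression,
                             expr_lower_quartile) {
  nrow(mutations) == 0 && !isTRUE(deep_deletion) &&
    !is.na(expression) && expression > expr_lower_quartile
}

#' Likely epigenetic silencing call
#'
#' Flags likely promoter-methylation silencing: expression strictly below
#' the lower-quartile threshold combined with promoter methylation fraction
#' strictly above 0.3.
#'
#' @param expression log2(TPM+1) expression value.
#' @param expr_lower_quartile Expression threshold (strict `<`).
#' @param methylation Promoter methylation fraction in \[0, 1\].
#' @param meth_cutoff Methylation threshold (default 0.3, strict `>`).
#' @return Logical (`NA` if methylation is missing).
#' @export
label_silenced <- function(expression, expr_lower_quartile, methylation,
                           meth_cutoff = 0.3) {
  if (is.na(methylation)) return(NA)
  !is.na(expression) && expression < expr_lower_quartile &&
    methylation > meth_cutoff
}

#' Label gene states across samples
#'
#' Combines the deficiency, silencing and proficiency rules into one label
#' per sample/gene: `deficient` takes precedence, then `silenced-likely`
#' (requires methylation data), then `proficient`; anything else is
#' `indeterminate`. Manual literature overrides (e.g. a known revertant)
#' are applied last.
#'
#' @param mutations Tibble `sample, gene, allele_frequency,
#'   clinvar_significance, impact`.
#' @param cn_categories Tibble `sample, gene, deep_deletion` (logical).
#' @param expression Tibble `sample, gene, expression` (log2(TPM+1)).
#' @param methylation Optional tibble `sample, gene, methylation` (promoter
#'   methylation fraction).
#' @param expr_quartiles Named numeric vector of per-gene lower-quartile
#'   thresholds; genes not named are given the quartile of their own
#'   expression column via [expression_lower_quartile()].
#' @param overrides Optional tibble `sample, gene, label` applied verbatim
#'   after rule evaluation, or a path to a YAML file with entries
#'   `sample`, `gene`, `label`.
#' @return Tibble `sample, gene, deficient, proficient, silenced, label`.
#' @export
label_gene_states <- function(mutations, cn_categories, expression,
                              methylation = NULL, expr_quartiles = NULL,
                              overrides = NULL) {
  base <- expression %>% select("sample", "gene", "expression")
  genes <- unique(base$gene)
  quart <- purrr::map_dbl(setNames(genes, genes), function(g) {
    if (!is.null(expr_quartiles) && g %in% names(expr_quartiles))
      expr_quartiles[[g]]
    else expression_lower_quartile(base$expression[base$gene == g])
  })
  cn <- cn_categories %>% select("sample", "gene", "deep_deletion")
  base <- base %>%
    left_join(cn, by = c("sample", "gene")) %>%
    mutate(deep_deletion = dplyr::coalesce(.data$deep_deletion, FALSE))
  if (!is.null(methylation)) {
    base <- base %>%
      left_join(select(methylation, "sample", "gene", "methylation"),
                by = c("sample", "gene"))
  } else {
    base$methylation <- NA_real_
  }
  out <- base %>%
    mutate(q = quart[.data$gene]) %>%
    purrr::pmap_dfr(function(sample, gene, expression, deep_deletion,
                             methylation, q) {
      mut <- mutations[mutations$sample == sample & mutations$gene == gene, ]
      def <- label_deficient(mut, deep_deletion)
      sil <- isTRUE(label_silenced(expression, q, methylation))
      prof <- label_proficient(mut, deep_deletion, expression, q)
      tibble(sample = sample, gene = gene, deficient = def,
             proficient = prof, silenced = sil,
             label = case_when(def ~ "deficient",
                               sil ~ "silenced-likely",
                               prof ~ "proficient",
                               TRUE ~ "indeterminate"))
    })
  if (!is.null(overrides)) {
    if (is.character(overrides))
      overrides <- bind_rows(lapply(yaml::read_yaml(overrides), as_tibble))
    for (i in seq_len(nrow(overrides))) {
      hit <- out$sample == overrides$sample[i] & out$gene == overrides$gene[i]
      out$label[hit] <- overrides$label[i]
    }
  }
  out
}
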