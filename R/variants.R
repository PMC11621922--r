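#' Tumor-only small-variant filter cascade
#'
#' Retains exactly the records that pass all six post-calling filters used
#' to select high-quality, likely-somatic variants from tumor-only calls:
#' not flagged by a panel of normals; no hits in the germline/artifact
#' blacklists (gnomAD, dbSNP, known indels); seen in at most two cell lines
#' of the cohort; caller `filter_status == "PASS"`; allele frequency at
#' least 0.1 (inclusive); and quality at least 240 in low-confidence
#' regions or 170 in high-confidence regions (records with unknown
#' confidence use the stricter 240 cutoff). The filter is total (no errors)
#' and order-independent: rules are pure per-record predicates plus a
#' cohort-recurrence count on normalized `(chrom, pos, ref, alt)` keys.
#'
#' @param records Tibble with columns `sample, chrom, pos, ref, alt, qual,
#'   filter_status, allele_frequency, pon_flag, confidence_region,
#'   blacklist_hits` (`blacklist_hits` a list-column of character vectors
#'   or a character column with comma-separated hits; empty/`NA` = clean;
#'   `confidence_region` in `"high"`, `"low"` or `NA`). Records should be
#'   normalized first (see [normalize_variants()]).
#' @param cohort_recurrence Optional named integer vector mapping
#'   `chrom:pos:ref:alt` keys to the number of cell lines carrying the
#'   variant; if `NULL`, recurrence is computed from `records` itself
#'   (distinct samples per key).
#' @param min_af Allele-frequency cutoff (default 0.1, inclusive).
#' @param max_recurrence Maximum number of cell lines a variant may appear
#'   in (default 2; "three or more" are removed).
#' @param qual_low,qual_high Quality cutoffs for low-/high-confidence
#'   regions (defaults 240 and 170, inclusive).
#' @return The retained records, with a `variant_key` column added.
#' @export
filter_small_variants <- function(records, cohort_recurrence = NULL,
                                  min_af = 0.1, max_recurrence = 2,
                                  qual_low = 240, qual_high = 170) {
  if (nrow(records) == 0) return(mutate(records, variant_key = character(0)))
  records <- mutate(records,
                    variant_key = variant_key(.data$chrom, .data$pos,
                                              .data$ref, .data$alt))
  if (is.null(cohort_recurrence)) {
    rec <- records %>%
      distinct(.data$sample, .data$variant_key) %>%
      count(.data$variant_key)
    cohort_recurrence <- setNames(rec$n, rec$variant_key)
  }
  recur <- unname(cohort_recurrence[records$variant_key])
  recur[is.na(recur)] <- 0L
  clean_bl <- blacklist_empty(records$blacklist_hits)
  qual_cut <- dplyr::if_else(!is.na(records$confidence_region) &
                               records$confidence_region == "high",
                             qual_high, qual_low)
  keep <- !records$pon_flag &
    clean_bl &
    recur <= max_recurrence &
    records$filter_status == "PASS" &
    records$allele_frequency >= min_af &
    records$qual >= qual_cut
  records[keep & !is.na(keep), ]
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

blacklist_empty <- function(bl) {
  if (is.list(bl)) {
    purrr::map_lgl(bl, ~length(.x) == 0 || all(is.na(.x) | .x == ""))
  } else {
    is.na(bl) | bl == ""
  }
}

#' Normalize small-variant records
#'
#' Applies the standard representation normalizations applied before
#' filtering and context extraction: multiallelic records are split into
#' one alt per record, multi-nucleotide variants (MNVs) are split into
#' their constituent SNVs, and indels are parsimony-trimmed and
#' left-aligned against the reference. Normalization is idempotent.
#'
#' @param records Variant tibble (`chrom, pos, ref, alt` plus any other
#'   columns, which are carried through; `alt` may contain comma-separated
#'   alleles).
#' @param reference Named character vector (or list) of chromosome
#'   sequences covering the record loci.
#' @return Normalized records, re-sorted by `(sample, chrom, pos)` when a
#'   `sample` column is present.
#' @export
normalize_variants <- function(records, reference) {
  if (nrow(records) == 0) return(records)
  records <- records %>%
    mutate(alt = strsplit(as.character(.data$alt), ",", fixed = TRUE)) %>%
    tidyr::unnest("alt")
  out <- purrr::pmap_dfr(
    list(seq_len(nrow(records))),
    function(i) {
      row <- records[i, ]
      refseq <- reference[[row$chrom]]
      if (is.null(refseq))
        abort(paste0("no reference sequence for ", row$chrom))
      obs <- toupper(substr(refseq, row$pos, row$pos + nchar(row$ref) - 1))
      if (obs != toupper(row$ref))
        abort(paste0("reference mismatch at ", row$chrom, ":", row$pos,
                     " (expected ", row$ref, ", reference has ", obs, ")"))
      norm_one_variant(row, refseq)
    })
  if ("sample" %in% names(out))
    out <- arrange(out, .data$sample, .data$chrom, .data$pos)
  else out <- arrange(out, .data$chrom, .data$pos)
  out
}

# Normalize a single (already biallelic) record against its chromosome
# sequence; may emit several rows (MNV split).
norm_one_variant <- function(row, refseq) {
  ref <- toupper(row$ref); alt <- toupper(row$alt); pos <- row$pos
  # trim shared suffix/prefix (parsimony)
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  if (nchar(ref) == nchar(alt) && nchar(ref) > 1) {
    # MNV: one SNV per differing base
    out <- list()
    for (k in seq_len(nchar(ref))) {
      rb <- substr(ref, k, k); ab <- substr(alt, k, k)
      if (rb != ab) {
        r2 <- row; r2$pos <- pos + k - 1; r2$ref <- rb; r2$alt <- ab
        out[[length(out) + 1]] <- r2
      }
    }
    return(bind_rows(out))
  }
  if (nchar(ref) != nchar(alt)) {
    # indel: ensure anchor-base form, then left-align
    shifted <- left_align_indel(pos, ref, alt, refseq)
    row$pos <- shifted$pos; row$ref <- shifted$ref; row$alt <- shifted$alt
  } else {
    row$pos <- pos; row$ref <- ref; row$alt <- alt
  }
  row
}

# Left-align an indel (VCF anchor convention, 1-based pos) by shifting to
# the 5'-most equivalent representation.
left_align_indel <- function(pos, ref, alt, refseq) {
  # ensure both alleles share a leading anchor base
  if (substr(ref, 1, 1) != substr(alt, 1, 1) || nchar(ref) == 0 ||
      nchar(alt) == 0) {
    if (pos > 1) {
      anchor <- toupper(substr(refseq, pos - 1, pos - 1))
      pos <- pos - 1
      ref <- paste0(anchor, ref); alt <- paste0(anchor, alt)
    }
  }
  repeat {
    last_ref <- substr(ref, nchar(ref), nchar(ref))
    last_alt <- substr(alt, nchar(alt), nchar(alt))
    if (last_ref == last_alt && pos > 1) {
      prev <- toupper(substr(refseq, pos - 1, pos - 1))
      pos2 <- pos - 1
      ref2 <- paste0(prev, substr(ref, 1, nchar(ref) - 1))
      alt2 <- paste0(prev, substr(alt, 1, nchar(alt) - 1))
      # shifting is valid only if the new ref still matches the reference
      if (toupper(substr(refseq, pos2, pos2 + nchar(ref2) - 1)) == ref2) {
        pos <- pos2; ref <- ref2; alt <- alt2
        next
      }
    }
    break
  }
  # re-trim any shared suffix created by the shift
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Structural-variant (breakend-pair) filter
#'
#' Retains breakend pairs with quality at least 1,000 (inclusive),
#' assembly support from both sides of the breakpoint (`AS > 0` and
#' `RAS > 0`), no panel-of-normals flag, cohort recurrence of at most two
#' cell lines, caller `filter_status == "PASS"`, and allele frequency at
#' least 0.1.
#'
#' @param pairs Tibble with columns `sample, chrom1, pos1, orient1, chrom2,
#'   pos2, orient2, qual, filter_status, allele_frequency, pon_flag, AS,
#'   RAS`.
#' @param cohort_recurrence Optional named integer vector keyed by
#'   `chrom1:pos1:chrom2:pos2`; computed from `pairs` when `NULL`.
#' @param min_qual Quality cutoff (default 1000, inclusive).
#' @param min_af Allele-frequency cutoff (default 0.1, inclusive).
#' @param max_recurrence Maximum cohort recurrence (default 2).
#' @return Retained pairs.
#' @export
filter_structural_variants <- function(pairs, cohort_recurrence = NULL,
                                       min_qual = 1000, min_af = 0.1,
                                       max_recurrence = 2) {
  if (nrow(pairs) == 0) return(pairs)
  key <- paste(pairs$chrom1, pairs$pos1, pairs$chrom2, pairs$pos2, sep = ":")
  if (is.null(cohort_recurrence)) {
    rec <- tibble(sample = pairs$sample, key = key) %>%
      distinct() %>% count(.data$key)
    cohort_recurrence <- setNames(rec$n, rec$key)
  }
  recur <- unname(cohort_recurrence[key])
  recur[is.na(recur)] <- 0L
  keep <- pairs$qual >= min_qual &
    pairs$AS > 0 & pairs$RAS > 0 &
    !pairs$pon_flag &
    recur <= max_recurrence &
    pairs$filter_status == "PASS" &
    pairs$allele_frequency >= min_af
  pairs[keep & !is.na(keep), ]
}

#' Annotate breakend pairs as simple structural-variant events
#'
#' Classifies each breakend pair into the simple-event truth table:
#' different chromosomes give a translocation (`TRA`, length `NA`); on one
#' chromosome, after canonical ordering (`pos1 <= pos2`, orientations
#' travelling with their breakends), orientations `(+,-)` give a deletion,
#' `(-,+)` a duplication, and `(+,+)` or `(-,-)` an inversion, with
#' `length = pos2 - pos1`.
#'
#' @param pairs Breakend-pair tibble (see [filter_structural_variants()]).
#' @return Input tibble with added `sv_type` and `sv_length` columns.
#' @export
annotate_sv_events <- function(pairs) {
  if (nrow(pairs) == 0)
    return(mutate(pairs, sv_type = character(0), sv_length = numeric(0)))
  same <- pairs$chrom1 == pairs$chrom2
  if (any(same & pairs$pos1 == pairs$pos2))
    abort("breakend pair with pos1 == pos2 on the same chromosome")
  swap <- same & pairs$pos1 > pairs$pos2
  p1 <- ifelse(swap, pairs$pos2, pairs$pos1)
  p2 <- ifelse(swap, pairs$pos1, pairs$pos2)
  o1 <- ifelse(swap, pairs$orient2, pairs$orient1)
  o2 <- ifelse(swap, pairs$orient1, pairs$orient2)
  type <- dplyr::case_when(
    !same ~ "TRA",
    o1 == "+" & o2 == "-" ~ "DEL",
    o1 == "-" & o2 == "+" ~ "DUP",
    TRUE ~ "INV"
  )
  len <- ifelse(same, p2 - p1, NA_real_)
  mutate(pairs, sv_type = type, sv_length = len)
}

#' Classify indel context: microhomology, repeat, or none
#'
#' For a deletion (or insertion), the changed sequence is examined against
#' the reference flank 3' of the event site. The indel is in a repeat
#' context (`"rep"`) when the changed sequence is a whole number of tandem
#' copies of a unit that continues immediately 3' in the reference (so the
#' locus carries at least two tandem copies in total); otherwise it is a
#' microhomology context (`"mh"`) when at least `min_homology` bases of the
#' changed sequence's 5' end match the reference immediately 3' of the
#' event; otherwise `"none"`. The homology or repeat-unit length is
#' reported.
#'
#' @param records Normalized indel records (`chrom, pos, ref, alt`, VCF
#'   anchor convention).
#' @param reference Named character vector of chromosome sequences.
#' @param min_homology Minimum microhomology length in bp (default 2).
#' @param min_repeat_units Minimum total tandem copies for a repeat call
#'   (default 2).
#' @param flank Number of reference bases examined 3' of the event
#'   (default 100).
#' @return Input tibble with `indel_type` (`"del"`/`"ins"`),
#'   `indel_context` (`"mh"`, `"rep"`, `"none"`) and `context_len` columns.
#' @export
classify_indel_context <- function(records, reference, min_homology = 2,
                                   min_repeat_units = 2, flank = 100) {
  if (nrow(records) == 0)
    return(mutate(records, indel_type = character(0),
                  indel_context = character(0), context_len = integer(0)))
  res <- purrr::pmap_dfr(
    list(records$chrom, records$pos, records$ref, records$alt),
    function(chrom, pos, ref, alt) {
      ref <- toupper(ref); alt <- toupper(alt)
      if (nchar(ref) == nchar(alt))
        abort("classify_indel_context called on a non-indel record")
      is_del <- nchar(ref) > nchar(alt)
      seq_chg <- if (is_del) substr(ref, 2, nchar(ref))
                 else substr(alt, 2, nchar(alt))
      refseq <- reference[[chrom]]
      # position immediately 3' of the REF allele span
      after <- pos + nchar(ref)
      flank3 <- toupper(substr(refseq, after,
                               min(nchar(refseq), after + flank - 1)))
      rep_unit <- repeat_unit_with_flank(seq_chg, flank3, min_repeat_units)
      if (!is.na(rep_unit)) {
        ctx <- "rep"; clen <- rep_unit
      } else {
        hom <- homology_length(seq_chg, flank3)
        if (hom >= min_homology) { ctx <- "mh"; clen <- hom }
        else { ctx <- "none"; clen <- 0L }
      }
      tibble(indel_type = if (is_del) "del" else "ins",
             indel_context = ctx, context_len = as.integer(clen))
    })
  dplyr::bind_cols(records, res)
}

# Length of the repeat unit if `seq_chg` is k >= 1 tandem copies of a unit
# that continues immediately in `flank3`, with total copies (within the
# indel plus adjacent in the reference) >= min_units; NA otherwise.
repeat_unit_with_flank <- function(seq_chg, flank3, min_units = 2) {
  n <- nchar(seq_chg)
  for (u in seq_len(n)) {
    if (n %% u != 0) next
    unit <- substr(seq_chg, 1, u)
    k <- n / u
    if (paste(rep(unit, k), collapse = "") != seq_chg) next
    # adjacent copies in the reference flank
    adj <- 0
    while (substr(flank3, adj * u + 1, (adj + 1) * u) == unit) adj <- adj + 1
    if (adj >= 1 && k + adj >= min_units) return(u)
  }
  NA_integer_
}

# Number of leading bases of seq_chg matching the reference immediately 3'
# of the event (partial-copy homology; full-copy matches are repeats).
homology_length <- function(seq_chg, flank3) {
  n <- min(nchar(seq_chg), nchar(flank3))
  h <- 0
  while (h < n && substr(seq_chg, h + 1, h + 1) == substr(flank3, h + 1, h + 1))
    h <- h + 1
  h
}

#' SNV trinucleotide context (96 classes)
#'
#' Assigns each SNV its pyrimidine-strand-normalized trinucleotide class
#' `X[R>A]Y`: substitutions from a purine reference base are
#' reverse-complemented so all classes have a C or T reference. SNVs whose
#' flank contains `N` get class `NA` and are excluded from counts.
#'
#' @param records Normalized SNV records (`chrom, pos, ref, alt`).
#' @param reference Named character vector of chromosome sequences.
#' @return Input tibble with an `snv_context` column.
#' @export
snv_trinucleotide_context <- function(records, reference) {
  if (nrow(records) == 0)
    return(mutate(records, snv_context = character(0)))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ctx <- purrr::pmap_chr(
    list(records$chrom, records$pos, records$ref, records$alt),
    function(chrom, pos, ref, alt) {
      ref <- toupper(ref); alt <- toupper(alt)
      if (nchar(ref) != 1 || nchar(alt) != 1) return(NA_character_)
      refseq <- reference[[chrom]]
      if (pos < 2 || pos >= nchar(refseq)) return(NA_character_)
      tri <- toupper(substr(refseq, pos - 1, pos + 1))
      if (grepl("N", tri)) return(NA_character_)
      l <- substr(tri, 1, 1); r <- substr(tri, 3, 3)
      if (ref %in% c("A", "G")) {
        ref2 <- comp[[ref]]; alt2 <- comp[[alt]]
        l2 <- comp[[r]]; r2 <- comp[[l]]
        paste0(l2, "[", ref2, ">", alt2, "]", r2)
      } else {
        paste0(l, "[", ref, ">", alt, "]", r)
      }
    })
  mutate(records, snv_context = ctx)
}

#' Count mutation contexts per sample
#'
#' Tallies classified SNV trinucleotide contexts, indel contexts
#' (`del.mh`, `del.rep`, `del.none`, `ins.mh`, `ins.rep`, `ins.none`) and
#' structural-variant type/length-bin categories into one long count table
#' per sample.
#'
#' @param snvs Output of [snv_trinucleotide_context()] (may be empty).
#' @param indels Output of [classify_indel_context()] (may be empty).
#' @param svs Output of [annotate_sv_events()] (may be empty).
#' @param sv_breaks Length-bin breaks in bp for intrachromosomal SV types.
#' @return Tibble `sample, category, count`.
#' @export
count_contexts <- function(snvs = NULL, indels = NULL, svs = NULL,
                           sv_breaks = c(0, 1e3, 1e4, 1e5, 1e6, 1e7, Inf)) {
  parts <- list()
  if (!is.null(snvs) && nrow(snvs) > 0) {
    parts$snv <- snvs %>%
      filter(!is.na(.data$snv_context)) %>%
      count(.data$sample, category = .data$snv_context, name = "count")
  }
  if (!is.null(indels) && nrow(indels) > 0) {
    parts$indel <- indels %>%
      count(.data$sample,
            category = paste0(.data$indel_type, ".", .data$indel_context),
            name = "count")
  }
  if (!is.null(svs) && nrow(svs) > 0) {
    svs2 <- svs %>%
      mutate(bin = dplyr::if_else(
        .data$sv_type == "TRA", "",
        paste0("_", as.character(cut(.data$sv_length, sv_breaks,
                                     dig.lab = 10)))))
    parts$sv <- svs2 %>%
      count(.data$sample, category = paste0(.data$sv_type, .data$bin),
            name = "count")
  }
  out <- bind_rows(parts)
  if (nrow(out) == 0)
    return(tibble(sample = character(0), category = character(0),
                  count = integer(0)))
  arrange(out, .data$sample, .data$category)
}

#' Microsatellite-instability call from repeat-region indel counts
#'
#' A sample is MSI when its count of indels in repeat regions reaches the
#' minimum threshold (default 10,000, the cell-line calibration of the
#' `min.msi.indel.rep` parameter; inclusive `>=`).
#'
#' @param indels_in_repeat_regions Non-negative integer count (vectorized).
#' @param threshold Minimum count for an MSI call (default 10000).
#' @param inclusive Use `>=` (default) rather than strict `>`.
#' @return Logical: `TRUE` = MSI, `FALSE` = microsatellite-stable.
#' @export
classify_msi <- function(indels_in_repeat_regions, threshold = 10000,
                         inclusive = TRUE) {
  if (any(indels_in_repeat_regions < 0))
    abort("indel counts must be non-negative")
  if (inclusive) indels_in_repeat_regions >= threshold
  else indels_in_repeat_regions > threshold
}
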