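clean_var <- function(pos, ref = "A", alt = "T", sample = "CL1", ...) {
  tibble::tibble(sample = sample, chrom = "chr1", pos = pos, ref = ref,
                 alt = alt, qual = 300, filter_status = "PASS",
                 allele_frequency = 0.5, pon_flag = FALSE,
                 confidence_region = "high", blacklist_hits = "") %>%
    dplyr::mutate(...)
}

test_that("small-variant filter applies each rule at its printed boundary", {
  expect_equal(nrow(filter_small_variants(clean_var(numeric(0))[0, ])), 0)

  # AF boundary: 0.1 retained (inclusive), below removed
  expect_equal(nrow(filter_small_variants(
    clean_var(10, allele_frequency = 0.1))), 1)
  expect_equal(nrow(filter_small_variants(
    clean_var(10, allele_frequency = 0.0999))), 0)

  # qual by confidence region: high >= 170, low >= 240, NA -> stricter
  expect_equal(nrow(filter_small_variants(clean_var(10, qual = 170))), 1)
  expect_equal(nrow(filter_small_variants(clean_var(10, qual = 169))), 0)
  expect_equal(nrow(filter_small_variants(
    clean_var(10, qual = 240, confidence_region = "low"))), 1)
  expect_equal(nrow(filter_small_variants(
    clean_var(10, qual = 239, confidence_region = "low"))), 0)
  expect_equal(nrow(filter_small_variants(
    clean_var(10, qual = 200, confidence_region = NA_character_))), 0)

  # PON, blacklist, FILTER
  expect_equal(nrow(filter_small_variants(clean_var(10, pon_flag = TRUE))), 0)
  expect_equal(nrow(filter_small_variants(
    clean_var(10, blacklist_hits = "dbsnp"))), 0)
  expect_equal(nrow(filter_small_variants(
    clean_var(10, filter_status = "germline"))), 0)

  # recurrence: present in 3 cell lines -> removed everywhere
  tri <- dplyr::bind_rows(clean_var(10), clean_var(10, sample = "CL2"),
                          clean_var(10, sample = "CL3"), clean_var(99))
  kept <- filter_small_variants(tri)
  expect_equal(kept$pos, 99)
  duo <- dplyr::bind_rows(clean_var(10), clean_var(10, sample = "CL2"))
  expect_equal(nrow(filter_small_variants(duo)), 2)
})

test_that("filter cascade retains exactly the planted clean records", {
  sv <- simulate_variants(n_clean = 4, seed = 3)
  expect_equal(nrow(sv$records), 10 + 2)  # 6 violations, recurrent adds 2
  kept <- filter_small_variants(sv$records)
  truth_keys <- sv$truth$records$key[sv$truth$records$retained]
  expect_setequal(kept$variant_key, truth_keys)
  expect_equal(nrow(kept), 4)
})

test_that("filter cascade is order-independent", {
  sv <- simulate_variants(seed = 9)
  perm <- sv$records[sample(nrow(sv$records)), ]
  a <- filter_small_variants(sv$records) %>% dplyr::arrange(variant_key)
  b <- filter_small_variants(perm) %>% dplyr::arrange(variant_key)
  expect_equal(a, b)
})

test_that("normalization splits MNVs and multiallelics and left-aligns indels", {
  ref <- c(chr1 = "GGTCAAAAATGCATAT")
  # biallelic SNV unchanged
  snv <- clean_var(3, ref = "T", alt = "A")
  expect_equal(normalize_variants(snv, ref)[, c("pos", "ref", "alt")],
               snv[, c("pos", "ref", "alt")])
  # MNV "CA" -> "GT" at 4: two SNVs at consecutive positions
  mnv <- clean_var(4, ref = "CA", alt = "GT")
  out <- normalize_variants(mnv, ref)
  expect_equal(out$pos, c(4, 5))
  expect_equal(out$ref, c("C", "A"))
  expect_equal(out$alt, c("G", "T"))
  # multiallelic separated into entries
  ma <- clean_var(3, ref = "T", alt = "A,G")
  expect_equal(normalize_variants(ma, ref)$alt, c("A", "G"))
  # right-aligned single-base deletion in the A-homopolymer -> 5'-most
  del <- clean_var(8, ref = "AA", alt = "A")
  out <- normalize_variants(del, ref)
  expect_equal(out$pos, 4)
  expect_equal(out$ref, "CA")
  expect_equal(out$alt, "C")
  # reference mismatch errors
  expect_error(normalize_variants(clean_var(3, ref = "G", alt = "A"), ref),
               "mismatch")
})

test_that("normalization is idempotent", {
  sv <- simulate_variants(seed = 4)
  recs <- dplyr::bind_rows(sv$records, sv$indels[names(sv$records)])
  n1 <- normalize_variants(recs, sv$reference)
  n2 <- normalize_variants(n1, sv$reference)
  expect_equal(n1, n2)
})

sv_pair <- function(chrom2 = "chr1", pos1 = 1000, pos2 = 6000,
                    orient1 = "+", orient2 = "-", ...) {
  tibble::tibble(sample = "CL1", chrom1 = "chr1", pos1 = pos1,
                 orient1 = orient1, chrom2 = chrom2, pos2 = pos2,
                 orient2 = orient2, qual = 1500, filter_status = "PASS",
                 allele_frequency = 0.5, pon_flag = FALSE, AS = 2,
                 RAS = 2) %>%
    dplyr::mutate(...)
}

test_that("structural-variant filter enforces qual and two-sided assembly", {
  expect_equal(nrow(filter_structural_variants(sv_pair(qual = 1000))), 1)
  expect_equal(nrow(filter_structural_variants(sv_pair(qual = 999))), 0)
  expect_equal(nrow(filter_structural_variants(sv_pair(AS = 5, RAS = 0))), 0)
  expect_equal(nrow(filter_structural_variants(sv_pair(AS = 0, RAS = 5))), 0)
  expect_equal(nrow(filter_structural_variants(sv_pair(pon_flag = TRUE))), 0)
  expect_equal(nrow(filter_structural_variants(
    sv_pair(allele_frequency = 0.05))), 0)
  expect_equal(nrow(filter_structural_variants(
    sv_pair(filter_status = "lowqual"))), 0)
})

test_that("breakend orientation truth table is exhaustive", {
  combos <- tidyr::expand_grid(orient1 = c("+", "-"), orient2 = c("+", "-"))
  same <- purrr::pmap_dfr(combos, function(orient1, orient2)
    sv_pair(orient1 = orient1, orient2 = orient2))
  ann <- annotate_sv_events(same)
  expect_equal(ann$sv_type, c("INV", "DEL", "DUP", "INV"))
  expect_true(all(ann$sv_length == 5000))
  # interchromosomal -> TRA with NA length, any orientation
  tra <- purrr::pmap_dfr(combos, function(orient1, orient2)
    sv_pair(chrom2 = "chr2", orient1 = orient1, orient2 = orient2))
  ann_tra <- annotate_sv_events(tra)
  expect_true(all(ann_tra$sv_type == "TRA"))
  expect_true(all(is.na(ann_tra$sv_length)))
  # canonical ordering: swapped breakends give the same event
  swapped <- sv_pair(pos1 = 6000, pos2 = 1000, orient1 = "-", orient2 = "+")
  expect_equal(annotate_sv_events(swapped)$sv_type, "DEL")
  expect_error(annotate_sv_events(sv_pair(pos1 = 5, pos2 = 5)), "pos1 == pos2")
})

test_that("indel context classification matches string-matching oracles", {
  # deletion of AT inside ...ATATAT... -> rep (unit continues 3')
  ref2 <- c(chr1 = "CCGAATATATCGG")
  rec <- clean_var(4, ref = "AAT", alt = "A")
  out <- classify_indel_context(rec, ref2)
  expect_equal(out$indel_context, "rep")
  expect_equal(out$context_len, 2L)

  # deletion GTCA whose 3' flank begins GT -> mh with homology 2
  ref3 <- c(chr1 = paste0("CCTAGTCA", "GTGGAACC"))
  rec3 <- clean_var(4, ref = "AGTCA", alt = "A")
  out3 <- classify_indel_context(rec3, ref3)
  expect_equal(out3$indel_context, "mh")
  expect_equal(out3$context_len, 2L)

  # deletion GGGG with non-repetitive T flank -> none
  ref4 <- c(chr1 = paste0("CCTAGGGG", "TTCAAACC"))
  rec4 <- clean_var(4, ref = "AGGGG", alt = "A")
  expect_equal(classify_indel_context(rec4, ref4)$indel_context, "none")

  # insertion contexts mirror deletions
  ins_rep <- clean_var(4, ref = "A", alt = "ACA")
  ref5 <- c(chr1 = paste0("CCTA", "CACAGGAA"))
  expect_equal(classify_indel_context(ins_rep, ref5)$indel_context, "rep")
  expect_error(classify_indel_context(clean_var(4, ref = "A", alt = "T"),
                                      ref5), "non-indel")
})

test_that("planted context categories are recovered exactly", {
  contexts <- c(del.mh = 3, del.rep = 2, del.none = 1, ins.mh = 2,
                ins.rep = 1, ins.none = 1)
  sv <- simulate_variants(contexts = contexts, seed = 8)
  out <- classify_indel_context(sv$indels, sv$reference)
  got <- table(paste0(out$indel_type, ".", out$indel_context))
  expect_equal(as.integer(got[names(contexts)]), unname(contexts))
  counts <- count_contexts(indels = out)
  expect_equal(sum(counts$count), sum(contexts))
})

test_that("trinucleotide classes are pyrimidine-normalized and partition SNVs", {
  ref <- c(chr1 = "AACGTACGT")
  # A C G with C>T -> A[C>T]G (already pyrimidine)
  r1 <- clean_var(3, ref = "C", alt = "T")
  expect_equal(snv_trinucleotide_context(r1, ref)$snv_context, "A[C>T]G")
  # C G T with G>A -> A[C>T]G after reverse complement
  r2 <- clean_var(4, ref = "G", alt = "A")
  expect_equal(snv_trinucleotide_context(r2, ref)$snv_context, "A[C>T]G")
  # N in flank -> NA, excluded from counts
  refn <- c(chr1 = "ANCGT")
  r3 <- clean_var(3, ref = "C", alt = "A")
  out <- snv_trinucleotide_context(r3, refn)
  expect_true(is.na(out$snv_context))
  expect_equal(nrow(count_contexts(snvs = out)), 0)
  # partition: class counts sum to classifiable SNVs
  sv <- simulate_variants(seed = 12)
  snvs <- snv_trinucleotide_context(
    dplyr::filter(sv$records, nchar(ref) == 1, nchar(alt) == 1),
    sv$reference)
  cc <- count_contexts(snvs = snvs)
  expect_equal(sum(cc$count), sum(!is.na(snvs$snv_context)))
})

test_that("MSI call is a minimum threshold at 10,000", {
  expect_false(classify_msi(0))
  expect_true(classify_msi(10000))
  expect_false(classify_msi(9999))
  expect_true(classify_msi(10000, inclusive = FALSE) == FALSE)
  expect_error(classify_msi(-1), "non-negative")
})

test_that("VCF round trip preserves filter-relevant fields", {
  sv <- simulate_variants(seed = 6)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_variants(sv$records, f, contigs = c(toy1 = nchar(sv$reference)))
  back <- read_vcf_variants(f, sample_id = "CL1")
  expect_equal(nrow(back), nrow(sv$records))
  expect_equal(back$pos, sv$records$pos)
  expect_equal(back$ref, sv$records$ref)
  expect_equal(back$allele_frequency, sv$records$allele_frequency)
  expect_equal(back$pon_flag, sv$records$pon_flag)
  expect_equal(back$confidence_region, sv$records$confidence_region)
  # retained set is unchanged after the round trip (single-sample keys)
  one <- dplyr::filter(sv$records, sample == "CL1")
  write_vcf_variants(one, f)
  back1 <- read_vcf_variants(f, sample_id = "CL1")
  rec <- dplyr::count(dplyr::distinct(sv$records, sample, chrom, pos, ref, alt),
                      chrom, pos, ref, alt)
  recur <- setNames(rec$n, paste(rec$chrom, rec$pos, rec$ref, rec$alt,
                                 sep = ":"))
  expect_setequal(
    filter_small_variants(back1, cohort_recurrence = recur)$variant_key,
    filter_small_variants(one, cohort_recurrence = recur)$variant_key)
})
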