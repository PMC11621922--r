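#' Read small-variant records from a VCF file
#'
#' Thin wrapper over `vcfR::read.vcfR()` that maps a VCF 4.2 file onto the
#' package's variant-record tibble. Per-record annotations consumed by the
#' filter cascade are read from INFO keys: `AF` (allele frequency), `PON`
#' (flag), `CONF` (`high`/`low` confidence region) and `BLACKLIST`
#' (comma-separated hits among gnomad/dbsnp/known_indels).
#'
#' @param path VCF file path.
#' @param sample_id Sample identifier to attach (default: file base name).
#' @return Tibble with the columns expected by [filter_small_variants()].
#' @export
read_vcf_variants <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (is.null(sample_id))
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  if (nrow(fix) == 0) {
    return(tibble(sample = character(0), chrom = character(0),
                  pos = numeric(0), ref = character(0), alt = character(0),
                  qual = numeric(0), filter_status = character(0),
                  allele_frequency = numeric(0), pon_flag = logical(0),
                  confidence_region = character(0),
                  blacklist_hits = character(0)))
  }
  info <- vcfR::getINFO(v)
  get_key <- function(key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    m
  }
  tibble(
    sample = sample_id,
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = as.numeric(fix$QUAL),
    filter_status = ifelse(is.na(fix$FILTER) | fix$FILTER == ".",
                           "PASS", fix$FILTER),
    allele_frequency = as.numeric(get_key("AF")),
    pon_flag = stringr::str_detect(info, "(^|;)PON(;|$|=1)"),
    confidence_region = get_key("CONF"),
    blacklist_hits = dplyr::coalesce(get_key("BLACKLIST"), "")
  )
}

#' Write small-variant records to a VCF file
#'
#' Inverse of [read_vcf_variants()]: emits a minimal VCF 4.2 with the
#' package's INFO annotations so that filter inputs round-trip through
#' files.
#'
#' @param records Variant tibble (see [filter_small_variants()]).
#' @param path Output path (`.vcf`; vcfR appends `.gz` compression when
#'   asked for, which we avoid).
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf_variants <- function(records, path, contigs = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=hrdscar",
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele frequency">',
    '##INFO=<ID=PON,Number=0,Type=Flag,Description="Panel of normals hit">',
    '##INFO=<ID=CONF,Number=1,Type=String,Description="Confidence region">',
    '##INFO=<ID=BLACKLIST,Number=1,Type=String,Description="Blacklist hits">'
  )
  if (!is.null(contigs))
    lines <- c(lines, paste0("##contig=<ID=", names(contigs),
                             ",length=", unname(contigs), ">"))
  lines <- c(lines,
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(records) > 0) {
    bl <- if (is.list(records$blacklist_hits)) {
      purrr::map_chr(records$blacklist_hits,
                     ~paste(.x[!is.na(.x) & .x != ""], collapse = ","))
    } else {
      dplyr::coalesce(records$blacklist_hits, "")
    }
    info <- paste0(
      "AF=", records$allele_frequency,
      ifelse(records$pon_flag, ";PON", ""),
      ifelse(is.na(records$confidence_region), "",
             paste0(";CONF=", records$confidence_region)),
      ifelse(bl == "", "", paste0(";BLACKLIST=", bl))
    )
    body <- paste(records$chrom, format(records$pos, scientific = FALSE,
                                        trim = TRUE),
                  ".", records$ref, records$alt,
                  records$qual, records$filter_status, info, sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a toy reference as FASTA
#'
#' @param reference Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  lines <- unlist(purrr::imap(as.list(reference), function(seq, name) {
    c(paste0(">", name),
      substring(seq, seq(1, nchar(seq), 70),
                pmin(nchar(seq), seq(1, nchar(seq), 70) + 69)))
  }))
  writeLines(lines, path)
  invisible(path)
}
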