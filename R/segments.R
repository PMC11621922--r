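#' Read allele-specific copy-number segment tables
#'
#' Reads per-sample allele-specific copy-number segments in one of three
#' CSV/TSV dialects and returns a single validated tibble with columns
#' `sample, chrom, start, end, total_cn, minor_cn` in the package-internal
#' 0-based half-open coordinate convention (segment length is simply
#' `end - start`). Input dialects follow the seg-file convention of 1-based
#' inclusive coordinates; starts are decremented on read.
#'
#' Dialects map the column headers of the two public sources of
#' allele-specific calls onto the generic schema:
#' \describe{
#'   \item{`generic`}{`sample,chrom,start,end,total_cn,minor_cn`}
#'   \item{`broad_ccle`}{CCLE 2019 allelic calls:
#'     `CCLE_ID,Chromosome,Start,End,Modal_Total_CN,Modal_HSCN_1` (minor
#'     allele copy number in `Modal_HSCN_1`).}
#'   \item{`sanger_purecn`}{PureCN segment exports:
#'     `model_id,chr,start,end,total_copy_number,minor_copy_number`.}
#' }
#'
#' @param path File path of the segment table (CSV or TSV, autodetected).
#' @param dialect One of `"generic"`, `"broad_ccle"`, `"sanger_purecn"`.
#' @param merge_adjacent Merge abutting segments with identical
#'   `(total_cn, minor_cn)` within a sample/chromosome (default `TRUE`);
#'   merging never changes any scar count.
#' @param keep_y Keep chromosome Y segments (default `FALSE`; copy-number
#'   calls on Y are unreliable).
#' @return Tibble of segments, sorted by `(sample, chrom, start)`.
#' @export
read_segments <- function(path, dialect = c("generic", "broad_ccle",
                                            "sanger_purecn"),
                          merge_adjacent = TRUE, keep_y = FALSE) {
  dialect <- match.arg(dialect)
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  map <- switch(dialect,
    generic = c(sample = "sample", chrom = "chrom", start = "start",
                end = "end", total_cn = "total_cn", minor_cn = "minor_cn"),
    broad_ccle = c(sample = "CCLE_ID", chrom = "Chromosome", start = "Start",
                   end = "End", total_cn = "Modal_Total_CN",
                   minor_cn = "Modal_HSCN_1"),
    sanger_purecn = c(sample = "model_id", chrom = "chr", start = "start",
                      end = "end", total_cn = "total_copy_number",
                      minor_cn = "minor_copy_number"))
  miss <- setdiff(unname(map), names(raw))
  if (length(miss) > 0)
    abort(paste0("segment file lacks required columns for dialect '",
                 dialect, "': ", paste(miss, collapse = ", ")))
  seg <- tibble(
    sample   = as.character(raw[[map[["sample"]]]]),
    chrom    = as.character(raw[[map[["chrom"]]]]),
    start    = as.numeric(raw[[map[["start"]]]]) - 1,  # 1-based incl -> 0-based
    end      = as.numeric(raw[[map[["end"]]]]),
    total_cn = as.numeric(raw[[map[["total_cn"]]]]),
    minor_cn = as.numeric(raw[[map[["minor_cn"]]]])
  )
  if (!keep_y) seg <- filter(seg, !.data$chrom %in% c("chrY", "Y"))
  seg <- validate_segments(seg)
  if (merge_adjacent) seg <- merge_segments(seg)
  seg
}

#' Write segments in the generic dialect
#'
#' Inverse of [read_segments()] for the generic dialect: coordinates are
#' converted back to 1-based inclusive on write so that a read/write round
#' trip reproduces a canonical generic file.
#'
#' @param segments Segment tibble (internal convention).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- segments %>%
    mutate(start = .data$start + 1) %>%
    select("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a segment tibble
#'
#' Checks the internal segment invariants: required columns, `start < end`,
#' `0 <= minor_cn <= total_cn / 2` (minor allele cannot exceed the major),
#' and no overlapping segments within a sample/chromosome. Errors name the
#' offending sample and locus.
#'
#' @param segments Segment tibble.
#' @return The validated tibble, sorted by `(sample, chrom, start)`.
#' @export
validate_segments <- function(segments) {
  req <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(req, names(segments))
  if (length(miss) > 0)
    abort(paste0("segment table is missing columns: ",
                 paste(miss, collapse = ", ")))
  seg <- as_tibble(segments) %>% arrange(.data$sample, .data$chrom, .data$start)
  if (nrow(seg) == 0) return(seg)
  if (any(seg$start >= seg$end))
    abort("segments with start >= end present")
  if (any(seg$minor_cn < 0 | seg$total_cn < 0))
    abort("negative copy numbers present")
  bad_minor <- seg$minor_cn > seg$total_cn - seg$minor_cn
  if (any(bad_minor))
    abort(paste0("minor_cn exceeds major_cn for sample ",
                 seg$sample[which(bad_minor)[1]]))
  ovl <- seg %>%
    group_by(.data$sample, .data$chrom) %>%
    mutate(.ovl = .data$start < lag(.data$end, default = -Inf)) %>%
    ungroup()
  if (any(ovl$.ovl)) {
    i <- which(ovl$.ovl)[1]
    abort(paste0("overlapping segments in sample ", ovl$sample[i],
                 " on ", ovl$chrom[i], " near position ", ovl$start[i]))
  }
  seg
}

#' Merge abutting segments with identical copy-number state
#'
#' @param segments Validated segment tibble.
#' @return Tibble with runs of abutting equal-state segments collapsed.
#' @export
merge_segments <- function(segments) {
  if (nrow(segments) == 0) return(segments)
  segments %>%
    arrange(.data$sample, .data$chrom, .data$start) %>%
    group_by(.data$sample, .data$chrom) %>%
    mutate(.new_run = .data$start != lag(.data$end, default = -1) |
             .data$total_cn != lag(.data$total_cn, default = -1) |
             .data$minor_cn != lag(.data$minor_cn, default = -1),
           .run = cumsum(.data$.new_run)) %>%
    group_by(.data$sample, .data$chrom, .data$.run) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              total_cn = first(.data$total_cn),
              minor_cn = first(.data$minor_cn), .groups = "drop") %>%
    select(-".run") %>%
    arrange(.data$sample, .data$chrom, .data$start)
}
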