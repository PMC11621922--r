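#' Genome models for scar scoring
#'
#' A genome model is a tibble with one row per chromosome and columns
#' `chrom`, `length`, `cen_start`, `cen_end` (all bp, 0-based half-open
#' internally). The centromere interval splits each chromosome into a p and
#' a q arm; arm boundaries drive the LST and TAI definitions ("large-scale
#' state transitions" are counted per arm, and "telomeric" allelic imbalance
#' must reach a chromosome end without crossing the centromere).
#'
#' Two builtins ship with the package:
#' \describe{
#'   \item{`"toy"`}{three chromosomes (100-250 Mb) with fixed centromeres;
#'     small, deterministic, used throughout the test-suite.}
#'   \item{`"GRCh38-lite"`}{the 22 autosomes plus X with GRCh38 lengths and
#'     centromere (acen cytoband) intervals frozen into the package.}
#' }
#'
#' @param source `"toy"`, `"GRCh38-lite"`, a file path to a CSV/TSV with
#'   columns `chrom,length,cen_start,cen_end`, or a data frame with those
#'   columns.
#' @return A validated genome tibble (class `hrd_genome`).
#' @examples
#' load_genome("toy")
#' @export
load_genome <- function(source) {
  if (is.data.frame(source)) {
    gen <- as_tibble(source)
  } else if (is.character(source) && length(source) == 1) {
    if (source == "toy") {
      gen <- toy_genome_table()
    } else if (source %in% c("GRCh38-lite", "grch38-lite", "GRCh38")) {
      gen <- grch38_lite_table()
    } else if (file.exists(source)) {
      gen <- readr::read_delim(source, show_col_types = FALSE,
                               progress = FALSE)
    } else {
      abort(paste0("unknown genome builtin or missing file: '", source, "'"))
    }
  } else {
    abort("`source` must be a builtin name, a file path or a data frame")
  }
  validate_genome(gen)
}

toy_genome_table <- function() {
  tibble(
    chrom     = c("chr1", "chr2", "chr3"),
    length    = c(250e6, 180e6, 100e6),
    cen_start = c(120e6,  90e6,  40e6),
    cen_end   = c(128e6,  96e6,  46e6)
  )
}

# GRCh38 autosome + X lengths and acen-cytoband centromere intervals,
# transcribed once from the UCSC cytoband table and frozen here.
grch38_lite_table <- function() {
  tibble(
    chrom = paste0("chr", c(1:22, "X")),
    length = c(248956422, 242193529, 198295559, 190214555, 181538259,
               170805979, 159345973, 145138636, 138394717, 133797422,
               135086622, 133275309, 114364328, 107043718, 101991189,
               90338345, 83257441, 80373285, 58617616, 64444167,
               46709983, 50818468, 156040895),
    cen_start = c(121700000, 91800000, 87800000, 48200000, 46100000,
                  58500000, 58100000, 43200000, 42200000, 38000000,
                  51000000, 33200000, 16500000, 16100000, 17500000,
                  35300000, 22700000, 15400000, 24200000, 25700000,
                  10900000, 13700000, 58100000),
    cen_end = c(125100000, 96000000, 94000000, 51800000, 50600000,
                62600000, 62100000, 47200000, 45500000, 41600000,
                55800000, 37800000, 18900000, 18200000, 20500000,
                38400000, 27400000, 21500000, 28100000, 30400000,
                13000000, 17400000, 63800000)
  )
}

validate_genome <- function(gen) {
  req <- c("chrom", "length", "cen_start", "cen_end")
  miss <- setdiff(req, names(gen))
  if (length(miss) > 0)
    abort(paste0("genome table is missing columns: ",
                 paste(miss, collapse = ", ")))
  gen <- as_tibble(gen)[req]
  gen$chrom <- as.character(gen$chrom)
  if (anyDuplicated(gen$chrom))
    abort("duplicate chromosome names in genome table")
  if (any(!is.finite(gen$length) | gen$length <= 0))
    abort("chromosome lengths must be positive")
  bad <- gen$cen_start <= 0 | gen$cen_start >= gen$cen_end |
    gen$cen_end >= gen$length
  if (any(bad))
    abort(paste0("invalid centromere interval on ",
                 paste(gen$chrom[bad], collapse = ", "),
                 " (need 0 < cen_start < cen_end < length)"))
  class(gen) <- c("hrd_genome", class(gen))
  gen
}
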