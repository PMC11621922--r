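#' Scar-metric parameters
#'
#' Length thresholds of the three genomic scar metrics. Defaults follow the
#' canonical definitions: LOH regions must exceed 15 Mb (and not span a
#' whole chromosome); LST breakpoints require both flanking segments to be
#' at least 10 Mb after removal ("smoothing") of segments shorter than
#' 3 Mb; telomeric allelic imbalance regions must reach a chromosome end to
#' within `telomere_tolerance` (WES segments rarely touch the literal end).
#'
#' @param loh_min_len Minimum LOH region length in bp (strict `>`).
#' @param lst_min_flank Minimum flank length in bp for an LST breakpoint
#'   (inclusive `>=`).
#' @param lst_smooth_len Segments shorter than this are removed before LST
#'   counting; also the maximum allowed gap across a counted breakpoint.
#' @param telomere_tolerance Distance in bp from a chromosome end within
#'   which an allelic-imbalance region counts as telomeric.
#' @param tai_min_len Minimum TAI region length in bp (default 0: no size
#'   filter beyond the telomere/centromere/whole-chromosome exclusions).
#' @return A list of class `scar_params`.
#' @export
scar_params <- function(loh_min_len = 15e6, lst_min_flank = 10e6,
                        lst_smooth_len = 3e6, telomere_tolerance = 1e3,
                        tai_min_len = 0) {
  p <- list(loh_min_len = loh_min_len, lst_min_flank = lst_min_flank,
            lst_smooth_len = lst_smooth_len,
            telomere_tolerance = telomere_tolerance,
            tai_min_len = tai_min_len)
  if (any(unlist(p[1:4]) <= 0) || tai_min_len < 0)
    abort("scar parameters must be positive (tai_min_len >= 0)")
  structure(p, class = "scar_params")
}

check_profile_genome <- function(segments, genome) {
  extra <- setdiff(unique(segments$chrom), genome$chrom)
  if (length(extra) > 0)
    abort(paste0("profile contains chromosomes absent from genome: ",
                 paste(extra, collapse = ", ")))
}

# Maximal runs of consecutive rows satisfying `flag` within one chromosome's
# sorted segments; returns per-run start/end/summed length/whole-chromosome
# coverage.
segment_runs <- function(seg, flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  cumlen <- cumsum(seg$end - seg$start)
  list(
    run_start = seg$start[starts[keep]],
    run_end = seg$end[ends[keep]],
    run_len = cumlen[ends[keep]] -
      c(0, cumlen)[starts[keep]],
    whole_chrom = r$lengths[keep] == nrow(seg),
    n = length(keep)
  )
}

#' Count LOH scar regions
#'
#' LOH regions are maximal runs of segments with minor-allele copy number 0
#' and total copy number > 0. A region is counted when its summed segment
#' length strictly exceeds `loh_min_len` and it does not span every observed
#' segment of its chromosome (the whole-chromosome exclusion; operationalized
#' against the observed record rather than the nominal chromosome length, so
#' WES coverage gaps do not defeat it). Runs spanning the centromere are a
#' single region: only the length rule applies to LOH.
#'
#' @param segments Segment tibble for one sample.
#' @param genome Genome tibble from [load_genome()].
#' @param params [scar_params()].
#' @return Integer count.
#' @export
count_loh <- function(segments, genome, params = scar_params()) {
  check_profile_genome(segments, genome)
  total <- 0L
  for (seg in split(segments, segments$chrom)) {
    runs <- segment_runs(seg, seg$minor_cn == 0 & seg$total_cn > 0)
    total <- total + sum(runs$run_len > params$loh_min_len & !runs$whole_chrom)
  }
  as.integer(total)
}

# Clip one chromosome's segments to its two arms; segments wholly inside the
# centromere are dropped, spanning segments are split. Works on plain
# per-chromosome vectors for speed.
clip_to_arms <- function(start, end, total_cn, minor_cn,
                         cen_start, cen_end, chrom_len) {
  lapply(list(c(0, cen_start), c(cen_end, chrom_len)), function(iv) {
    keep <- end > iv[1] & start < iv[2]
    list(start = pmax(start[keep], iv[1]), end = pmin(end[keep], iv[2]),
         total_cn = total_cn[keep], minor_cn = minor_cn[keep])
  })
}

#' Count large-scale state transitions (LST)
#'
#' Per chromosome arm: segments shorter than `lst_smooth_len` are removed
#' and flanking segments with equal copy-number state are joined; an LST is
#' a breakpoint between adjacent remaining segments of different state where
#' both flanks are at least `lst_min_flank` long and the gap across the
#' breakpoint is shorter than `lst_smooth_len`. Segments are clipped to arm
#' boundaries first, so no counted breakpoint spans the centromere.
#'
#' @inheritParams count_loh
#' @return Integer count.
#' @export
count_lst <- function(segments, genome, params = scar_params()) {
  check_profile_genome(segments, genome)
  total <- 0L
  for (seg in split(segments, segments$chrom)) {
    g <- genome[genome$chrom == seg$chrom[1], ]
    arms <- clip_to_arms(seg$start, seg$end, seg$total_cn, seg$minor_cn,
                         g$cen_start, g$cen_end, g$length)
    for (arm in arms) {
      keep <- arm$end - arm$start >= params$lst_smooth_len
      arm <- lapply(arm, `[`, keep)
      arm <- join_equal_state(arm)
      m <- length(arm$start)
      if (m < 2) next
      len <- arm$end - arm$start
      gap <- arm$start[-1] - arm$end[-m]
      ok <- len[-m] >= params$lst_min_flank &
        len[-1] >= params$lst_min_flank &
        gap < params$lst_smooth_len
      total <- total + sum(ok)
    }
  }
  as.integer(total)
}

# Join adjacent segments with identical (total_cn, minor_cn), bridging any
# gap left by removed small segments. Operates on plain vectors.
join_equal_state <- function(arm) {
  m <- length(arm$start)
  if (m < 2) return(arm)
  new_run <- c(TRUE, arm$total_cn[-1] != arm$total_cn[-m] |
                 arm$minor_cn[-1] != arm$minor_cn[-m])
  run <- cumsum(new_run)
  first_idx <- which(new_run)
  last_idx <- c(first_idx[-1] - 1, m)
  list(start = arm$start[first_idx], end = arm$end[last_idx],
       total_cn = arm$total_cn[first_idx], minor_cn = arm$minor_cn[first_idx])
}

#' Count telomeric allelic imbalance (TAI) regions
#'
#' TAI regions are maximal runs of segments in allelic imbalance (minor
#' copy number different from major, i.e. `2 * minor_cn != total_cn`) that
#' reach a chromosome end to within `telomere_tolerance`, do not cross the
#' centromere, and do not span every observed segment of the chromosome.
#' At most two regions (one per telomere) can qualify per chromosome.
#'
#' @inheritParams count_loh
#' @return Integer count.
#' @export
count_tai <- function(segments, genome, params = scar_params()) {
  check_profile_genome(segments, genome)
  total <- 0L
  tol <- params$telomere_tolerance
  for (seg in split(segments, segments$chrom)) {
    g <- genome[genome$chrom == seg$chrom[1], ]
    runs <- segment_runs(seg, 2 * seg$minor_cn != seg$total_cn)
    if (runs$n == 0) next
    crosses_cen <- runs$run_start < g$cen_start & runs$run_end > g$cen_end
    telomeric <- runs$run_start <= tol | runs$run_end >= g$length - tol
    big_enough <- runs$run_len > params$tai_min_len |
      params$tai_min_len == 0
    total <- total +
      min(2L, sum(telomeric & !crosses_cen & !runs$whole_chrom & big_enough))
  }
  as.integer(total)
}

#' Score genomic scars and HRDsum
#'
#' Computes the LOH, LST and TAI counts and their sum (`hrdsum`, the "HRD
#' score") for every sample in a segment tibble.
#'
#' @param segments Segment tibble for one or more samples (columns
#'   `sample, chrom, start, end, total_cn, minor_cn`, internal coordinates;
#'   see [read_segments()]).
#' @param genome Genome tibble from [load_genome()].
#' @param params [scar_params()].
#' @return Tibble with columns `sample, loh, lst, tai, hrdsum`.
#' @examples
#' genome <- load_genome("toy")
#' prof <- simulate_profile(genome, n_loh = 2, n_lst = 1, n_tai = 1, seed = 1)
#' score_scars(prof$segments, genome)
#' @export
score_scars <- function(segments, genome, params = scar_params()) {
  segments <- validate_segments(segments)
  samples <- unique(segments$sample)
  purrr::map_dfr(samples, function(s) {
    seg <- segments[segments$sample == s, ]
    loh <- count_loh(seg, genome, params)
    lst <- count_lst(seg, genome, params)
    tai <- count_tai(seg, genome, params)
    tibble(sample = s, loh = loh, lst = lst, tai = tai,
           hrdsum = loh + lst + tai)
  })
}
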