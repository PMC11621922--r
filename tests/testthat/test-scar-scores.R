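# Hand-built profiles on the toy genome (chr1: 250 Mb, cen 120-128 Mb;
# chr2: 180 Mb, cen 90-96 Mb; chr3: 100 Mb, cen 40-46 Mb).

test_that("LOH counting obeys length and whole-chromosome rules", {
  # all heterozygous -> 0
  expect_equal(count_loh(diploid_baseline(), toy_g), 0L)

  # one 20 Mb LOH segment amid heterozygous segments -> 1
  p <- dplyr::bind_rows(
    seg_row("chr1", 0, 30e6, 2, 1),
    seg_row("chr1", 30e6, 50e6, 2, 0),
    seg_row("chr1", 50e6, 250e6, 2, 1))
  expect_equal(count_loh(p, toy_g), 1L)

  # trimmed to exactly 15 Mb -> 0 (strict >)
  p15 <- p
  p15$end[2] <- 45e6; p15$start[3] <- 45e6
  expect_equal(count_loh(p15, toy_g), 0L)
  p15$end[2] <- 45e6 + 1
  p15$start[3] <- 45e6 + 1
  expect_equal(count_loh(p15, toy_g), 1L)

  # LOH covering the entire observed chromosome -> 0
  whole <- seg_row("chr3", 0, 100e6, 2, 0)
  expect_equal(count_loh(whole, toy_g), 0L)

  # centromere-spanning LOH run is one region (length rule only)
  span <- dplyr::bind_rows(
    seg_row("chr1", 0, 110e6, 2, 1),
    seg_row("chr1", 110e6, 140e6, 1, 0),
    seg_row("chr1", 140e6, 250e6, 2, 1))
  expect_equal(count_loh(span, toy_g), 1L)
})

test_that("LOH run length is the sum of segment lengths across a run", {
  # two abutting LOH segments of different total CN form one run of 20 Mb
  p <- dplyr::bind_rows(
    seg_row("chr1", 0, 30e6, 2, 1),
    seg_row("chr1", 30e6, 40e6, 2, 0),
    seg_row("chr1", 40e6, 50e6, 3, 0),
    seg_row("chr1", 50e6, 250e6, 2, 1))
  expect_equal(count_loh(p, toy_g), 1L)
})

test_that("LST counting smooths small segments and respects flank rule", {
  # one segment per chromosome -> 0
  expect_equal(count_lst(diploid_baseline(), toy_g), 0L)

  # adjacent 20 Mb and 30 Mb of different state on one arm -> 1
  p <- dplyr::bind_rows(
    seg_row("chr1", 0, 20e6, 2, 1),
    seg_row("chr1", 20e6, 50e6, 3, 1))
  expect_equal(count_lst(p, toy_g), 1L)

  # 20 / 2 / 30 Mb triplet with a differing middle -> 1 after smoothing
  p3 <- dplyr::bind_rows(
    seg_row("chr1", 0, 20e6, 2, 1),
    seg_row("chr1", 20e6, 22e6, 5, 1),
    seg_row("chr1", 22e6, 52e6, 3, 1))
  expect_equal(count_lst(p3, toy_g), 1L)

  # same triplet with equal-state flanks: joined after smoothing -> 0
  p3$total_cn[3] <- 2
  expect_equal(count_lst(p3, toy_g), 0L)

  # flank of exactly 10 Mb is counted (inclusive >=)
  pf <- dplyr::bind_rows(
    seg_row("chr1", 0, 10e6, 2, 1),
    seg_row("chr1", 10e6, 30e6, 3, 1))
  expect_equal(count_lst(pf, toy_g), 1L)
  pf$end[1] <- 10e6 - 1e5; pf$start[2] <- 10e6 - 1e5
  expect_equal(count_lst(pf, toy_g), 0L)

  # breakpoint spanning the centromere is not counted
  pc <- dplyr::bind_rows(
    seg_row("chr1", 0, 124e6, 2, 1),
    seg_row("chr1", 124e6, 250e6, 3, 1))
  expect_equal(count_lst(pc, toy_g), 0L)

  # gap wider than the smoothing length across a breakpoint is not counted
  pg <- dplyr::bind_rows(
    seg_row("chr1", 0, 20e6, 2, 1),
    seg_row("chr1", 24e6, 50e6, 3, 1))
  expect_equal(count_lst(pg, toy_g), 0L)
})

test_that("TAI counting applies telomere, centromere and whole-chromosome rules", {
  # fully balanced -> 0
  expect_equal(count_tai(diploid_baseline(), toy_g), 0L)

  # AI region from 200 Mb to the 250 Mb chromosome end (q arm) -> 1
  p <- dplyr::bind_rows(
    seg_row("chr1", 0, 200e6, 2, 1),
    seg_row("chr1", 200e6, 250e6, 3, 1))
  expect_equal(count_tai(p, toy_g), 1L)

  # AI through the centromere to the chromosome end -> 0 (crosses centromere)
  pc <- dplyr::bind_rows(
    seg_row("chr1", 0, 100e6, 2, 1),
    seg_row("chr1", 100e6, 250e6, 3, 1))
  expect_equal(count_tai(pc, toy_g), 0L)

  # AI spanning the whole chromosome -> 0
  expect_equal(count_tai(seg_row("chr3", 0, 100e6, 3, 1), toy_g), 0L)

  # interior AI region (not reaching a telomere) -> 0
  pi <- dplyr::bind_rows(
    seg_row("chr1", 0, 50e6, 2, 1),
    seg_row("chr1", 50e6, 80e6, 3, 1),
    seg_row("chr1", 80e6, 250e6, 2, 1))
  expect_equal(count_tai(pi, toy_g), 0L)

  # both arms telomeric AI, balanced middle -> 2 (at most 2 per chromosome)
  p2 <- dplyr::bind_rows(
    seg_row("chr1", 0, 30e6, 3, 1),
    seg_row("chr1", 30e6, 220e6, 2, 1),
    seg_row("chr1", 220e6, 250e6, 3, 1))
  expect_equal(count_tai(p2, toy_g), 2L)

  # telomere tolerance: region stopping 500 bp short of the end still counts
  pt <- dplyr::bind_rows(
    seg_row("chr1", 0, 200e6, 2, 1),
    seg_row("chr1", 200e6, 250e6 - 500, 3, 1))
  expect_equal(count_tai(pt, toy_g), 1L)
  pt$end[2] <- 250e6 - 5e3  # outside the 1 kb tolerance
  expect_equal(count_tai(pt, toy_g), 0L)
})

test_that("hrdsum is the sum of the three counts and errors on unknown chroms", {
  pr <- simulate_profile(toy_g, 2, 3, 1, seed = 11)
  sc <- score_scars(pr$segments, toy_g)
  expect_equal(sc$hrdsum, sc$loh + sc$lst + sc$tai)
  expect_equal(sc$hrdsum, 6L)
  bad <- seg_row("chr99", 0, 1e6, 2, 1)
  expect_error(score_scars(bad, toy_g), "absent from genome")
})

test_that("splitting a segment into abutting equal-state halves changes no count", {
  for (s in 1:10) {
    pr <- simulate_profile(toy_g, sample(0:2, 1), sample(0:2, 1),
                           sample(0:1, 1), seed = s)
    seg <- pr$segments
    before <- score_scars(seg, toy_g)
    # split every segment longer than 2 bp at its midpoint
    lo <- seg %>% dplyr::mutate(end = floor((start + end) / 2))
    hi <- seg %>% dplyr::mutate(start = floor((start + end) / 2))
    split_seg <- dplyr::bind_rows(lo, hi) %>%
      dplyr::arrange(sample, chrom, start)
    after <- score_scars(split_seg, toy_g)
    expect_equal(after, before)
  }
})

test_that("merging adjacent equal-state segments changes no scar count", {
  for (s in 1:5) {
    pr <- simulate_profile(toy_g, 1, 1, 1, seed = s)
    seg <- pr$segments
    lo <- seg %>% dplyr::mutate(end = floor((start + end) / 2))
    hi <- seg %>% dplyr::mutate(start = floor((start + end) / 2))
    split_seg <- dplyr::bind_rows(lo, hi) %>%
      dplyr::arrange(sample, chrom, start)
    merged <- merge_segments(split_seg)
    expect_equal(merged, seg)
    expect_equal(score_scars(merged, toy_g), score_scars(seg, toy_g))
  }
})

test_that("translation of an arm's internal breakpoints preserves LOH and LST", {
  pr <- simulate_profile(toy_g, 1, 1, 0, seed = 21)
  seg <- pr$segments
  base <- score_scars(seg, toy_g)
  # shift interior event boundaries by 1 Mb (events stay within their arms)
  shifted <- seg %>%
    dplyr::group_by(chrom) %>%
    dplyr::mutate(
      start = ifelse(start > 0, start + 1e6, start),
      end = ifelse(dplyr::row_number() < dplyr::n(), end + 1e6, end)) %>%
    dplyr::ungroup()
  sc <- score_scars(shifted, toy_g)
  expect_equal(sc$loh, base$loh)
  expect_equal(sc$lst, base$lst)
})

test_that("adding one disjoint >15 Mb LOH region increases loh by exactly 1", {
  # hand-built base: one interior LOH run on chr1 p, baseline elsewhere
  base_seg <- dplyr::bind_rows(
    seg_row("chr1", 0, 20e6, 2, 1),
    seg_row("chr1", 20e6, 24e6, 3, 1),
    seg_row("chr1", 24e6, 44e6, 2, 0),
    seg_row("chr1", 44e6, 48e6, 3, 1),
    seg_row("chr1", 48e6, 250e6, 2, 1),
    seg_row("chr2", 0, 180e6, 2, 1),
    seg_row("chr3", 0, 100e6, 2, 1))
  base <- score_scars(base_seg, toy_g)
  expect_equal(base$loh, 1L)
  # add a disjoint shielded 20 Mb LOH run on chr2 q
  seg2 <- dplyr::bind_rows(
    base_seg[base_seg$chrom != "chr2", ],
    seg_row("chr2", 0, 97e6, 2, 1),
    seg_row("chr2", 97e6, 101e6, 3, 1),
    seg_row("chr2", 101e6, 121e6, 2, 0),
    seg_row("chr2", 121e6, 125e6, 3, 1),
    seg_row("chr2", 125e6, 180e6, 2, 1)) %>%
    dplyr::arrange(sample, chrom, start)
  sc <- score_scars(seg2, toy_g)
  expect_equal(sc$loh, base$loh + 1L)
  expect_gte(sc$hrdsum, base$hrdsum)
})
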