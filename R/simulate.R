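# Run code under a local integer seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    abort("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Arm table (chrom, arm, start, end) from a genome model.
genome_arms <- function(genome) {
  bind_rows(
    tibble(chrom = genome$chrom, arm = "p", start = 0,
           end = genome$cen_start, chrom_len = genome$length),
    tibble(chrom = genome$chrom, arm = "q", start = genome$cen_end,
           end = genome$length, chrom_len = genome$length)
  ) %>% mutate(arm_len = .data$end - .data$start)
}

#' Simulate a segment profile with planted scar events
#'
#' Generates a diploid heterozygous baseline (total 2, minor 1) over a
#' genome and plants non-interacting scar events so that the true
#' `(loh, lst, tai)` counts equal the request exactly:
#' \itemize{
#'   \item an LOH event is an interior copy-neutral LOH segment (18-30 Mb,
#'     state 2/0) shielded on both sides by 4 Mb segments of a third state
#'     so its boundaries never qualify as LST breakpoints;
#'   \item an LST event is a single 15 Mb segment of altered state placed
#'     so that exactly one of its boundaries has two >=10 Mb flanks (the
#'     other boundary is shielded by a 4 Mb balanced buffer);
#'   \item a TAI event is an allelic-imbalance segment (20-35 Mb, state
#'     3/1) anchored at a telomere and shielded from the rest of the arm
#'     by a 4 Mb balanced buffer.
#' }
#' Each event occupies its own chromosome arm (sampled without
#' replacement among arms long enough for the event type), which makes the
#' planted events mutually non-interacting by construction.
#'
#' @param genome Genome tibble from [load_genome()].
#' @param n_loh,n_lst,n_tai Requested event counts.
#' @param seed Integer seed; the same seed reproduces the same profile.
#' @param sample_id Sample name (default `"SIM"`).
#' @return List with `segments` (tibble) and `truth`
#'   (`list(loh, lst, tai, seed)`).
#' @export
simulate_profile <- function(genome, n_loh = 0, n_lst = 0, n_tai = 0,
                             seed = 1, sample_id = "SIM") {
  with_seed(seed, {
    arms <- genome_arms(genome)
    # minimum arm length required per event type (event + buffers + margins)
    need <- c(loh = 48e6, lst = 36e6, tai = 42e6)
    events <- c(rep("loh", n_loh), rep("lst", n_lst), rep("tai", n_tai))
    events <- events[order(-need[events])]  # place greediest first
    placed <- list()
    avail <- arms[sample.int(nrow(arms)), ]  # shuffled arm order
    for (ev in events) {
      ok <- which(avail$arm_len >= need[[ev]])
      if (length(ok) == 0)
        abort("genome too small for the requested events")
      i <- ok[1]
      placed[[length(placed) + 1]] <- c(avail[i, ], list(event = ev))
      avail <- avail[-i, , drop = FALSE]
    }
    # per-chromosome event sub-segments
    ev_segs <- purrr::map_dfr(placed, function(p) {
      a0 <- p$start; a1 <- p$end
      if (p$event == "loh") {
        len <- runif(1, 18e6, 30e6)
        lo <- runif(1, a0 + 3e6, a1 - len - 8e6 - 3e6)
        tibble(chrom = p$chrom,
               start = c(lo, lo + 4e6, lo + 4e6 + len),
               end = c(lo + 4e6, lo + 4e6 + len, lo + 8e6 + len),
               total_cn = c(3, 2, 3), minor_cn = c(1, 0, 1))
      } else if (p$event == "lst") {
        # buffer (4,2) then 15 Mb (3,1); downstream baseline >= 12 Mb
        lo <- runif(1, a0 + 3e6, a1 - 19e6 - 12e6)
        tibble(chrom = p$chrom,
               start = c(lo, lo + 4e6),
               end = c(lo + 4e6, lo + 19e6),
               total_cn = c(4, 3), minor_cn = c(2, 1))
      } else {
        len <- runif(1, 20e6, 35e6)
        if (p$arm == "p") {
          tibble(chrom = p$chrom, start = c(0, len),
                 end = c(len, len + 4e6),
                 total_cn = c(3, 4), minor_cn = c(1, 2))
        } else {
          tibble(chrom = p$chrom,
                 start = c(p$chrom_len - len - 4e6, p$chrom_len - len),
                 end = c(p$chrom_len - len, p$chrom_len),
                 total_cn = c(4, 3), minor_cn = c(2, 1))
        }
      }
    })
    if (nrow(ev_segs) == 0)
      ev_segs <- tibble(chrom = character(0), start = numeric(0),
                        end = numeric(0), total_cn = numeric(0),
                        minor_cn = numeric(0))
    # fill the rest of every chromosome with diploid heterozygous baseline
    segments <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
      ch <- genome$chrom[i]; len <- genome$length[i]
      ev <- ev_segs[ev_segs$chrom == ch, , drop = FALSE]
      ev <- ev[order(ev$start), , drop = FALSE]
      bounds <- rbind(c(0, if (nrow(ev)) ev$start[1] else len),
                      if (nrow(ev))
                        cbind(ev$end, c(ev$start[-1], len)))
      base <- tibble(chrom = ch, start = bounds[, 1], end = bounds[, 2],
                     total_cn = 2, minor_cn = 1) %>%
        filter(.data$end > .data$start)
      bind_rows(base, ev) %>% arrange(.data$start)
    })
    segments <- segments %>%
      mutate(sample = sample_id) %>%
      select("sample", "chrom", "start", "end", "total_cn", "minor_cn")
    list(segments = validate_segments(segments),
         truth = list(loh = n_loh, lst = n_lst, tai = n_tai, seed = seed))
  })
}

#' Simulate raw HRDsum scores from several distorted datasets
#'
#' Draws per-sample truth scores from a gamma distribution resembling a
#' skewed HRDsum distribution, then derives each dataset's raw scores by a
#' dataset-specific monotone distortion plus Gaussian noise (clamped at 0).
#' A configurable core of samples is present in every dataset; the
#' remaining samples are assigned to single datasets in rotation.
#'
#' @param n Number of samples (default 300).
#' @param distortions List of monotone functions, one per dataset (default:
#'   identity, `1.3 x + 2`, `8 sqrt(x)`).
#' @param noise_sd Gaussian noise standard deviation (default 3).
#' @param overlap_fraction Fraction of samples present in all datasets
#'   (default 0.35).
#' @param truth_scores Optional numeric vector of truth scores (overrides
#'   `n`).
#' @param seed Integer seed.
#' @return List with `scores` (tibble `sample, dataset, hrdsum`) and
#'   `truth` (tibble `sample, truth_score`), plus the seed.
#' @export
simulate_multidataset <- function(n = 300,
                                  distortions = list(
                                    function(x) x,
                                    function(x) 1.3 * x + 2,
                                    function(x) 8 * sqrt(x)),
                                  noise_sd = 3, overlap_fraction = 0.35,
                                  truth_scores = NULL, seed = 1) {
  if (length(distortions) < 2) abort("need at least 2 distortions")
  with_seed(seed, {
    if (is.null(truth_scores))
      truth_scores <- rgamma(n, shape = 2, scale = 10)
    n <- length(truth_scores)
    ids <- sprintf("CL%04d", seq_len(n))
    n_core <- ceiling(overlap_fraction * n)
    if (n_core < 3) abort("common-sample core must have at least 3 samples")
    ds_names <- paste0("ds", seq_along(distortions))
    assign_ds <- purrr::map(seq_len(n), function(i) {
      if (i <= n_core) ds_names
      else ds_names[(i %% length(ds_names)) + 1]
    })
    scores <- purrr::map_dfr(seq_len(n), function(i) {
      tibble(sample = ids[i], dataset = assign_ds[[i]],
             truth = truth_scores[i])
    }) %>%
      mutate(hrdsum = purrr::map2_dbl(.data$dataset, .data$truth, function(d, t) {
        k <- match(d, ds_names)
        max(0, distortions[[k]](t) + rnorm(1, sd = noise_sd))
      })) %>%
      select("sample", "dataset", "hrdsum")
    list(scores = scores,
         truth = tibble(sample = ids, truth_score = truth_scores),
         seed = seed)
  })
}

#' Simulate a toy reference and variant set with known filter outcomes
#'
#' Builds a deterministic toy reference chromosome with planted context
#' motifs, then emits one clean PASS record per requested clean variant,
#' one record violating exactly one filter rule per requested violation
#' class, and indel records with planted microhomology / repeat / neutral
#' contexts. Recurrent variants are emitted for three cohort samples so the
#' "three or more cell lines" rule fires on the full table.
#'
#' @param n_clean Number of clean (retained) SNV records (default 4).
#' @param violations Character vector of single-rule violations to plant,
#'   among `"pon"`, `"blacklist"`, `"recurrent"`, `"fail_filter"`,
#'   `"low_af"`, `"low_qual"` (default all six).
#' @param contexts Named integer vector of planted indel-context counts,
#'   categories among `del.mh`, `del.rep`, `del.none`, `ins.mh`,
#'   `ins.rep`, `ins.none`.
#' @param seed Integer seed.
#' @param sample_id Cohort sample carrying the planted records.
#' @return List with `reference` (named character), `records` (variant
#'   tibble incl. cohort extras), `indels` (clean indel records with
#'   planted contexts) and `truth`.
#' @export
simulate_variants <- function(n_clean = 4,
                              violations = c("pon", "blacklist", "recurrent",
                                             "fail_filter", "low_af",
                                             "low_qual"),
                              contexts = c(del.mh = 2, del.rep = 2,
                                           del.none = 1, ins.mh = 1,
                                           ins.rep = 1, ins.none = 1),
                              seed = 1, sample_id = "CL1") {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    n_slots <- n_clean + length(violations) + sum(contexts) + 2
    ref_len <- 200 * (n_slots + 2)
    refseq <- paste(sample(bases, ref_len, replace = TRUE), collapse = "")
    slot_pos <- 200 * seq_len(n_slots)  # motif anchor positions
    put <- function(s, pos, motif) {
      paste0(substr(s, 1, pos - 1), motif,
             substr(s, pos + nchar(motif), nchar(s)))
    }
    clean_rec <- function(pos, ref, alt, sample = sample_id) {
      tibble(sample = sample, chrom = "toy1", pos = pos, ref = ref,
             alt = alt, qual = 300, filter_status = "PASS",
             allele_frequency = 0.5, pon_flag = FALSE,
             confidence_region = "high", blacklist_hits = "")
    }
    recs <- list(); truth <- list(); slot <- 0
    next_pos <- function() { slot <<- slot + 1; slot_pos[slot] }
    snv_at <- function(pos) {
      ref <- substr(refseq, pos, pos)
      alt <- sample(setdiff(bases, ref), 1)
      list(ref = ref, alt = alt)
    }
    for (i in seq_len(n_clean)) {
      p <- next_pos(); s <- snv_at(p)
      recs[[length(recs) + 1]] <- clean_rec(p, s$ref, s$alt)
      truth[[length(truth) + 1]] <- tibble(
        key = variant_key("toy1", p, s$ref, s$alt), planted = "clean",
        retained = TRUE)
    }
    for (v in violations) {
      p <- next_pos(); s <- snv_at(p)
      r <- clean_rec(p, s$ref, s$alt)
      extra <- NULL
      if (v == "pon") r$pon_flag <- TRUE
      if (v == "blacklist") r$blacklist_hits <- "gnomad"
      if (v == "fail_filter") r$filter_status <- "germline"
      if (v == "low_af") r$allele_frequency <- 0.05
      if (v == "low_qual") { r$confidence_region <- "low"; r$qual <- 200 }
      if (v == "recurrent")
        extra <- bind_rows(clean_rec(p, s$ref, s$alt, "CL2"),
                           clean_rec(p, s$ref, s$alt, "CL3"))
      recs[[length(recs) + 1]] <- bind_rows(r, extra)
      truth[[length(truth) + 1]] <- tibble(
        key = variant_key("toy1", p, s$ref, s$alt), planted = v,
        retained = FALSE)
    }
    # context indels: build motif, overwrite reference, emit anchored record
    indels <- list()
    add_ctx <- function(category) {
      p <- next_pos()
      parts <- strsplit(category, ".", fixed = TRUE)[[1]]
      type <- parts[1]; ctx <- parts[2]
      anchor <- "T"
      if (ctx == "rep") { chg <- "CA"; flank <- "CACAGG" }
      if (ctx == "mh") { chg <- "GTCA"; flank <- "GTGGTT" }
      if (ctx == "none") { chg <- "GGGG"; flank <- "TTTTTT" }
      if (type == "del") {
        motif <- paste0("C", anchor, chg, flank)  # C blocks left-shift
        refseq <<- put(refseq, p - 1, motif)
        rec <- clean_rec(p, paste0(anchor, chg), anchor)
      } else {
        motif <- paste0("C", anchor, flank)
        refseq <<- put(refseq, p - 1, motif)
        rec <- clean_rec(p, anchor, paste0(anchor, chg))
      }
      indels[[length(indels) + 1]] <<- mutate(rec, planted_context = category)
    }
    for (cat in names(contexts))
      for (k in seq_len(contexts[[cat]])) add_ctx(cat)
    list(reference = c(toy1 = refseq),
         records = bind_rows(recs),
         indels = if (length(indels)) bind_rows(indels) else tibble(),
         truth = list(records = bind_rows(truth),
                      contexts = contexts, seed = seed))
  })
}

#' Simulate a feature table with planted correlation and enrichment effects
#'
#' Generates a per-sample score, numeric features with specified Pearson
#' correlations to that score (0 for null features), and a boolean gene
#' deficiency matrix whose association with an HRD label (top quintile of
#' the score) follows the requested per-gene deficiency probabilities.
#'
#' @param n_samples Number of samples (default 200).
#' @param effects Named numeric vector of true Pearson correlations, one
#'   per feature, absolute value < 1.
#' @param n_null Additional null (r = 0) features (default 0).
#' @param genes Named list of `c(p_hrd, p_hrp)` deficiency probabilities
#'   per gene (default none).
#' @param seed Integer seed.
#' @return List with `scores` (tibble `sample, summary_hrdsum`),
#'   `features`, `deficiency` (long tibble), `hrd_labels` and `truth`.
#' @export
simulate_features <- function(n_samples = 200, effects = c(feat_pos = 0.6),
                              n_null = 0, genes = list(), seed = 1) {
  if (any(abs(effects) >= 1)) abort("effect correlations must be < 1")
  with_seed(seed, {
    ids <- sprintf("CL%04d", seq_len(n_samples))
    score <- rgamma(n_samples, shape = 2, scale = 10)
    z <- as.numeric(scale(score))
    eff <- c(effects,
             setNames(rep(0, n_null),
                      if (n_null) sprintf("null%03d", seq_len(n_null))))
    feats <- purrr::imap(eff, function(r, nm) {
      r * z + sqrt(1 - r^2) * rnorm(n_samples)
    })
    features <- dplyr::bind_cols(tibble(sample = ids), as_tibble(feats))
    hrd <- score >= quantile(score, 0.8, type = 7)
    deficiency <- purrr::imap_dfr(genes, function(pp, g) {
      tibble(sample = ids, gene = g,
             deficient = rbinom(n_samples, 1, ifelse(hrd, pp[1], pp[2])) == 1)
    })
    list(scores = tibble(sample = ids, summary_hrdsum = score),
         features = features,
         deficiency = deficiency,
         hrd_labels = tibble(sample = ids, hrd = hrd),
         truth = list(effects = eff, genes = genes, seed = seed))
  })
}

#' Simulate dose-response plates from the primary curve model
#'
#' Samples replicate plates from the primary two-parameter model on the
#' standard assay design: a top dose of 10 umol/L across a 10-point 1:3
#' dilution series, with control wells at mean absorbance 1. Absorbance is
#' `1 - response` (viability) plus Gaussian noise.
#'
#' @param a,b True curve parameters (`IC50 = 10^a` nmol/L).
#' @param n_points Number of doses (default 10).
#' @param dilution Dilution factor between doses (default 3).
#' @param top_nmolL Top dose in nmol/L (default 10000 = 10 umol/L).
#' @param noise_sd Gaussian noise sd on absorbance (default 0.03).
#' @param replicates Number of replicate plates (default 1).
#' @param n_controls Control wells per plate (default 6).
#' @param max_response Optional cap on the true response (shallow or
#'   partial-response curves), default `NULL` (no cap).
#' @param seed Integer seed.
#' @return List with `plate` (tibble `replicate, well, concentration_nmolL,
#'   absorbance, is_control`), `points` (tibble `replicate, x, y` of
#'   noise-free normalized coordinates with noise applied to `y`), and
#'   `truth`.
#' @export
simulate_dose_response <- function(a = 2, b = 0, n_points = 10, dilution = 3,
                                   top_nmolL = 1e4, noise_sd = 0.03,
                                   replicates = 1, n_controls = 6,
                                   max_response = NULL, seed = 1) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  with_seed(seed, {
    conc <- top_nmolL / dilution^(seq_len(n_points) - 1)
    x <- log10(conc)
    y_true <- dr_primary(x, a, b)
    if (!is.null(max_response)) y_true <- pmin(y_true, max_response)
    plate <- purrr::map_dfr(seq_len(replicates), function(r) {
      y <- y_true + rnorm(n_points, sd = noise_sd)
      ctrl <- 1 + rnorm(n_controls, sd = noise_sd)
      bind_rows(
        tibble(replicate = r, well = paste0("D", seq_len(n_points)),
               concentration_nmolL = conc, absorbance = 1 - y,
               is_control = FALSE),
        tibble(replicate = r, well = paste0("C", seq_len(n_controls)),
               concentration_nmolL = 0, absorbance = ctrl,
               is_control = TRUE))
    })
    points <- plate %>%
      filter(!.data$is_control) %>%
      mutate(x = log10(.data$concentration_nmolL),
             y = 1 - .data$absorbance) %>%
      select("replicate", "x", "y")
    list(plate = plate, points = points,
         truth = list(a = a, b = b, n_points = n_points,
                      dilution = dilution, top_nmolL = top_nmolL,
                      noise_sd = noise_sd, replicates = replicates,
                      max_response = max_response, seed = seed))
  })
}
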