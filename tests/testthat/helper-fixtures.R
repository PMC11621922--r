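# Shared fixtures and independent oracles for the test-suite.

# One-segment-per-row builder for hand-made profiles (internal 0-based
# half-open coordinates).
seg_row <- function(chrom, start, end, total_cn, minor_cn,
                    sample = "S1") {
  tibble::tibble(sample = sample, chrom = chrom, start = start, end = end,
                 total_cn = total_cn, minor_cn = minor_cn)
}

toy_g <- hrdscar::load_genome("toy")

# A fully heterozygous diploid baseline on the toy genome.
diploid_baseline <- function(sample = "S1") {
  dplyr::bind_rows(lapply(seq_len(nrow(toy_g)), function(i) {
    seg_row(toy_g$chrom[i], 0, toy_g$length[i], 2, 1, sample = sample)
  }))
}

# Minimal converged dose-response fit for vote-rule tests.
mk_fit <- function(ic50_nmolL, max_response, converged = TRUE) {
  structure(list(model = "primary", a = log10(ic50_nmolL), b = 0,
                 ic50_nmolL = ic50_nmolL, ic50_printed = ic50_nmolL,
                 max_response = max_response, converged = converged,
                 rss = 0, points = tibble::tibble(x = 1:4, y = 1:4)),
            class = "dr_fit")
}

# Independent one-tailed Fisher oracle: enumerate all 2x2 tables with the
# observed margins and sum hypergeometric probabilities of tables at least
# as extreme (greater alternative) via choose().
fisher_greater_oracle <- function(a, b, c, d) {
  m <- a + b          # deficient total
  n <- c + d          # proficient total
  k <- a + c          # HRD total
  xs <- max(0, k - n):min(m, k)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= a])
}

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Kruskal-Wallis H by the rank-sum formula with ties correction.
kw_oracle <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Deterministic per-seed event request for the planted-recovery sweep.
with_seed_req <- function(s) {
  set.seed(s + 10000)
  c(sample(0:4, 1), sample(0:4, 1), sample(0:4, 1))
}

# Interpolated percentile oracle (linear between order statistics,
# matching the R type-7 convention, written out directly).
pct_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
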