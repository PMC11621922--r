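---
title: "Genomic scar scores and HRD analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic scar scores and HRD analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscar)
```

This vignette documents the models implemented in `hrdscar`, the tunable
parameters and their defaults, the numerical and design decisions taken
where the underlying procedures leave room, and what the synthetic-data
generators do and do not emulate.

## The scar model

Homologous recombination deficiency (HRD) leaves large-scale footprints in
a tumor genome's allele-specific copy-number profile. `hrdscar` counts
three such footprints on a per-sample segment table (`sample, chrom,
start, end, total_cn, minor_cn`; internally 0-based half-open, so segment
length is exactly `end − start`):

**LOH.** A loss-of-heterozygosity region is a maximal run of consecutive
segments with minor-allele copy number 0 and total copy number above 0. A
region counts when its summed segment length strictly exceeds
`loh_min_len` (default 15 Mb) and it does not span the whole chromosome.
"Whole chromosome" is operationalized against the *observed* record — a
run covering every observed segment of the chromosome — rather than
against the nominal chromosome length, so the exclusion still works on
exome profiles with coverage gaps. A run that spans the centromere is one
region; only the length rule applies to LOH.

**LST.** A large-scale state transition is a copy-number breakpoint with
two big flanks. Per chromosome arm (segments are clipped at the centromere
interval first, so no counted breakpoint spans it), segments shorter than
`lst_smooth_len` (default 3 Mb) are removed and flanking segments of equal
`(total_cn, minor_cn)` state are joined across the gap; a breakpoint
between adjacent remaining segments of different state counts when both
flanks are at least `lst_min_flank` (default 10 Mb, inclusive) and the gap
across the breakpoint is smaller than `lst_smooth_len`.

**TAI.** A telomeric allelic-imbalance region is a maximal run of
segments with unequal allele counts (`2 · minor_cn ≠ total_cn`) that
reaches a chromosome end, does not cross the centromere, and does not span
the whole chromosome. Because exome segments rarely touch the literal
chromosome end, "reaches a telomere" means within `telomere_tolerance`
(default 1 kb) of position 0 or the chromosome length. A region that
extends from one arm across the centromere into the other is excluded
outright — the centromere-crossing exclusion is integral to the telomeric
metric, and it is what makes a whole-chromosome imbalance count zero
rather than two. At most two regions (one per telomere) can qualify per
chromosome. No minimum length is applied beyond these exclusions; a
`tai_min_len` parameter exists for users who want one.

**HRDsum** is the sum of the three counts. All four lengths live in
`scar_params()` rather than as constants.

Two further conventions: input segment tables follow the seg-file
convention of 1-based inclusive coordinates and are converted on read;
chromosome Y is dropped by default (copy-number calls there are
unreliable) with a flag to keep it. Gaps between segments are permitted
and treated as unobserved sequence — the metrics operate on the observed
record.

## Harmonizing scores across datasets

Scores computed from different copy-number sources (different capture
kits, callers, institutes) sit on shifted scales even though they rank
samples almost identically. The merge proceeds in three steps:

1. for the samples present in *every* dataset, take the per-sample median
   of the raw scores (middle value for odd counts, mean of the central
   pair for even counts);
2. for each dataset, fit ordinary least squares of that median on a
   natural cubic spline basis of the dataset's raw scores;
3. transform every score by its dataset's map, clamp below at zero
   (HRDsum is a count), and average transformed scores for samples present
   in more than one dataset.

The spline degrees of freedom default to `df = 4` with interior knots at
quantiles of the raw scores — enough flexibility to absorb smooth
monotone scale differences while resisting oscillation; it is exposed as
an argument because the appropriate flexibility depends on how many
common samples anchor the fit (the fit requires at least `df + 2`).
Natural splines are linear beyond the boundary knots, which is exactly the
extrapolation behavior wanted for samples scoring outside the common
range. Because affine functions lie in the span of the basis, identical
datasets are a fixed point of the whole procedure to numerical precision —
a property the test-suite checks.

## Classification

The HRDsum cutoff is derived as the fifth percentile of scores among
samples with known BRCA1/2 deficiencies, with linear interpolation between
order statistics (the common default of statistical environments) and
rounding to the nearest integer, since published cutoffs are integers.
Because the rounding convention behind a published integer cannot be
recovered from the integer itself, `derive_cutoff()` attaches the
unrounded percentile as an attribute. Classification boundaries follow the
printed rules exactly: HRDsum-high is *inclusive* (score ≥ cutoff), the
CHORD probability rule is *strict* (p > 0.4), and MSI samples are excluded
from CHORD classification before the probability is consulted, because an
abundance of repeat-region indels dominates the mutation-context signal
that classifier relies on.

## Gene deficiency, proficiency and silencing labels

A gene in a sample is **deficient** when it carries a homozygous mutation
(allele frequency strictly above 0.85) that is ClinVar-pathogenic or
VEP-HIGH-impact, or a deep deletion. ClinVar matching is case-insensitive
on significance strings containing "pathogenic" but not "conflicting" or
"benign", so "Likely_pathogenic" qualifies and
"Conflicting_interpretations_of_pathogenicity" does not. Only HIGH impact
is admitted — "moderate" missense calls are not treated as damaging.
**Proficient** requires no mutations at all in the supplied table (the
rule is deliberately unqualified, so silent variants also disqualify), no
deep deletion, and expression strictly above the lower-quartile threshold
(on the CCLE scale: log2(TPM+1) of 3.8 for *BRCA1*, 2.07 for *BRCA2*).
**Likely silenced** requires expression strictly below that threshold
together with promoter methylation fraction strictly above 0.3, and is
only assessable when methylation data exist. Deficient and proficient are
mutually exclusive by construction. Literature-derived corrections (a
known revertant, a methylation status only reported externally) are
applied through an explicit override table, never hard-coded.

## Tumor-only variant filtering and mutation contexts

Cell lines usually lack matched normals, so somatic calls are made in
tumor-only mode and cleaned by a cascade of filters. A small-variant
record is retained exactly when all of the following hold: no
panel-of-normals flag; no hits in the gnomAD/dbSNP/known-indels
blacklists; seen in at most two cohort cell lines (recurrence counts
normalized `(chrom, pos, ref, alt)` keys, so representation differences
cannot split a recurrent variant); caller `FILTER` is PASS; allele
frequency at least 0.1; and quality at least 240 in low-confidence or 170
in high-confidence regions. Records with unknown confidence get the
stricter cutoff. Each rule is a pure per-record predicate, so the cascade
is order-independent — a property tested by permutation. Structural
(breakend-pair) records additionally require quality ≥ 1,000 and assembly
support from both sides (`AS > 0` and `RAS > 0`).

Normalization (applied before filtering and context extraction)
left-aligns and parsimony-trims indels, splits multi-nucleotide variants
into their constituent SNVs, and separates multiallelic records; it is
idempotent.

Breakend pairs are classified by the simple-event truth table after
canonical ordering: interchromosomal pairs are translocations; on one
chromosome, orientations `(+,−)` are deletions, `(−,+)` duplications, and
equal orientations inversions, with length `pos2 − pos1`.

Indel contexts follow the conventions used by mutation-context HRD
classifiers: an indel is in a *repeat* context when its changed sequence
is a whole number of tandem copies of a unit that continues immediately 3′
in the reference (at least two copies in total at the locus, so a
single-unit deletion inside a longer tandem array qualifies); otherwise it
is a *microhomology* context when at least 2 bp of the changed sequence's
5′ end match the reference immediately 3′ of the event; otherwise *none*.
Both minimums are parameters. Repeat takes precedence over microhomology
because a full adjacent copy is stronger evidence than a partial one. SNV
contexts use the standard 96-class pyrimidine-normalized trinucleotide
encoding. The MSI call is a minimum threshold on the count of indels in
repeat regions, default 10,000 (the cell-line calibration of that
parameter) and inclusive; the comparator is exposed as a flag because a
"minimum" admits either reading and the two differ only at the exact
boundary.

## Statistics

Enrichment of gene deficiencies among HRD-classified lines uses a
one-tailed Fisher exact test in the "greater" direction — the question is
specifically whether deficiency is *enriched* among HRD lines — with
Benjamini–Hochberg adjustment across tested genes. Only genes deficient in
at least one HRD line enter testing; a gene that never co-occurs with the
HRD label cannot be enriched and would only dilute the adjustment. The
implementation calls `stats::fisher.test` and `stats::p.adjust`; the
test-suite checks both against hand-written oracles (hypergeometric
enumeration via `choose()`, brute-force step-up) to 1e-12.

Association scans report the Pearson correlation of a score with each
numeric feature on pairwise-complete samples (features differ in
missingness, and listwise deletion would needlessly discard samples),
with t-distribution p-values on n−2 degrees of freedom; constant features
are reported as `NA` and excluded from the adjustment. Quartile-binned
tests cut the score at interpolated quartile breaks — samples exactly on
a break fall in the lower bin, and degenerate breaks collapse bins, the
test then using groups−1 degrees of freedom. A constant response returns
H = 0 directly, since the ties-corrected formula is 0/0 there. Noncancerous
and MSI cell lines are excluded from all association and enrichment scans
by a single central masking step (`feature_table()`), so no individual
scan can forget the rule.

CRISPR screen gene scores follow the fold-change recipe exactly: per
replicate, guide-level log2((endpoint + 1)/(initial + 1)), centered by the
replicate's median; centered values averaged across replicates per guide;
gene score the median over its guides. Median centering makes the scores
invariant to global scaling of a replicate's counts.

## Dose–response fitting and sensitivity calls

Plate absorbances are divided by the mean of the control wells; response
is one minus that viability. The primary model is

y = 1 − 1 / (1 + 10^(10^b · (x − a)))

with x the log10 concentration in nmol/L, midpoint y(a) = 0.5 by
construction, and IC50 = 10^a nmol/L. The printed form of the slope term
is typographically ambiguous between 10^b and 10·b; we adopt 10^b — it
keeps the slope positive so the curve is always increasing with dose,
mirroring the |b| device of the fallback model — and expose the choice as
a flag. The fallback model, used when the primary optimizer fails, is
y = 1/(1 + e^(−|b|(x − a))); its published IC50 convention is the
parameter a itself, which lives in log10-concentration space, so the fit
records both a and 10^a rather than guessing the intended unit.

Fitting is Levenberg–Marquardt least squares
(`minpack.lm`) with a deterministic multistart grid: seven starting values
of a spanning the observed x-range crossed with three slope starts.
Failure of every start (no finite-parameter solution) triggers the
fallback, and failure of both marks the replicate fit unconverged.
`max_response` is the maximum *observed* normalized inhibition rather than
the model asymptote — the conservative reading of "maximal inhibitory
response", and robust to asymptote extrapolation on partial curves.

A cell line is **sensitive** when at least 66 % of replicates show
IC50 < 1 µmol/L (strict) together with maximal response > 75 %;
**insensitive** when at least 66 % show IC50 ≥ 1 µmol/L with maximal
response < 35 %; anything else is excluded. The 66 % rule is evaluated as
fraction ≥ 0.66, so 2 of 3 replicates qualify. Failed fits stay in the
denominator but satisfy neither rule.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with ground
truth recorded alongside:

- `simulate_profile()` plants scar events on a diploid heterozygous
  baseline. Events are *non-interacting by construction*: each occupies
  its own chromosome arm, and every event is shielded by 4 Mb segments of
  a third copy state so that an LOH or TAI region's boundaries never
  double-count as LST breakpoints. This is what makes the planted counts
  an exact oracle. The cost is realism: real profiles have interacting,
  nested and noisy events, focal amplifications, and whole-genome
  doubling, none of which the planter produces. Passing the
  planted-recovery sweep therefore shows the counting rules are
  implemented correctly, not that the metrics are robust to real-data
  messiness (the boundary and perturbation tests cover the rule edges
  separately).
- `simulate_multidataset()` draws truth scores from a gamma distribution
  (shape 2, scale 10 — a skewed, mostly-low distribution with a long
  right tail, the shape seen in large cell-line panels), applies
  per-dataset monotone distortions (defaults: identity, affine
  1.3x + 2, square-root 8√x) plus Gaussian noise (default sd 3), and
  controls the common-sample core via `overlap_fraction` (default 0.35,
  resembling the partial overlap of real panels; recovery checks use 1.0,
  i.e. three complete copies of the truth cohort).
- `simulate_variants()` builds a toy reference with planted context
  motifs and emits records that each violate exactly one filter rule,
  plus clean records and indels with known mh/rep/none contexts.
  Recurrent variants are emitted for three cohort samples so the
  recurrence rule fires on the assembled table.
- `simulate_features()` plants exact-correlation features
  (r·z + √(1−r²)·ε) and per-gene deficiency probabilities against a
  top-quintile HRD label.
- `simulate_dose_response()` samples plates from the primary curve on the
  standard assay design (10 points, 1:3 dilution, top dose 10 µmol/L)
  with control wells at mean 1.

All generators run under a single local integer seed (the caller's RNG
state is saved and restored), so every dataset is exactly reproducible
from `(parameters, seed)`.

## Problem sizes and numerical tolerances

The test-suite and the acceptance script use: 200 seeded profiles for the
planted-recovery sweep (on the GRCh38-scale genome, whose 46 arms host up
to 12 planted events per profile); n = 300 samples for harmonization
recovery at noise sd 3; exhaustive 2×2 tables up to n = 60 against the
hypergeometric oracle; 1,000 random vectors against the step-up oracle;
2,000 permutations for the type-I-error calibration; and 50 seeded
repetitions for noisy dose–response recovery. Identity fixed points are
asserted at 1e-6, oracle agreement at 1e-12, and noise-free curve
recovery at 1e-4 — tolerances reflecting exact-arithmetic expectations
versus optimizer termination.

## Known limitations

- Scar metrics consume allele-specific calls as given: no ploidy
  correction, purity adjustment, or re-segmentation. Systematically wrong
  inputs give systematically wrong scores.
- The centromere model is a single interval per chromosome; acrocentric
  short arms are treated like any other arm.
- The spline harmonization assumes a monotone, smooth relation between a
  dataset's scores and the consensus; it cannot repair rank disagreements
  between datasets.
- The CHORD random-forest classifier itself is out of scope: its HRD
  probabilities are consumed as an input column, and only its
  preprocessing (filters, contexts, MSI rule) is implemented here.
- The proficiency rule's "no mutations at all" is as blunt as printed: a
  single benign polymorphism in the mutation table disqualifies a line
  from the proficient label (it becomes indeterminate, not deficient).
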