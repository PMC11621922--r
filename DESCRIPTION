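Package: hrdscar
Title: Genomic Scar Scores and Homologous Recombination Deficiency Analysis for Cancer Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the three genomic scar metrics of homologous recombination
    deficiency (HRD) - loss of heterozygosity (LOH), large-scale state
    transitions (LST) and telomeric allelic imbalance (TAI) - and their sum
    (HRDsum) from allele-specific copy-number segment tables, harmonizes
    scores across datasets with natural-spline regression, derives and applies
    HRD classification cutoffs, labels gene deficiencies and likely epigenetic
    silencing, implements a tumor-only somatic variant filter cascade with
    structural-variant event annotation, indel/SNV mutation-context
    classification and a microsatellite-instability call, provides the
    enrichment, association and CRISPR-screen statistics used in large
    cell-line panels, and fits logistic dose-response curves for PARP
    inhibitor sensitivity calls. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    splines,
    minpack.lm,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
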