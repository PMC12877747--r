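Package: karyosel
Title: Copy-Number Evolution Under Negative Selection in Colorectal Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying somatic copy-number alteration (CNA) dynamics in
    multi-region and longitudinal tumor sequencing data. Implements a gland-level
    birth-death simulator of CNA accrual on a single-peak karyotype fitness
    landscape (negative selection of karyotypes distant from an optimum),
    approximate Bayesian computation for fitting the CNA rate and selection
    strength and for selecting between neutral and negative-selection models,
    six pairwise CNA divergence metrics with cohort aggregation, a linear
    genome-doubling classifier on segment count and percentage genome altered
    with patient-level clonal/subclonal logic, multi-sample ploidy/purity grid
    search from shallow whole-genome-sequencing log2 ratios, classification of
    CNA events on phylogenetic trees into clonal, intermediate and tip
    categories, B-allele-frequency SNP phasing with allelic-imbalance tests,
    and a fully seeded synthetic cohort generator producing every input the
    pipeline consumes together with its ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
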