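Package: mitocohort
Title: Cohort-Scale Mitochondrial DNA Variant, Heteroplasmy and NUMT Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cohort-scale analysis of the human
    mitochondrial genome from whole-genome sequencing evidence: sample and
    variant quality control for mtDNA calls, variant allele fraction based
    heteroplasmy classification, population frequency spectra and region
    enrichment, detection of non-reference nuclear mitochondrial DNA segments
    (NUMTs) from discordant read pairs with split-read breakpoint refinement
    on the circular mitochondrial genome, permutation enrichment of NUMT
    breakpoints against nuclear annotation tracks, extraction of invariable
    mitochondrial intervals, and association of heteroplasmic levels with
    nuclear genotype dosages under principal-component and sex covariates.
    A synthetic-data module generates every input with planted truth so the
    full pipeline is exercisable end-to-end without access-restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
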