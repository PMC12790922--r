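#' Variant allele fraction
#'
#' The VAF of a call is the ratio of the allele depth AD (reads supporting
#' the variant allele) to the total sequencing depth DP at the site.
#'
#' @param ad Non-negative integer vector, alt-supporting read counts.
#' @param dp Positive integer vector, total depth.
#' @return Numeric vector `ad / dp` in `[0, 1]`.
#' @export
#' @examples
#' compute_vaf(50, 100)
compute_vaf <- function(ad, dp) {
  if (any(dp <= 0)) abort("DP must be positive to compute a VAF.")
  if (any(ad < 0) || any(ad > dp)) abort("AD must satisfy 0 <= AD <= DP.")
  ad / dp
}

#' Mitochondrial DNA copy number per cell
#'
#' Estimated as (mean mtDNA depth / mean autosomal depth) x 2, the factor 2
#' reflecting the two autosomal copies per diploid cell.
#'
#' @param mean_mt_depth Mean fold-coverage of the mitochondrial genome.
#' @param mean_autosomal_depth Mean fold-coverage of the autosomes.
#' @return Numeric copy-number estimate.
#' @export
#' @examples
#' compute_mt_copy_number(3000, 31)
compute_mt_copy_number <- function(mean_mt_depth, mean_autosomal_depth) {
  if (any(mean_mt_depth <= 0) || any(mean_autosomal_depth <= 0)) {
    abort("depths must be positive.")
  }
  (mean_mt_depth / mean_autosomal_depth) * 2
}

#' Sample-level quality-control filter
#'
#' Applies the cohort sample filters. In variant mode (`for_numt = FALSE`) a
#' sample is dropped when its nuclear-DNA contamination exceeds
#' `max_contamination`, when it is flagged contaminated by the
#' phylogeny-based check, or when its mtDNA copy number falls below
#' `min_copy_number`. In NUMT mode (`for_numt = TRUE`) only the median
#' insert-size filter applies: samples with insert size below
#' `min_insert_size` are dropped (exactly `min_insert_size` is kept).
#'
#' @param qcs Tibble with columns `sample_id`, `mean_mt_depth`,
#'   `mean_autosomal_depth`, `contamination_fraction`,
#'   `mt_contaminated_flag`, `median_insert_size`.
#' @param max_contamination Maximum tolerated contamination fraction
#'   (default 0.02; strictly greater is dropped).
#' @param min_copy_number Minimum mtDNA copy number (default 50; strictly
#'   lower is dropped).
#' @param min_insert_size Minimum median insert size in bp for NUMT analysis
#'   (default 250; strictly smaller is dropped).
#' @param for_numt Apply the NUMT-mode filter instead of the variant-mode
#'   filters.
#' @return A list with `kept` (QC tibble with `copy_number` added) and
#'   `dropped` (tibble of `sample_id`, `reason` with machine-readable codes
#'   `contamination`, `mt_contamination_flag`, `copy_number`,
#'   `insert_size`).
#' @export
filter_samples <- function(qcs, max_contamination = 0.02,
                           min_copy_number = 50, min_insert_size = 250,
                           for_numt = FALSE) {
  if (nrow(qcs) == 0L) abort("qcs must contain at least one sample.")
  qcs <- dplyr::mutate(
    qcs,
    copy_number = compute_mt_copy_number(.data$mean_mt_depth,
                                         .data$mean_autosomal_depth))
  if (for_numt) {
    reason <- ifelse(qcs$median_insert_size < min_insert_size,
                     "insert_size", NA_character_)
  } else {
    reason <- dplyr::case_when(
      qcs$contamination_fraction > max_contamination ~ "contamination",
      qcs$mt_contaminated_flag ~ "mt_contamination_flag",
      qcs$copy_number < min_copy_number ~ "copy_number",
      TRUE ~ NA_character_
    )
  }
  list(
    kept = qcs[is.na(reason), , drop = FALSE],
    dropped = tibble::tibble(sample_id = qcs$sample_id[!is.na(reason)],
                             reason = reason[!is.na(reason)])
  )
}

#' Filter raw calls into the high-quality variant set
#'
#' Retains calls that are FILTER `PASS`, have depth strictly greater than
#' `min_dp` (100x), do not fall on a known artifact or low-complexity
#' position, and have VAF at or above `min_vaf` (0.1). The VAF is attached
#' to every retained call.
#'
#' @param records Call tibble from [read_mt_vcf()] (columns `sample_id`,
#'   `pos`, `ref`, `alt`, `filter`, `ad`, `dp`).
#' @param min_dp Depth bound; calls must have `dp > min_dp` (default 100).
#' @param min_vaf Minimum VAF retained (default 0.1, inclusive).
#' @param artifact_positions 1-based positions to exclude; default
#'   [mt_artifact_positions()].
#' @return A tibble of retained calls with columns `sample_id`, `pos`,
#'   `ref`, `alt`, `vaf`, `dp`, `level` (heteroplasmy classification).
#' @export
filter_variant_calls <- function(records, min_dp = 100, min_vaf = 0.1,
                                 artifact_positions = mt_artifact_positions()) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(sample_id = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          vaf = double(0), dp = integer(0),
                          level = character(0)))
  }
  records |>
    dplyr::filter(
      filter_is_pass(.data$filter),
      .data$dp > min_dp,
      !.data$pos %in% artifact_positions
    ) |>
    dplyr::mutate(vaf = compute_vaf(.data$ad, .data$dp)) |>
    dplyr::filter(.data$vaf >= min_vaf) |>
    dplyr::mutate(level = classify_heteroplasmy(.data$vaf)) |>
    dplyr::select("sample_id", "pos", "ref", "alt", "vaf", "dp", "level")
}

#' Classify a call as homoplasmic or heteroplasmic
#'
#' Homoplasmic calls have VAF in `[0.95, 1.00]`; heteroplasmic calls have
#' VAF in `[0.10, 0.95)`. Calls below VAF 0.1 should never reach this point
#' (they are removed by [filter_variant_calls()]) and raise an error.
#'
#' @param vaf Numeric vector of VAFs, each at least 0.1.
#' @return Character vector, `"homoplasmic"` or `"heteroplasmic"`.
#' @export
#' @examples
#' classify_heteroplasmy(c(0.10, 0.949, 0.95))
classify_heteroplasmy <- function(vaf) {
  if (any(vaf < 0.1) || any(vaf > 1)) {
    abort("VAF below 0.1 (or above 1) cannot be classified; filter first.")
  }
  ifelse(vaf >= 0.95, "homoplasmic", "heteroplasmic")
}

#' Classify a variant by allele lengths
#'
#' Single-base substitutions are SNVs, annotated as transition or
#' transversion and with their substitution class on both strands of the
#' mitochondrial duplex: VCF alleles are reported on the reference L-strand,
#' so the H-strand class is the reverse-complement base pair (e.g. L-strand
#' `G>A` is H-strand `C>T`). Length differences give insertions/deletions
#' with the net length change as subclass.
#'
#' @param ref,alt Uppercase DNA allele strings (A/C/G/T only).
#' @return A tibble with `ref`, `alt`, `vtype` (`SNV`, `insertion`,
#'   `deletion`), `subclass` (`transition`/`transversion` or e.g. `del_6bp`),
#'   `substitution_l`, `substitution_h` (NA for indels).
#' @export
#' @examples
#' classify_variant_type("G", "A")
#' classify_variant_type("CCCCTCT", "C")
classify_variant_type <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  if (any(ref == alt)) abort("ref and alt must differ.")
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt))) {
    abort("alleles must be non-empty ACGT strings.")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L
  transitions <- c("A>G", "G>A", "C>T", "T>C")
  sub_l <- ifelse(is_snv, paste0(ref, ">", alt), NA_character_)
  sub_h <- ifelse(is_snv, paste0(comp[ref], ">", comp[alt]), NA_character_)
  tibble::tibble(
    ref = ref,
    alt = alt,
    vtype = dplyr::case_when(
      is_snv ~ "SNV",
      nchar(ref) > nchar(alt) ~ "deletion",
      TRUE ~ "insertion"
    ),
    subclass = dplyr::case_when(
      is_snv & sub_l %in% transitions ~ "transition",
      is_snv ~ "transversion",
      nchar(ref) > nchar(alt) ~ paste0("del_", nchar(ref) - nchar(alt), "bp"),
      TRUE ~ paste0("ins_", nchar(alt) - nchar(ref), "bp")
    ),
    substitution_l = sub_l,
    substitution_h = unname(sub_h)
  )
}

#' Aggregate per-sample calls into distinct-variant summaries
#'
#' Collapses filtered calls to one row per distinct `(pos, ref, alt)`,
#' recording the carrier count, population frequency
#' (carriers / `n_samples`), the level category over carriers
#' (`homoplasmic_only`, `heteroplasmic_only`, or `both`), the maximum
#' heteroplasmic VAF among heteroplasmic carriers (`NA` when none), the
#' variant type, region annotation and singleton status.
#'
#' @param calls Filtered call tibble from [filter_variant_calls()].
#' @param n_samples Number of QC-retained samples (the frequency
#'   denominator); must be at least the carrier count of every variant.
#' @param region_table Flattened region table; default [mt_region_table()].
#' @return One-row-per-variant tibble with columns `pos`, `ref`, `alt`,
#'   `vtype`, `n_carriers`, `pop_freq`, `level_category`, `max_het_level`,
#'   `region`, `region_class`, `singleton`, `freq_category`.
#' @export
aggregate_variants <- function(calls, n_samples,
                               region_table = mt_region_table()) {
  if (nrow(calls) == 0L) {
    return(tibble::tibble(
      pos = integer(0), ref = character(0), alt = character(0),
      vtype = character(0), n_carriers = integer(0), pop_freq = double(0),
      level_category = character(0), max_het_level = double(0),
      region = character(0), region_class = character(0),
      singleton = logical(0), freq_category = character(0)))
  }
  out <- calls |>
    dplyr::group_by(.data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      n_carriers = dplyr::n_distinct(.data$sample_id),
      any_hom = any(.data$level == "homoplasmic"),
      any_het = any(.data$level == "heteroplasmic"),
      max_het_level = ifelse(any(.data$level == "heteroplasmic"),
                             max(.data$vaf[.data$level == "heteroplasmic"]),
                             NA_real_),
      .groups = "drop"
    )
  if (any(out$n_carriers > n_samples)) {
    abort("n_samples is smaller than a variant's carrier count.")
  }
  vt <- classify_variant_type(out$ref, out$alt)
  ann <- annotate_region(out$pos, region_table)
  out |>
    dplyr::mutate(
      vtype = vt$vtype,
      pop_freq = .data$n_carriers / n_samples,
      level_category = dplyr::case_when(
        .data$any_hom & .data$any_het ~ "both",
        .data$any_hom ~ "homoplasmic_only",
        TRUE ~ "heteroplasmic_only"
      ),
      region = ann$region_name,
      region_class = ann$region_class,
      singleton = .data$n_carriers == 1L,
      freq_category = frequency_category(.data$n_carriers, n_samples)
    ) |>
    dplyr::select("pos", "ref", "alt", "vtype", "n_carriers", "pop_freq",
                  "level_category", "max_het_level", "region",
                  "region_class", "singleton", "freq_category") |>
    dplyr::arrange(.data$pos, .data$ref, .data$alt)
}

#' Carrier frequency of a variant or NUMT in a cohort
#'
#' The population frequency used throughout: carriers divided by the
#' QC-retained cohort size.
#'
#' @param n_carriers Carrier count (vectorised).
#' @param n_samples Cohort size.
#' @return Numeric frequency in `[0, 1]`.
#' @export
#' @examples
#' carrier_frequency(6, 4064)
carrier_frequency <- function(n_carriers, n_samples) {
  if (any(n_samples <= 0) || any(n_carriers < 0) ||
      any(n_carriers > n_samples)) {
    abort("need 0 <= n_carriers <= n_samples with n_samples > 0.")
  }
  n_carriers / n_samples
}

#' Population frequency category of a variant
#'
#' Variants are binned by carrier frequency F = carriers / samples:
#' `private` when carried by exactly one person (checked first), `common`
#' when F >= 1%, `rare` when 0.1% <= F < 1%, and `ultra_rare` when F < 0.1%.
#'
#' @param n_carriers Positive integer vector of carrier counts.
#' @param n_samples Cohort size (scalar or vector).
#' @return Character vector of categories.
#' @export
#' @examples
#' frequency_category(c(1, 8, 74), 7324)
frequency_category <- function(n_carriers, n_samples) {
  if (any(n_carriers < 1) || any(n_carriers > n_samples)) {
    abort("need 1 <= n_carriers <= n_samples.")
  }
  f <- n_carriers / n_samples
  dplyr::case_when(
    n_carriers == 1 ~ "private",
    f >= 0.01 ~ "common",
    f >= 0.001 ~ "rare",
    TRUE ~ "ultra_rare"
  )
}

#' Per-region enrichment of variant positions (hypergeometric)
#'
#' Tests whether a region carries more distinct variant positions than
#' expected if the observed positions were drawn uniformly without
#' replacement from the genome: a one-tailed (upper) hypergeometric test
#' with the region length as the number of "success" positions out of
#' `genome_len`.
#'
#' @param observed_counts_by_region Tibble with `region` and `observed`
#'   (distinct variant positions falling in the region).
#' @param background_lengths Tibble with `region` and `length` in bp.
#' @param genome_len Total genome length (default 16,569).
#' @return Input joined with `expected` and upper-tail `p_value`.
#' @export
region_enrichment <- function(observed_counts_by_region, background_lengths,
                              genome_len = MT_GENOME_LENGTH) {
  d <- dplyr::inner_join(observed_counts_by_region, background_lengths,
                         by = "region")
  if (any(d$length <= 0)) abort("region lengths must be positive.")
  if (any(d$observed > d$length)) abort("observed exceeds region length.")
  k <- sum(d$observed)
  d |>
    dplyr::mutate(
      expected = k * .data$length / genome_len,
      p_value = phyper(.data$observed - 1, .data$length,
                       genome_len - .data$length, k, lower.tail = FALSE)
    )
}

#' Bin a MitoTIP pathogenicity score for tRNA variants
#'
#' MitoTIP scores of tRNA variants are binned as: likely pathogenic
#' (score > 16.25), possibly pathogenic (12.66, 16.25], possibly benign
#' (8.44, 12.66], likely benign (score <= 8.44). Scores exactly on a
#' boundary fall in the lower bin.
#'
#' @param score Numeric MitoTIP score vector.
#' @return Character vector of pathogenicity bins.
#' @export
#' @examples
#' classify_mitotip(c(17, 16.25, 10, 5))
classify_mitotip <- function(score) {
  dplyr::case_when(
    score > 16.25 ~ "likely_pathogenic",
    score > 12.66 ~ "possibly_pathogenic",
    score > 8.44 ~ "possibly_benign",
    TRUE ~ "likely_benign"
  )
}

#' Per-sample nDNA:mtDNA depth-ratio diagnostic
#'
#' Reports each sample's ratio of autosomal to mitochondrial mean depth and
#' whether it stays below the bound under which reads from a single nuclear
#' locus cannot mimic a heteroplasmy at VAF 0.1 or above. A diagnostic
#' report, not a filter.
#'
#' @param qcs QC tibble as in [filter_samples()].
#' @param max_ratio Diagnostic bound (default 0.04).
#' @return Tibble of `sample_id`, `depth_ratio`, `within_bound`.
#' @export
depth_ratio_report <- function(qcs, max_ratio = 0.04) {
  tibble::tibble(
    sample_id = qcs$sample_id,
    depth_ratio = qcs$mean_autosomal_depth / qcs$mean_mt_depth,
    within_bound = qcs$mean_autosomal_depth / qcs$mean_mt_depth < max_ratio
  )
}
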