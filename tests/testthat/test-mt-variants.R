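test_that("VAF and copy-number arithmetic follow their definitions", {
  expect_equal(compute_vaf(50, 100), 0.5)
  expect_equal(compute_vaf(100, 100), 1)
  expect_equal(compute_vaf(9, 100), 0.09)
  expect_error(compute_vaf(5, 0), "DP")
  expect_error(compute_vaf(101, 100), "AD")

  expect_equal(compute_mt_copy_number(3000, 31), 3000 / 31 * 2)
  expect_equal(compute_mt_copy_number(100, 100), 2)
  expect_equal(compute_mt_copy_number(775, 31), 50)
  expect_error(compute_mt_copy_number(0, 31), "positive")
})

test_that("sample QC drops on contamination, copy number and insert size with reasons", {
  qcs <- tibble::tibble(
    sample_id = c("a", "b", "c", "d", "e"),
    mean_mt_depth = c(499, 3000, 775, 3000, 3000),
    mean_autosomal_depth = c(20, 30, 31, 30, 30),
    contamination_fraction = c(0, 0.021, 0, 0.02, 0),
    mt_contaminated_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    median_insert_size = c(400, 400, 250, 249, 400))
  r <- filter_samples(qcs)
  # a: CN (499/20)*2 = 49.9 < 50; b: contamination 0.021 > 0.02; e: flag.
  expect_setequal(r$kept$sample_id, c("c", "d")) # 0.02 itself is kept
  expect_equal(r$dropped$reason[r$dropped$sample_id == "a"], "copy_number")
  expect_equal(r$dropped$reason[r$dropped$sample_id == "b"], "contamination")
  expect_equal(r$dropped$reason[r$dropped$sample_id == "e"],
               "mt_contamination_flag")

  rn <- filter_samples(qcs, for_numt = TRUE)
  expect_setequal(rn$kept$sample_id, c("a", "b", "c", "e")) # 250 kept
  expect_equal(rn$dropped$reason, "insert_size")
})

test_that("variant-call filtering enforces PASS, DP > 100, artifact set and VAF >= 0.1", {
  rec <- tibble::tibble(
    sample_id = "s", chrom = "chrM",
    pos = c(5000L, 5001L, 3107L, 5002L, 5003L),
    ref = "A", alt = "C",
    filter = c("PASS", "PASS", "PASS", "base_qual", "PASS"),
    ad = c(18L, 50L, 250L, 80L, 9L),
    dp = c(150L, 100L, 500L, 200L, 100000L))
  kept <- filter_variant_calls(rec)
  # 5001 has dp exactly 100 (not > 100); 3107 is an artifact site; 5002 is
  # not PASS; 5003 has VAF 9e-5.
  expect_equal(kept$pos, 5000L)
  expect_equal(kept$vaf, 18 / 150)
  expect_equal(kept$level, "heteroplasmic")
})

test_that("heteroplasmy bins split exactly at VAF 0.95 with 0.10 inclusive", {
  expect_equal(classify_heteroplasmy(c(0.95, 0.10, 0.949, 1)),
               c("homoplasmic", "heteroplasmic", "heteroplasmic",
                 "homoplasmic"))
  expect_error(classify_heteroplasmy(0.09), "filter")
})

test_that("variant typing distinguishes SNV classes and indel lengths on both strands", {
  snv <- classify_variant_type("G", "A")
  expect_equal(snv$vtype, "SNV")
  expect_equal(snv$subclass, "transition")
  expect_equal(snv$substitution_l, "G>A")
  expect_equal(snv$substitution_h, "C>T") # reverse complement pair

  tv <- classify_variant_type("C", "A")
  expect_equal(tv$subclass, "transversion")

  del <- classify_variant_type("CCCCTCT", "C")
  expect_equal(del$vtype, "deletion")
  expect_equal(del$subclass, "del_6bp")

  ins <- classify_variant_type("A", "AT")
  expect_equal(ins$vtype, "insertion")
  expect_equal(ins$subclass, "ins_1bp")

  expect_error(classify_variant_type("A", "A"), "differ")
  expect_error(classify_variant_type("N", "A"), "ACGT")
})

test_that("aggregation yields one summary per variant with level categories and frequencies", {
  calls <- tibble::tibble(
    sample_id = c("s1", "s1", "s2", paste0("h", 1:10)),
    pos = c(100L, 200L, 200L, rep(300L, 10)),
    ref = "A", alt = "G",
    vaf = c(0.4, 0.3, 0.99, rep(1, 10)),
    dp = 1000L,
    level = c("heteroplasmic", "heteroplasmic", "homoplasmic",
              rep("homoplasmic", 10)))
  s <- aggregate_variants(calls, 100)
  expect_equal(nrow(s), 3L)
  expect_equal(s$level_category[s$pos == 100], "heteroplasmic_only")
  expect_true(s$singleton[s$pos == 100])
  expect_equal(s$level_category[s$pos == 200], "both")
  expect_equal(s$max_het_level[s$pos == 200], 0.3)
  expect_equal(s$level_category[s$pos == 300], "homoplasmic_only")
  expect_equal(s$pop_freq[s$pos == 300], 0.1)
  expect_true(is.na(s$max_het_level[s$pos == 300]))
  # the three categories partition the summaries
  expect_true(all(s$level_category %in%
                    c("homoplasmic_only", "heteroplasmic_only", "both")))
  expect_error(aggregate_variants(calls, 5), "n_samples")
})

test_that("frequency categories match the published bins and are monotone", {
  expect_equal(frequency_category(1, 7324), "private")
  expect_equal(frequency_category(74, 7324), "common")   # ~1.01%
  expect_equal(frequency_category(8, 7324), "rare")      # ~0.109%
  expect_equal(frequency_category(7, 7324), "ultra_rare")
  expect_error(frequency_category(0, 100), "n_carriers")
  # monotone in carrier count at fixed cohort size
  lev <- c(private = 0, ultra_rare = 1, rare = 2, common = 3)
  ranks <- lev[frequency_category(2:7324, 7324)]
  expect_true(all(diff(ranks) >= 0))
})

test_that("the region table tiles the genome and annotates marker positions", {
  tbl <- mt_region_table()
  expect_equal(sum(tbl$end - tbl$start + 1), mt_genome_length())
  expect_true(all(tbl$start[-1] == tbl$end[-nrow(tbl)] + 1)) # disjoint tiling
  ann <- annotate_region(c(300L, 11778L, 1555L, 3230L))
  expect_equal(ann$region_class,
               c("D-loop", "protein_coding", "rRNA", "tRNA"))
  expect_equal(ann$region_name[2:3], c("MT-ND4", "MT-RNR1"))
  expect_error(annotate_region(0), "1..16")
  expect_error(annotate_region(16570), "1..16")
})

test_that("region enrichment matches the exact combinatorial tail", {
  # all 10 variants inside a 100 bp region of a 1000 bp toy genome
  obs <- tibble::tibble(region = c("hot", "rest"), observed = c(10L, 0L))
  len <- tibble::tibble(region = c("hot", "rest"), length = c(100, 900))
  r <- region_enrichment(obs, len, genome_len = 1000)
  exact <- choose(100, 10) / choose(1000, 10)
  expect_equal(r$p_value[r$region == "hot"], exact, tolerance = 1e-12)
  # zero observed in a region is never enriched
  expect_equal(r$p_value[r$region == "rest"], 1)
  # observed equal to expectation is unremarkable
  obs2 <- tibble::tibble(region = c("a", "b"), observed = c(1L, 9L))
  len2 <- tibble::tibble(region = c("a", "b"), length = c(100, 900))
  r2 <- region_enrichment(obs2, len2, genome_len = 1000)
  expect_gt(r2$p_value[r2$region == "a"], 0.5)
  expect_error(region_enrichment(obs, dplyr::mutate(len, length = c(0, 900)),
                                 1000), "positive")
})

test_that("MitoTIP bins respect published cut points with boundaries in the lower bin", {
  expect_equal(classify_mitotip(c(17, 10, 5)),
               c("likely_pathogenic", "possibly_benign", "likely_benign"))
  expect_equal(classify_mitotip(c(16.25, 12.66, 8.44)),
               c("possibly_pathogenic", "possibly_benign", "likely_benign"))
})

test_that("retained calls always satisfy the quality invariants on synthetic cohorts", {
  sim <- gen_mt_cohort(15, seed = 42)
  kept <- filter_variant_calls(sim$calls)
  expect_true(all(kept$vaf >= 0.1))
  expect_true(all(kept$dp > 100))
  expect_true(!any(kept$pos %in% mt_artifact_positions()))
})

test_that("depth-ratio diagnostic reports without filtering", {
  qcs <- tibble::tibble(sample_id = c("a", "b"),
                        mean_mt_depth = c(3000, 500),
                        mean_autosomal_depth = c(31, 31),
                        contamination_fraction = 0,
                        mt_contaminated_flag = FALSE,
                        median_insert_size = 400)
  r <- depth_ratio_report(qcs)
  expect_equal(r$within_bound, c(TRUE, FALSE)) # 31/500 = 0.062 > 0.04
  expect_equal(nrow(r), 2L)
})
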