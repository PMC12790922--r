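## Synthetic-data generators. Every generator is deterministic given
## (arguments, seed) and returns its planted truth alongside the data, so
## pipeline-recovery tests compare against the truth table, never against
## re-derived values.

#' Simulate a cohort of per-sample mitochondrial variant calls
#'
#' Emulates deep-coverage mitochondrial pileup calls: a pool of distinct
#' variant sites with population frequencies, each carried call being
#' homoplasmic (true VAF 1) with probability `hom_fraction` or heteroplasmic
#' with true VAF uniform on `het_vaf_range`, with AD drawn binomially at the
#' site depth (or deterministically when `noiseless = TRUE`). Spurious calls
#' are injected to exercise every filter: calls at artifact positions, calls
#' with true VAF below 0.1, low-depth calls, and non-PASS records.
#'
#' @param n_samples Cohort size.
#' @param depth_mean Mean site depth (default 3000, deep mtDNA coverage).
#' @param n_sites Size of the variant site pool (default 120).
#' @param hom_fraction Probability a carried call is homoplasmic
#'   (default 0.978, the homoplasmic share of calls in deep cohorts).
#' @param het_vaf_range True heteroplasmic VAF range (default c(0.12, 0.90),
#'   held off the 0.10/0.95 bin boundaries so binomial depth noise cannot
#'   flip a class).
#' @param vtype_probs Probabilities of SNV/insertion/deletion sites
#'   (default c(0.96, 0.02, 0.02)).
#' @param artifact_noise_rate Per-sample expected count of artifact-site
#'   calls (default 2).
#' @param lowvaf_noise_rate Per-sample expected count of sub-0.1-VAF calls
#'   (default 2).
#' @param lowdepth_noise_rate Per-sample expected count of low-depth calls
#'   (default 1).
#' @param fail_filter_rate Per-sample expected count of non-PASS records
#'   (default 1).
#' @param noiseless Draw AD as round(VAF x DP) instead of binomially.
#' @param seed RNG seed.
#' @param out_dir When given, one VCF per sample is written there.
#' @return List with `calls` (raw record tibble in [read_mt_vcf()] layout),
#'   `truth` (per planted call: `sample_id`, `pos`, `ref`, `alt`,
#'   `true_vaf`, `true_level`, `category`), `site_pool`, `paths` (VCF paths
#'   or NULL), and `seed`.
#' @export
gen_mt_cohort <- function(n_samples, depth_mean = 3000, n_sites = 120,
                          hom_fraction = 0.978,
                          het_vaf_range = c(0.12, 0.90),
                          vtype_probs = c(SNV = 0.96, insertion = 0.02,
                                          deletion = 0.02),
                          artifact_noise_rate = 2, lowvaf_noise_rate = 2,
                          lowdepth_noise_rate = 1, fail_filter_rate = 1,
                          noiseless = FALSE, seed = 1L, out_dir = NULL) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  artifacts <- mt_artifact_positions()
  ok_pos <- setdiff(seq_len(MT_GENOME_LENGTH), artifacts)

  pos <- sample(ok_pos, n_sites)
  vtype <- sample(names(vtype_probs), n_sites, replace = TRUE,
                  prob = vtype_probs)
  ref <- character(n_sites)
  alt <- character(n_sites)
  for (i in seq_len(n_sites)) {
    anchor <- sample(bases, 1)
    if (vtype[i] == "SNV") {
      ref[i] <- anchor
      alt[i] <- sample(setdiff(bases, anchor), 1)
    } else if (vtype[i] == "insertion") {
      ref[i] <- anchor
      alt[i] <- paste0(anchor, paste(sample(bases, sample(1:3, 1),
                                            replace = TRUE), collapse = ""))
    } else {
      ref[i] <- paste0(anchor, paste(sample(bases, sample(1:3, 1),
                                            replace = TRUE), collapse = ""))
      alt[i] <- anchor
    }
  }
  ## Mostly-rare frequency spectrum with a common tail.
  freq <- stats::rbeta(n_sites, 0.3, 3)
  freq <- pmin(pmax(freq, 1 / n_samples), 0.9)
  site_pool <- tibble::tibble(pos = pos, ref = ref, alt = alt,
                              vtype = vtype, pop_freq = freq)

  draw_dp <- function(n) pmax(rpois(n, depth_mean), 150L)
  draw_ad <- function(vaf, dp) {
    if (noiseless) as.integer(round(vaf * dp)) else rbinom(length(dp), dp, vaf)
  }

  calls_list <- vector("list", n_samples)
  truth_list <- vector("list", n_samples)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  for (s in seq_len(n_samples)) {
    carried <- which(runif(n_sites) < freq)
    n_c <- length(carried)
    is_hom <- runif(n_c) < hom_fraction
    true_vaf <- ifelse(is_hom, 1,
                       runif(n_c, het_vaf_range[1], het_vaf_range[2]))
    dp <- draw_dp(n_c)
    ad <- pmin(draw_ad(true_vaf, dp), dp)
    real <- tibble::tibble(
      sample_id = sample_ids[s], pos = pos[carried], ref = ref[carried],
      alt = alt[carried], filter = "PASS", ad = ad, dp = dp,
      true_vaf = true_vaf,
      true_level = ifelse(is_hom, "homoplasmic", "heteroplasmic"),
      category = "real")

    mk_noise <- function(n, positions, vaf_lo, vaf_hi, dp_draw, filt, cat) {
      if (n == 0L) return(NULL)
      p <- sample(positions, n)
      r <- sample(bases, n, replace = TRUE)
      a <- vapply(r, function(b) sample(setdiff(bases, b), 1), character(1))
      v <- runif(n, vaf_lo, vaf_hi)
      d <- dp_draw(n)
      tibble::tibble(sample_id = sample_ids[s], pos = p, ref = r, alt = a,
                     filter = filt, ad = pmin(draw_ad(v, d), d), dp = d,
                     true_vaf = v, true_level = NA_character_,
                     category = cat)
    }
    noise <- dplyr::bind_rows(
      mk_noise(rpois(1, artifact_noise_rate), artifacts, 0.1, 0.4,
               draw_dp, "PASS", "artifact_site"),
      mk_noise(rpois(1, lowvaf_noise_rate), ok_pos, 0.02, 0.05,
               draw_dp, "PASS", "low_vaf"),
      mk_noise(rpois(1, lowdepth_noise_rate), ok_pos, 0.3, 0.9,
               function(n) sample(20:100, n, replace = TRUE), "PASS",
               "low_depth"),
      mk_noise(rpois(1, fail_filter_rate), ok_pos, 0.3, 0.9,
               draw_dp, "base_qual", "fail_filter")
    )
    all_s <- dplyr::bind_rows(real, noise) |>
      dplyr::distinct(.data$pos, .keep_all = TRUE) |>
      dplyr::arrange(.data$pos)
    calls_list[[s]] <- dplyr::select(all_s, "sample_id", "pos", "ref",
                                     "alt", "filter", "ad", "dp")
    truth_list[[s]] <- dplyr::select(all_s, "sample_id", "pos", "ref",
                                     "alt", "true_vaf", "true_level",
                                     "category")
  }
  calls <- dplyr::bind_rows(calls_list) |>
    dplyr::mutate(chrom = "chrM",
                  is_artifact = .data$pos %in% artifacts,
                  .after = "sample_id")
  truth <- dplyr::bind_rows(truth_list)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(sample_ids, function(sid) {
      f <- file.path(out_dir, paste0(sid, ".vcf"))
      write_mt_vcf(dplyr::filter(calls, .data$sample_id == sid), f, sid)
      f
    }, character(1))
  }
  list(calls = calls, truth = truth, site_pool = site_pool, paths = paths,
       seed = seed)
}

#' Write calls as a minimal single-sample mitochondrial VCF
#'
#' Emits a VCF 4.2 file with FORMAT `GT:AD:DP`, suitable for round-tripping
#' through [read_mt_vcf()].
#'
#' @param calls Call tibble (columns `pos`, `ref`, `alt`, `filter`, `ad`,
#'   `dp`).
#' @param path Output path.
#' @param sample_id Sample column name.
#' @return `path`, invisibly.
#' @export
write_mt_vcf <- function(calls, path, sample_id) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrM,length=%d>", MT_GENOME_LENGTH),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  body <- sprintf("chrM\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:AD:DP\t0/1:%d,%d:%d",
                  calls$pos, calls$ref, calls$alt, calls$filter,
                  calls$dp - calls$ad, calls$ad, calls$dp)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate paired-end evidence around planted NUMT insertions
#'
#' Plants insertions of random mitochondrial arcs (on the circular
#' 16,569 bp genome, origin-spanning arcs included) at well-separated
#' nuclear positions, and emits the aligned evidence the detector consumes:
#' discordant pairs whose nuclear mates fall within one insert size of the
#' junction, split reads whose segment junctions equal the planted
#' breakpoints exactly (at least `split_reads[1]` per junction side), and
#' background concordant pairs. Sub-threshold decoy insertions (fewer than
#' five supporting pairs, no split reads) are planted as negative controls.
#'
#' @param n_insertions Number of detectable planted insertions.
#' @param n_decoys Number of sub-threshold decoys (default 0).
#' @param nuclear_len Length of the synthetic nuclear contig `chr1`
#'   (default 5e6).
#' @param carriers_range Carriers per insertion, sampled uniformly
#'   (default c(1, 3)).
#' @param support_pairs Range of discordant pairs per carrier
#'   (default c(5, 12)).
#' @param split_reads Range of split reads per junction side per carrier
#'   (default c(2, 4)).
#' @param decoy_pairs Range of pairs per decoy carrier (default c(1, 4)).
#' @param arc_len_range Inserted arc length range in bp (default c(5, 8000);
#'   lengths below 5 are rejected).
#' @param insert_size Library insert size (default 500).
#' @param read_len Read length (default 150).
#' @param n_samples Cohort size carriers are drawn from (default 20).
#' @param background_pairs Concordant nuclear-nuclear noise pairs
#'   (default 200).
#' @param seed RNG seed.
#' @return List with `records` (alignment record tibble in
#'   [read_alignment_records()] layout), `truth` (one row per planted
#'   insertion: breakpoints, arc, carriers, support, `is_decoy`),
#'   `samples`, and `seed`.
#' @export
gen_numt_reads <- function(n_insertions, n_decoys = 0, nuclear_len = 5e6,
                           carriers_range = c(1, 3),
                           support_pairs = c(5, 12), split_reads = c(2, 4),
                           decoy_pairs = c(1, 4),
                           arc_len_range = c(5, 8000), insert_size = 500,
                           read_len = 150, n_samples = 20,
                           background_pairs = 200, seed = 1L) {
  if (insert_size < 2 * read_len) abort("insert_size must be >= 2 x read_len.")
  if (arc_len_range[1] < 5) abort("inserted arcs below 5 bp are not modelled.")
  set.seed(seed)
  n_total <- n_insertions + n_decoys
  sep <- 2 * insert_size + 1000 + 2000 # keep events un-mergeable
  sites <- sort(sample(seq(10000, nuclear_len - 10000, by = sep), n_total))
  sites <- sample(sites) # random assignment to real/decoy
  samples <- sprintf("N%03d", seq_len(n_samples))

  rec <- list()
  truth <- list()
  rid <- 0L
  next_id <- function() {
    rid <<- rid + 1L
    sprintf("r%06d", rid)
  }

  for (i in seq_len(n_total)) {
    is_decoy <- i > n_insertions
    P <- sites[i]
    a <- sample.int(MT_GENOME_LENGTH, 1)
    arc_len <- sample(seq(arc_len_range[1], arc_len_range[2]), 1)
    b <- ((a - 1 + arc_len) %% MT_GENOME_LENGTH) + 1L
    n_carr <- sample(seq(carriers_range[1], carriers_range[2]), 1)
    carr <- sample(samples, n_carr)
    pair_rng <- if (is_decoy) decoy_pairs else support_pairs
    n_split_side <- if (is_decoy) 0L else sample(seq(split_reads[1], split_reads[2]), 1)
    tot_pairs <- 0L
    for (sm in carr) {
      n_pairs <- sample(seq(pair_rng[1], pair_rng[2]), 1)
      tot_pairs <- tot_pairs + n_pairs
      for (k in seq_len(n_pairs)) {
        left_side <- runif(1) < 0.5
        nuc_pos <- if (left_side) {
          P - sample(seq(read_len, insert_size - read_len), 1)
        } else {
          P + 1 + sample(seq(0, insert_size - 2 * read_len), 1)
        }
        mito_pos <- circular_arc_positions(a, arc_len)[sample(arc_len, 1)]
        rec[[length(rec) + 1L]] <- tibble::tibble(
          read_id = next_id(), sample_id = sm, chrom = "chr1",
          pos = as.integer(nuc_pos), strand = "+", mate_chrom = "chrM",
          mate_pos = as.integer(mito_pos), mate_strand = "+",
          is_split = FALSE, segments = NA_character_, mapq = 60L)
      }
      if (n_split_side > 0L) {
        for (k in seq_len(n_split_side)) {
          ## Left junction: nuclear segment ends at P, mito starts at a.
          nl <- sample(seq(40, read_len - 40), 1)
          ml <- read_len - nl
          m_end <- ((a - 1 + ml - 1) %% MT_GENOME_LENGTH) + 1L
          rec[[length(rec) + 1L]] <- tibble::tibble(
            read_id = next_id(), sample_id = sm, chrom = "chr1",
            pos = as.integer(P - nl + 1), strand = "+", mate_chrom = "chr1",
            mate_pos = as.integer(P - insert_size), mate_strand = "+",
            is_split = TRUE,
            segments = sprintf("chr1:%d-%d;chrM:%d-%d", P - nl + 1, P, a, m_end),
            mapq = 60L)
          ## Right junction: mito segment ends at b, nuclear starts at P+1.
          nr <- sample(seq(40, read_len - 40), 1)
          mr <- read_len - nr
          m_start <- ((b - 1 - (mr - 1)) %% MT_GENOME_LENGTH) + 1L
          rec[[length(rec) + 1L]] <- tibble::tibble(
            read_id = next_id(), sample_id = sm, chrom = "chrM",
            pos = as.integer(m_start), strand = "+", mate_chrom = "chr1",
            mate_pos = as.integer(P + insert_size), mate_strand = "+",
            is_split = TRUE,
            segments = sprintf("chrM:%d-%d;chr1:%d-%d", m_start, b, P + 1, P + nr),
            mapq = 60L)
        }
      }
    }
    truth[[length(truth) + 1L]] <- tibble::tibble(
      insertion_id = sprintf("ins%03d", i), nuclear_chrom = "chr1",
      nuclear_bp_left = as.integer(P), nuclear_bp_right = as.integer(P + 1),
      mito_bp_a = as.integer(a), mito_bp_b = as.integer(b),
      arc_len = as.integer(arc_len), carriers = list(sort(carr)),
      n_carriers = n_carr, n_support_pairs = tot_pairs,
      n_split_per_side = n_split_side, is_decoy = is_decoy)
  }

  ## Concordant nuclear background (never discordant to chrM).
  if (background_pairs > 0L) {
    bp <- sample.int(nuclear_len - 1000, background_pairs)
    rec[[length(rec) + 1L]] <- tibble::tibble(
      read_id = vapply(seq_len(background_pairs), function(i) next_id(),
                       character(1)),
      sample_id = sample(samples, background_pairs, replace = TRUE),
      chrom = "chr1", pos = as.integer(bp), strand = "+",
      mate_chrom = "chr1", mate_pos = as.integer(bp + insert_size),
      mate_strand = "-", is_split = FALSE, segments = NA_character_,
      mapq = 60L)
  }
  list(records = dplyr::bind_rows(rec), truth = dplyr::bind_rows(truth),
       samples = samples, seed = seed)
}

#' Simulate a genotype matrix with planted linear effects on heteroplasmy
#'
#' Genotypes are binomial(2, p) dosages with per-SNP allele frequencies
#' uniform on `maf_range`; optional two-population structure shifts the
#' allele frequencies of a subset of SNPs between two equal halves of the
#' cohort. The continuous phenotype mimics a heteroplasmic level: a baseline
#' plus the planted dosage effects, an optional population confound, and
#' gaussian noise, truncated to `[0, 1]`.
#'
#' @param n Samples.
#' @param n_snps Nuclear variants.
#' @param n_causal Number of causal variants (first `n_causal` columns).
#' @param beta Effect per dosage unit of each causal variant.
#' @param maf_range Allele-frequency range (default c(0.05, 0.5)).
#' @param two_pop Add two-population structure.
#' @param pop_shift Allele-frequency shift of structured SNPs between
#'   populations (default 0.2; only with `two_pop`).
#' @param frac_structured Fraction of SNPs carrying the shift
#'   (default 0.3).
#' @param confound Phenotype offset added to population 2 (creates
#'   stratification confounding; default 0).
#' @param noise_sd Residual SD (default 0.05).
#' @param baseline Phenotype baseline (default 0.4).
#' @param missing_rate Fraction of dosages set missing (default 0).
#' @param seed RNG seed.
#' @return List with `gmat` (n x n_snps dosage matrix, dimnames set), `sex`
#'   (0/1 covariate), `pop` (1/2), `phenotype`, and `truth` (tibble of
#'   causal `variant_id`, `beta`).
#' @export
gen_assoc_dataset <- function(n, n_snps, n_causal = 0, beta = 0,
                              maf_range = c(0.05, 0.5), two_pop = FALSE,
                              pop_shift = 0.2, frac_structured = 0.3,
                              confound = 0, noise_sd = 0.05,
                              baseline = 0.4, missing_rate = 0, seed = 1L) {
  if (n_causal > n_snps) abort("n_causal must not exceed n_snps.")
  set.seed(seed)
  p <- runif(n_snps, maf_range[1], maf_range[2])
  pop <- rep(1:2, length.out = n)
  gmat <- matrix(NA_real_, n, n_snps)
  if (two_pop) {
    structured <- seq_len(n_snps) %in%
      sample.int(n_snps, round(frac_structured * n_snps))
    p1 <- ifelse(structured, pmin(pmax(p - pop_shift / 2, 0.01), 0.99), p)
    p2 <- ifelse(structured, pmin(pmax(p + pop_shift / 2, 0.01), 0.99), p)
    for (j in seq_len(n_snps)) {
      gmat[, j] <- rbinom(n, 2, ifelse(pop == 1, p1[j], p2[j]))
    }
  } else {
    for (j in seq_len(n_snps)) gmat[, j] <- rbinom(n, 2, p[j])
  }
  dimnames(gmat) <- list(sprintf("A%05d", seq_len(n)),
                         sprintf("rs%06d", seq_len(n_snps)))
  betas <- rep(beta, length.out = n_causal)
  causal <- seq_len(n_causal)
  eff <- if (n_causal > 0) gmat[, causal, drop = FALSE] %*% betas else 0
  phen <- baseline + as.vector(eff) + confound * (pop == 2) +
    rnorm(n, 0, noise_sd)
  phen <- pmin(pmax(phen, 0), 1)
  if (missing_rate > 0) {
    miss <- runif(n * n_snps) < missing_rate
    gmat[miss] <- NA_real_
  }
  list(
    gmat = gmat,
    sex = rbinom(n, 1, 0.5),
    pop = pop,
    phenotype = phen,
    truth = tibble::tibble(variant_id = colnames(gmat)[causal],
                           beta = betas),
    seed = seed
  )
}

#' Simulate annotation tracks as random non-overlapping intervals
#'
#' For each requested track, draws interval lengths (exponential around
#' `mean_len`) until the requested coverage fraction of each chromosome is
#' reached exactly (the last interval is trimmed), then places the
#' intervals uniformly without overlap.
#'
#' @param chrom_sizes Tibble `chrom`, `size`.
#' @param track_specs Named numeric vector or list of coverage fractions in
#'   (0, 1], e.g. `c(LINE = 0.2, simple_repeat = 0.05)`.
#' @param mean_len Mean interval length (default 1000 bp).
#' @param seed RNG seed.
#' @return Named list of interval tibbles (0-based half-open, BED layout
#'   with `feature_class` set to the track name).
#' @export
gen_annotation_tracks <- function(chrom_sizes, track_specs, mean_len = 1000,
                                  seed = 1L) {
  set.seed(seed)
  cov <- unlist(track_specs)
  if (any(cov <= 0) || any(cov > 1)) {
    abort("track coverage fractions must lie in (0, 1].")
  }
  out <- purrr::imap(as.list(cov), function(frac, nm) {
    per_chrom <- purrr::map2(chrom_sizes$chrom, chrom_sizes$size,
                             function(cn, sz) {
      target <- round(frac * sz)
      if (target >= sz) {
        return(tibble::tibble(chrom = cn, start = 0, end = sz))
      }
      lens <- integer(0)
      while (sum(lens) < target) {
        lens <- c(lens, pmax(50L, as.integer(rexp(64, 1 / mean_len))))
      }
      lens <- lens[cumsum(lens) - lens < target]
      lens[length(lens)] <- target - sum(lens[-length(lens)])
      free <- sz - sum(lens)
      gaps <- sort(runif(length(lens), 0, free))
      starts <- floor(gaps) + c(0, cumsum(lens[-length(lens)]))
      tibble::tibble(chrom = cn, start = starts, end = starts + lens)
    })
    dplyr::bind_rows(per_chrom) |>
      dplyr::mutate(name = paste0(nm, "_", dplyr::row_number()),
                    feature_class = nm)
  })
  out
}
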