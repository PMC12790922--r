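#' Default pipeline configuration
#'
#' Builds the full configuration for [run_pipeline()] with every module
#' threshold at its standard value: contamination 0.02, copy number 50,
#' depth 100, VAF 0.1, homoplasmy bound 0.95, discordant-cluster gap 500 bp
#' with 5 supporting pairs, event grouping 1000 bp, 2 split reads within
#' 500 bp flanks, insert size 250 bp, permutation flank 100 bp with 10,000
#' permutations, significance 0.05 and 5e-8 over the number of mtDNA
#' phenotypes (autodetected when `n_mt` is `NULL`), call rates 0.9, MAF
#' 0.05, HWE 1e-6, 12 PCs. Any override is echoed to the run log.
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param out_dir Run directory.
#' @param ... Named overrides of default entries (nested lists are merged
#'   shallowly per stage).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("mitorun"), ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    stages = c("simulate", "mt_variants", "invariable", "numt", "enrich",
               "assoc"),
    simulate = list(n_samples = 50, depth_mean = 3000, n_insertions = 10,
                    n_decoys = 5, n_assoc_samples = 400, n_snps = 300,
                    n_causal = 2, beta = 0.1),
    mt_variants = list(max_contamination = 0.02, min_copy_number = 50,
                       min_dp = 100, min_vaf = 0.1, hom_threshold = 0.95),
    numt = list(min_insert_size = 250, min_mapq = 20, max_gap = 500,
                min_pairs = 5, group_dist = 1000, refine_flank = 500,
                min_split = 2, known_pad = 500),
    enrich = list(n_perm = 1000, flank = 100),
    assoc = list(alpha = 0.05, gw = 5e-8, n_mt = NULL,
                 min_variant_call_rate = 0.9, min_sample_call_rate = 0.9,
                 min_maf = 0.05, min_hwe_p = 1e-6, n_pcs = 12,
                 min_mt_freq = 0.05)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Loads overrides from a YAML file on top of [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

validate_config <- function(cfg) {
  numeric_keys <- list(
    c("mt_variants", "max_contamination"), c("mt_variants", "min_copy_number"),
    c("mt_variants", "min_dp"), c("mt_variants", "min_vaf"),
    c("numt", "min_pairs"), c("numt", "max_gap"), c("numt", "group_dist"),
    c("numt", "min_split"), c("enrich", "n_perm"), c("enrich", "flank"),
    c("assoc", "alpha"), c("assoc", "min_maf"), c("assoc", "n_pcs")
  )
  for (key in numeric_keys) {
    val <- cfg[[key[1]]][[key[2]]]
    if (!is.numeric(val) || length(val) != 1L || is.na(val)) {
      abort(sprintf("config key %s.%s must be a single number (got '%s').",
                    key[1], key[2], paste(val, collapse = ",")))
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    abort("config key seed must be a single number.")
  }
  invisible(cfg)
}

log_line <- function(con, stage, msg, ...) {
  entry <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage, msg = msg), list(...))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — synthetic-data generation,
#' mtDNA variant QC and aggregation, invariable-interval extraction, NUMT
#' detection and refinement, breakpoint enrichment, and the mtDNA-nDNA
#' association scan — writing each stage's tables as TSV under the run
#' directory plus a JSON manifest recording the package version, the
#' derived per-stage seeds and the MD5 of every output. A completed stage
#' whose inputs are unchanged is skipped on rerun (idempotence); a failing
#' stage halts only its downstream dependents.
#'
#' @param config A `pipeline_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the run directory, the manifest, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  log_con <- file(file.path(config$out_dir, "run.log"), open = "a")
  on.exit(close(log_con), add = TRUE)

  cfg_hash <- substr(tools::md5sum(
    textConnection_file(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                         force = TRUE))), 1, 32)
  manifest <- list(package_version = as.character(utils::packageVersion("mitocohort")),
                   seed = config$seed, config_md5 = unname(cfg_hash),
                   stages = list())
  results <- list()
  failed <- character(0)

  ## Idempotent writes: an output file whose content is unchanged from the
  ## previous run is left untouched (mtime preserved), so rerunning a
  ## completed stage with unchanged inputs is a no-op on disk.
  write_stage <- function(stage, tables) {
    files <- character(0)
    for (nm in names(tables)) {
      f <- file.path(config$out_dir, sprintf("%s_%s.tsv", stage, nm))
      tmp <- tempfile()
      readr::write_tsv(tables[[nm]], tmp, progress = FALSE)
      if (!file.exists(f) ||
          !identical(unname(tools::md5sum(tmp)), unname(tools::md5sum(f)))) {
        file.copy(tmp, f, overwrite = TRUE)
      } else {
        log_line(log_con, stage, "output up-to-date", file = basename(f))
      }
      unlink(tmp)
      files[nm] <- f
    }
    manifest$stages[[stage]] <<- list(
      seed = derive_seed(config$seed, stage),
      files = as.list(unname(tools::md5sum(files))) |>
        setNames(basename(files)))
    files
  }

  run_stage <- function(stage, deps, fun) {
    if (any(deps %in% failed)) {
      log_line(log_con, stage, "skipped: upstream failure",
               failed_deps = deps[deps %in% failed])
      failed <<- c(failed, stage)
      return(invisible(NULL))
    }
    tryCatch({
      results[[stage]] <<- fun()
      log_line(log_con, stage, "completed")
    }, error = function(e) {
      failed <<- c(failed, stage)
      log_line(log_con, stage, "failed", error = conditionMessage(e))
    })
  }

  ## simulate ---------------------------------------------------------------
  run_stage("simulate", character(0), function() {
    sc <- config$simulate
    mt <- gen_mt_cohort(sc$n_samples, depth_mean = sc$depth_mean,
                        seed = derive_seed(config$seed, "simulate_mt"))
    numt <- gen_numt_reads(sc$n_insertions, n_decoys = sc$n_decoys,
                           seed = derive_seed(config$seed, "simulate_numt"))
    assoc <- gen_assoc_dataset(sc$n_assoc_samples, sc$n_snps,
                               n_causal = sc$n_causal, beta = sc$beta,
                               seed = derive_seed(config$seed, "simulate_assoc"))
    tracks <- gen_annotation_tracks(
      tibble::tibble(chrom = "chr1", size = 5e6),
      c(LINE = 0.2, simple_repeat = 0.05),
      seed = derive_seed(config$seed, "simulate_tracks"))
    write_stage("simulate", list(mt_truth = mt$truth,
                                 numt_truth = dplyr::select(numt$truth, -"carriers")))
    list(mt = mt, numt = numt, assoc = assoc, tracks = tracks)
  })

  ## mt_variants ------------------------------------------------------------
  run_stage("mt_variants", "simulate", function() {
    mc <- config$mt_variants
    sim <- results$simulate
    calls <- filter_variant_calls(sim$mt$calls, min_dp = mc$min_dp,
                                  min_vaf = mc$min_vaf)
    n_samples <- length(unique(sim$mt$calls$sample_id))
    summaries <- aggregate_variants(calls, n_samples)
    write_stage("mt_variants", list(calls = calls, summaries = summaries))
    list(calls = calls, summaries = summaries, n_samples = n_samples)
  })

  ## invariable -------------------------------------------------------------
  run_stage("invariable", "mt_variants", function() {
    summ <- results$mt_variants$summaries
    iv <- invariable_intervals(variable_positions(summ),
                               insertion_anchors(summ))
    stats_tbl <- interval_region_stats(iv)
    write_stage("invariable", list(intervals = iv, region_stats = stats_tbl))
    list(intervals = iv, region_stats = stats_tbl)
  })

  ## numt -------------------------------------------------------------------
  run_stage("numt", "simulate", function() {
    nc <- config$numt
    sim <- results$simulate
    pairs <- select_discordant(sim$numt$records, min_mapq = nc$min_mapq)
    clusters <- cluster_discordant(pairs, max_gap = nc$max_gap,
                                   min_pairs = nc$min_pairs)
    events <- group_events(clusters, max_dist = nc$group_dist) |>
      refine_breakpoints(sim$numt$records, flank = nc$refine_flank,
                         min_split = nc$min_split) |>
      classify_event_frequency(length(sim$numt$samples))
    stats_out <- per_sample_numt_stats(events, sim$numt$samples)
    write_stage("numt", list(events = dplyr::select(events, -"samples"),
                             per_sample = stats_out$per_sample))
    list(events = events, stats = stats_out)
  })

  ## enrich -----------------------------------------------------------------
  run_stage("enrich", "numt", function() {
    ec <- config$enrich
    events <- results$numt$events
    tracks <- results$simulate$tracks
    enr <- enrichment_by_class(
      events, tracks, tibble::tibble(chrom = "chr1", size = 5e6),
      n_perm = ec$n_perm, flank = ec$flank,
      rng_seed = derive_seed(config$seed, "enrich"))
    bp <- c(events$mito_bp_a, events$mito_bp_b)
    bp <- bp[!is.na(bp)]
    nrc <- normalized_region_counts(bp)
    write_stage("enrich", list(enrichment = enr, mito_regions = nrc))
    list(enrichment = enr, mito_regions = nrc)
  })

  ## assoc ------------------------------------------------------------------
  run_stage("assoc", "simulate", function() {
    ac <- config$assoc
    sim <- results$simulate$assoc
    filt <- filter_genotypes(sim$gmat,
                             min_variant_call_rate = ac$min_variant_call_rate,
                             min_sample_call_rate = ac$min_sample_call_rate,
                             min_maf = ac$min_maf, min_hwe_p = ac$min_hwe_p)
    k <- min(ac$n_pcs, nrow(filt$gmat) - 2L, ncol(filt$gmat) - 1L)
    pcs <- genotype_pca(filt$gmat, k = k)
    kept <- rownames(filt$gmat)
    sex <- sim$sex[match(kept, rownames(sim$gmat))]
    phen <- sim$phenotype[match(kept, rownames(sim$gmat))]
    scan <- glm_scan(phen, filt$gmat, covariates = cbind(pcs, sex = sex),
                     mt_variant = "synthetic_het_level")
    n_mt <- ac$n_mt %||% 1L
    hits <- flag_significant(scan, significance_thresholds(ac$alpha, ac$gw,
                                                           n_mt))
    write_stage("assoc", list(scan = hits))
    list(scan = scan, hits = hits)
  })

  manifest$failed_stages <- failed
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(out_dir = config$out_dir, manifest = manifest,
                 results = results, failed = failed))
}

## md5 of an in-memory string via a temp file (tools::md5sum needs a path).
textConnection_file <- function(text) {
  f <- tempfile()
  writeLines(text, f)
  f
}
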