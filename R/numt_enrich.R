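#' Empirical CDF of mitochondrial breakpoints
#'
#' Right-continuous empirical cumulative distribution of NUMT mitochondrial
#' breakpoint positions along the 16,569 bp genome, evaluable at any
#' position. Regions where the ECDF climbs steeply are breakpoint-dense.
#'
#' @param breakpoints Integer vector of 1-based positions in 1..16,569.
#' @return A step function (class `ecdf`).
#' @export
#' @examples
#' f <- mito_breakpoint_ecdf(c(100, 8000, 16000))
#' f(8000)
mito_breakpoint_ecdf <- function(breakpoints) {
  if (length(breakpoints) == 0L) {
    abort("at least one breakpoint is required for an ECDF.")
  }
  if (any(breakpoints < 1 | breakpoints > MT_GENOME_LENGTH)) {
    abort("breakpoints must lie in 1..16,569.")
  }
  ecdf(breakpoints)
}

#' Breakpoints per base across mitochondrial regions
#'
#' Counts mitochondrial breakpoints per region of the flattened annotation
#' and normalises by region length. Normalised counts in short regions are
#' dominated by randomness, so regions shorter than `min_region_len` are
#' reported but flagged `excluded`.
#'
#' @param breakpoints Integer vector of 1-based positions.
#' @param region_table Flattened region table; default [mt_region_table()].
#' @param min_region_len Regions shorter than this are flagged
#'   (default 200 bp).
#' @return Tibble with `region_name`, `region_class`, `length`, `count`,
#'   `per_bp`, `excluded`.
#' @export
normalized_region_counts <- function(breakpoints,
                                     region_table = mt_region_table(),
                                     min_region_len = 200) {
  ann <- if (length(breakpoints) > 0L) {
    annotate_region(breakpoints, region_table)
  } else {
    tibble::tibble(pos = integer(0), region_name = character(0),
                   region_class = character(0))
  }
  ## Tiles of one feature (e.g. the two D-loop spans) are summed per name.
  region_table |>
    dplyr::group_by(.data$region_name, .data$region_class) |>
    dplyr::summarise(length = sum(.data$end - .data$start + 1),
                     .groups = "drop") |>
    dplyr::left_join(dplyr::count(ann, .data$region_name, name = "count"),
                     by = "region_name") |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      per_bp = .data$count / .data$length,
      excluded = .data$length < min_region_len
    ) |>
    dplyr::arrange(dplyr::desc(.data$per_bp))
}

#' Permutation enrichment of nuclear breakpoints against a track
#'
#' Tests whether NUMT nuclear insertion sites fall inside an annotation
#' track (LINEs, simple repeats, genes, ...) more often than uniformly
#' random positions would. Each event's anchor is widened to a +/-`flank`
#' (100 bp) window; `observed` counts events whose window overlaps the
#' track. Each of `n_perm` permutations draws the same number of positions
#' uniformly over the genome defined by `chrom_sizes`, windows them the same
#' way (windows running past a chromosome end are truncated, not discarded),
#' and counts overlaps. The upper-tail p-value carries a +1 pseudocount:
#' p = (#\{null >= observed\} + 1) / (n_perm + 1), so its floor is
#' 1/(n_perm + 1).
#'
#' @param events Tibble with `nuclear_chrom` and `anchor` (1-based
#'   positions).
#' @param track Interval tibble from [read_bed()] (0-based half-open) with
#'   optional `name`/`feature_class`.
#' @param chrom_sizes Tibble `chrom`, `size` for permutation sampling;
#'   contigs absent from it are never drawn.
#' @param n_perm Number of permutations (default 10,000).
#' @param flank Half-window in bp (default 100).
#' @param rng_seed Seed fixing the permutation draw; identical seeds give
#'   identical p-values.
#' @param numt_class Label recorded in the result (default `"all"`).
#' @param track_name Label recorded in the result.
#' @return One-row tibble: `track_name`, `numt_class`, `n_events`,
#'   `observed`, `n_perm`, `null_geq`, `p_value`.
#' @export
nuclear_enrichment_permutation <- function(events, track, chrom_sizes,
                                           n_perm = 10000, flank = 100,
                                           rng_seed = 1L,
                                           numt_class = "all",
                                           track_name = "track") {
  if (nrow(track) == 0L) abort("track must be non-empty.")
  if (nrow(events) == 0L) abort("events must be non-empty.")
  trk <- index_track(bed_to_1based(track))
  sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)

  window_hits <- function(chrom, pos) {
    s <- pmax(1, pos - flank)
    e <- pmin(sizes[chrom], pos + flank)
    overlaps_any_interval(chrom, s, e, trk)
  }

  n_ev <- nrow(events)
  observed <- sum(window_hits(events$nuclear_chrom, events$anchor))

  ## Uniform over the concatenated genome: chromosome chosen with
  ## probability proportional to its length, then position uniform within.
  ## Permutations are drawn in blocks and overlap-tested vectorised.
  set.seed(rng_seed)
  total <- sum(as.double(chrom_sizes$size))
  cum <- cumsum(as.double(chrom_sizes$size))
  null_geq <- 0L
  block <- max(1L, min(n_perm, floor(2e6 / n_ev)))
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    u <- runif(nb * n_ev) * total
    ci <- findInterval(u, cum) + 1L
    pos <- floor(u - c(0, cum)[ci]) + 1
    hits <- window_hits(chrom_sizes$chrom[ci], pos)
    counts <- rowsum(as.integer(hits), rep(seq_len(nb), each = n_ev))
    null_geq <- null_geq + sum(counts >= observed)
    done <- done + nb
  }
  tibble::tibble(
    track_name = track_name,
    numt_class = numt_class,
    n_events = n_ev,
    observed = observed,
    n_perm = as.integer(n_perm),
    null_geq = null_geq,
    p_value = (null_geq + 1) / (n_perm + 1)
  )
}

#' Stratified enrichment over tracks and NUMT frequency classes
#'
#' Runs [nuclear_enrichment_permutation()] for every combination of
#' annotation track and NUMT frequency class (`common`, `rare`,
#' `common_and_rare`, `ultra_rare` — pooling ultra-rare and private — and
#' `all`), mirroring the stratification used for breakpoint enrichment
#' analyses.
#'
#' @param events Event tibble with `nuclear_chrom`, `anchor`,
#'   `freq_category`.
#' @param tracks Named list of interval tibbles (0-based half-open).
#' @param chrom_sizes Tibble `chrom`, `size`.
#' @param classes Classes to test; default all five.
#' @param n_perm,flank,rng_seed Passed through.
#' @return Long tibble, one row per track x class with the permutation
#'   p-value; combinations with no events are omitted.
#' @export
enrichment_by_class <- function(events, tracks, chrom_sizes,
                                classes = c("common", "rare",
                                            "common_and_rare", "ultra_rare",
                                            "all"),
                                n_perm = 10000, flank = 100, rng_seed = 1L) {
  pick <- function(cls) {
    switch(cls,
      all = events,
      common_and_rare = dplyr::filter(
        events, .data$freq_category %in% c("common", "rare")),
      ultra_rare = dplyr::filter(
        events, .data$freq_category %in% c("ultra_rare", "private")),
      dplyr::filter(events, .data$freq_category == cls))
  }
  purrr::imap(tracks, function(trk, nm) {
    purrr::map(classes, function(cls) {
      ev <- pick(cls)
      if (nrow(ev) == 0L) return(NULL)
      nuclear_enrichment_permutation(
        ev, trk, chrom_sizes, n_perm = n_perm, flank = flank,
        rng_seed = derive_seed(rng_seed, paste0(nm, cls)),
        numt_class = cls, track_name = nm)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
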