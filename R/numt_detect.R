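#' Select discordant mitochondrial-nuclear read pairs
#'
#' A discordant pair supporting a NUMT insertion has exactly one mate on the
#' mitochondrial genome and one on a primary nuclear contig (chr1-22, X, Y).
#' Records are normalised so each pair appears once, keyed by
#' `(sample_id, read_id)`, with the pair's minimum mapping quality; pairs
#' below `min_mapq` are dropped.
#'
#' @param records Alignment records from [read_alignment_records()].
#' @param min_mapq Minimum of the two mates' MAPQ (default 20).
#' @return Tibble of `sample_id`, `read_id`, `nuclear_chrom`, `nuclear_pos`,
#'   `nuclear_strand`, `mito_pos`, `mito_strand`, `mapq_min`.
#' @export
select_discordant <- function(records, min_mapq = 20) {
  nuc <- primary_nuclear_chroms()
  cand <- records |>
    dplyr::filter(!.data$is_split) |>
    dplyr::filter(
      (is_mito_chrom(.data$chrom) & .data$mate_chrom %in% nuc) |
        (.data$chrom %in% nuc & is_mito_chrom(.data$mate_chrom))
    )
  if (nrow(cand) == 0L) {
    return(tibble::tibble(sample_id = character(0), read_id = character(0),
                          nuclear_chrom = character(0), nuclear_pos = integer(0),
                          nuclear_strand = character(0), mito_pos = integer(0),
                          mito_strand = character(0), mapq_min = integer(0)))
  }
  cand |>
    dplyr::mutate(
      on_mito = is_mito_chrom(.data$chrom),
      nuclear_chrom = ifelse(.data$on_mito, .data$mate_chrom, .data$chrom),
      nuclear_pos = ifelse(.data$on_mito, .data$mate_pos, .data$pos),
      nuclear_strand = ifelse(.data$on_mito, .data$mate_strand, .data$strand),
      mito_pos = ifelse(.data$on_mito, .data$pos, .data$mate_pos),
      mito_strand = ifelse(.data$on_mito, .data$strand, .data$mate_strand)
    ) |>
    dplyr::group_by(.data$sample_id, .data$read_id) |>
    dplyr::summarise(
      nuclear_chrom = dplyr::first(.data$nuclear_chrom),
      nuclear_pos = as.integer(dplyr::first(.data$nuclear_pos)),
      nuclear_strand = dplyr::first(.data$nuclear_strand),
      mito_pos = as.integer(dplyr::first(.data$mito_pos)),
      mito_strand = dplyr::first(.data$mito_strand),
      mapq_min = min(.data$mapq),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$mapq_min >= min_mapq)
}

#' Cluster discordant pairs into per-sample NUMT candidates
#'
#' Single-linkage chaining on the nuclear positions within each
#' `(sample_id, nuclear_chrom)`: consecutive sorted positions with gap at
#' most `max_gap` (500 bp) join one cluster. Clusters supported by fewer
#' than `min_pairs` (5) discordant pairs are discarded.
#'
#' @param pairs Discordant pairs from [select_discordant()].
#' @param max_gap Maximum gap between successive sorted nuclear positions
#'   within one cluster (default 500 bp).
#' @param min_pairs Minimum supporting pairs per retained cluster
#'   (default 5).
#' @return Tibble of clusters: `sample_id`, `nuclear_chrom`, `span_start`,
#'   `span_end`, `midpoint`, `n_pairs`, `member_ids` (list column of
#'   read ids), `mito_pos_min`, `mito_pos_max`.
#' @export
cluster_discordant <- function(pairs, max_gap = 500, min_pairs = 5) {
  empty <- tibble::tibble(
    sample_id = character(0), nuclear_chrom = character(0),
    span_start = integer(0), span_end = integer(0), midpoint = double(0),
    n_pairs = integer(0), member_ids = list(),
    mito_pos_min = integer(0), mito_pos_max = integer(0))
  if (nrow(pairs) == 0L) return(empty)
  pairs |>
    dplyr::group_by(.data$sample_id, .data$nuclear_chrom) |>
    dplyr::group_modify(function(d, key) {
      o <- order(d$nuclear_pos)
      d <- d[o, , drop = FALSE]
      brk <- c(FALSE, diff(d$nuclear_pos) > max_gap)
      cl <- cumsum(brk)
      d |>
        dplyr::mutate(.cl = cl) |>
        dplyr::group_by(.data$.cl) |>
        dplyr::summarise(
          span_start = min(.data$nuclear_pos),
          span_end = max(.data$nuclear_pos),
          midpoint = (min(.data$nuclear_pos) + max(.data$nuclear_pos)) / 2,
          n_pairs = dplyr::n(),
          member_ids = list(sort(.data$read_id)),
          mito_pos_min = min(.data$mito_pos),
          mito_pos_max = max(.data$mito_pos),
          .groups = "drop"
        ) |>
        dplyr::select(-".cl")
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_pairs >= min_pairs) |>
    dplyr::arrange(.data$sample_id, .data$nuclear_chrom, .data$span_start)
}

#' Group per-sample clusters into cross-sample NUMT events
#'
#' Clusters on the same nuclear chromosome whose span midpoints lie within
#' `max_dist` (1000 bp) of each other are grouped as one NUMT event
#' (single-linkage). The event carrier count is the number of distinct
#' samples in the group; each sample counts once however many of its
#' clusters joined.
#'
#' @param clusters Cluster tibble from [cluster_discordant()].
#' @param max_dist Maximum midpoint distance joining two clusters
#'   (default 1000 bp).
#' @return Tibble of unrefined events: `event_id`, `nuclear_chrom`,
#'   `span_start`, `span_end`, `anchor` (median midpoint), `n_samples`,
#'   `samples` (list column), `n_pairs`, `mito_pos_min`, `mito_pos_max`,
#'   plus placeholder refinement columns (`nuclear_bp_left`,
#'   `nuclear_bp_right`, `mito_bp_a`, `mito_bp_b`, `size_bp`,
#'   `n_split_reads`, `refined`).
#' @export
group_events <- function(clusters, max_dist = 1000) {
  empty <- tibble::tibble(
    event_id = character(0), nuclear_chrom = character(0),
    span_start = integer(0), span_end = integer(0), anchor = double(0),
    n_samples = integer(0), samples = list(), n_pairs = integer(0),
    mito_pos_min = integer(0), mito_pos_max = integer(0),
    nuclear_bp_left = integer(0), nuclear_bp_right = integer(0),
    mito_bp_a = integer(0), mito_bp_b = integer(0), size_bp = integer(0),
    n_split_reads = integer(0), refined = logical(0))
  if (nrow(clusters) == 0L) return(empty)
  grouped <- clusters |>
    dplyr::group_by(.data$nuclear_chrom) |>
    dplyr::group_modify(function(d, key) {
      o <- order(d$midpoint)
      d <- d[o, , drop = FALSE]
      brk <- c(FALSE, diff(d$midpoint) > max_dist)
      dplyr::mutate(d, .grp = cumsum(brk))
    }) |>
    dplyr::ungroup()
  ev <- grouped |>
    dplyr::group_by(.data$nuclear_chrom, .data$.grp) |>
    dplyr::summarise(
      span_start = min(.data$span_start),
      span_end = max(.data$span_end),
      anchor = stats::median(.data$midpoint),
      n_samples = dplyr::n_distinct(.data$sample_id),
      samples = list(sort(unique(.data$sample_id))),
      n_pairs = sum(.data$n_pairs),
      mito_pos_min = min(.data$mito_pos_min),
      mito_pos_max = max(.data$mito_pos_max),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$nuclear_chrom, .data$span_start) |>
    dplyr::select(-".grp")
  ev |>
    dplyr::mutate(
      event_id = sprintf("numt_%s_%d", .data$nuclear_chrom,
                         round(.data$anchor)),
      nuclear_bp_left = NA_integer_, nuclear_bp_right = NA_integer_,
      mito_bp_a = NA_integer_, mito_bp_b = NA_integer_,
      size_bp = NA_integer_, n_split_reads = 0L, refined = FALSE
    ) |>
    dplyr::relocate("event_id")
}

#' Split-read aligner that consumes pre-aligned segment coordinates
#'
#' The default "aligner" for [refine_breakpoints()]: it does not realign,
#' but parses the `segments` annotation that alignment records carry
#' (`chrom:start-end;chrom:start-end` in read order), returning the segment
#' table for each split read. Use [align_split_read()] when only raw read
#' sequence is available.
#'
#' @return A function `(record_row) -> tibble(chrom, start, end)` or `NULL`
#'   when the record carries no parseable segmentation.
#' @export
segments_aligner <- function() {
  function(record) parse_segments(record$segments)
}

#' Smith-Waterman split-mapper for raw split reads
#'
#' Locally aligns a read against a nuclear and a mitochondrial reference
#' window (via `Biostrings::pairwiseAlignment`, local mode) and returns the
#' two best segment placements in read order. Adequate for synthetic or
#' high-identity reads; heuristics of production split-mappers (chaining,
#' multi-hit resolution) are out of scope.
#'
#' @param read Character read sequence.
#' @param nuclear_seq,mito_seq Character reference windows.
#' @param nuclear_offset,mito_offset 1-based genomic coordinate of the first
#'   base of each window.
#' @param nuclear_chrom Contig name for the nuclear window.
#' @return Tibble of segments `(chrom, start, end)` in read order, or `NULL`
#'   when either side fails to align.
#' @export
align_split_read <- function(read, nuclear_seq, mito_seq,
                             nuclear_offset = 1L, mito_offset = 1L,
                             nuclear_chrom = "chr1") {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("align_split_read() requires the Biostrings package.")
  }
  one <- function(ref, offset, chrom) {
    al <- Biostrings::pairwiseAlignment(read, ref, type = "local")
    if (Biostrings::nchar(Biostrings::alignedPattern(al)) < 10L) return(NULL)
    tibble::tibble(
      chrom = chrom,
      start = as.integer(offset + Biostrings::start(Biostrings::subject(al)) - 1L),
      end = as.integer(offset + Biostrings::end(Biostrings::subject(al)) - 1L),
      read_start = as.integer(Biostrings::start(Biostrings::pattern(al)))
    )
  }
  a <- one(nuclear_seq, nuclear_offset, nuclear_chrom)
  b <- one(mito_seq, mito_offset, "chrM")
  if (is.null(a) || is.null(b)) return(NULL)
  segs <- dplyr::bind_rows(a, b)
  segs[order(segs$read_start), c("chrom", "start", "end")]
}

## Junction candidates from a split read's segment table: an adjacent
## (nuclear, chrM) pair of segments in read order defines one breakpoint
## pair. "left" junctions run nuclear -> mito (nuclear breakpoint at the
## nuclear segment end, mito breakpoint at the mito segment start); "right"
## junctions run mito -> nuclear.
junctions_from_segments <- function(segs) {
  if (is.null(segs) || nrow(segs) < 2L) return(NULL)
  out <- list()
  for (i in seq_len(nrow(segs) - 1L)) {
    a <- segs[i, ]
    b <- segs[i + 1L, ]
    if (!is_mito_chrom(a$chrom) && is_mito_chrom(b$chrom)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        side = "left", nuclear_chrom = a$chrom,
        nuclear_bp = a$end, mito_bp = b$start)
    } else if (is_mito_chrom(a$chrom) && !is_mito_chrom(b$chrom)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        side = "right", nuclear_chrom = b$chrom,
        nuclear_bp = b$start, mito_bp = a$end)
    }
  }
  if (length(out) == 0L) NULL else dplyr::bind_rows(out)
}

#' Refine NUMT event breakpoints with split reads
#'
#' For each event, collects split reads whose nuclear anchor falls within
#' the event span widened by `flank` (500 bp) on each side, maps them to
#' candidate (nuclear, mitochondrial) breakpoint pairs via the pluggable
#' `aligner`, and confirms a junction when at least `min_split` (2) split
#' reads agree on it exactly. An event is `refined` only when both a left
#' and a right junction are confirmed; otherwise it is retained unrefined.
#' Refined events get their insertion size on the circular mitochondrial
#' genome via [numt_size()].
#'
#' @param events Event tibble from [group_events()].
#' @param split_reads Alignment records with `is_split = TRUE` (any sample).
#' @param aligner Function mapping one split-read record to its segment
#'   table; default [segments_aligner()]. Reads the aligner fails on are
#'   skipped with a warning.
#' @param flank Span widening in bp when collecting split reads
#'   (default 500).
#' @param min_split Split reads required for exact junction confirmation
#'   (default 2).
#' @return `events` with `nuclear_bp_left`, `nuclear_bp_right`, `mito_bp_a`,
#'   `mito_bp_b`, `size_bp`, `n_split_reads`, `refined` filled in.
#' @export
refine_breakpoints <- function(events, split_reads,
                               aligner = segments_aligner(),
                               flank = 500, min_split = 2) {
  if (nrow(events) == 0L) return(events)
  splits <- dplyr::filter(split_reads, .data$is_split)
  all_junc <- vector("list", nrow(splits))
  n_failed <- 0L
  for (i in seq_len(nrow(splits))) {
    segs <- tryCatch(aligner(splits[i, ]), error = function(e) NA)
    if (identical(segs, NA)) {
      n_failed <- n_failed + 1L
      next
    }
    j <- junctions_from_segments(segs)
    if (!is.null(j)) {
      j$read_id <- splits$read_id[i]
      all_junc[[i]] <- j
    }
  }
  if (n_failed > 0L) {
    warn(sprintf("split-read aligner failed on %d read(s); skipped.", n_failed))
  }
  junc <- dplyr::bind_rows(all_junc)

  for (e in seq_len(nrow(events))) {
    lo <- events$span_start[e] - flank
    hi <- events$span_end[e] + flank
    if (nrow(junc) == 0L) next
    jj <- junc |>
      dplyr::filter(.data$nuclear_chrom == events$nuclear_chrom[e],
                    .data$nuclear_bp >= lo, .data$nuclear_bp <= hi)
    events$n_split_reads[e] <- dplyr::n_distinct(jj$read_id)
    if (nrow(jj) == 0L) next
    confirmed <- jj |>
      dplyr::count(.data$side, .data$nuclear_bp, .data$mito_bp) |>
      dplyr::filter(.data$n >= min_split)
    left <- dplyr::filter(confirmed, .data$side == "left") |>
      dplyr::slice_max(.data$n, n = 1, with_ties = FALSE)
    right <- dplyr::filter(confirmed, .data$side == "right") |>
      dplyr::slice_max(.data$n, n = 1, with_ties = FALSE)
    if (nrow(left) == 1L && nrow(right) == 1L) {
      events$nuclear_bp_left[e] <- as.integer(left$nuclear_bp)
      events$nuclear_bp_right[e] <- as.integer(right$nuclear_bp)
      events$mito_bp_a[e] <- as.integer(left$mito_bp)
      events$mito_bp_b[e] <- as.integer(right$mito_bp)
      events$size_bp[e] <- numt_size(left$mito_bp, right$mito_bp,
                                     orientation = "a_to_b")
      events$refined[e] <- TRUE
    }
  }
  events
}

#' Size of a NUMT insertion on the circular mitochondrial genome
#'
#' The inserted segment is an arc of the circular 16,569 bp molecule between
#' the two mitochondrial breakpoints. `"a_to_b"` walks forward from `a` to
#' `b` (wrapping through the origin when needed, so arcs spanning position
#' 16,569 -> 1 are handled); `"shorter"` (the default when orientation
#' evidence is absent) takes the shorter of the two arcs. Identical
#' breakpoints denote a full-circle insertion of 16,568 bp — the junction
#' base is not duplicated.
#'
#' @param mito_bp_a,mito_bp_b 1-based breakpoints in 1..16,569.
#' @param orientation `"shorter"`, `"a_to_b"` or `"b_to_a"`.
#' @return Integer insertion size in bp.
#' @export
#' @examples
#' numt_size(1000, 1119)          # 119
#' numt_size(16500, 100, "a_to_b") # 169, wraps the origin
#' numt_size(42, 42)               # 16568, full circle
numt_size <- function(mito_bp_a, mito_bp_b,
                      orientation = c("shorter", "a_to_b", "b_to_a")) {
  orientation <- match.arg(orientation)
  if (any(mito_bp_a < 1 | mito_bp_a > MT_GENOME_LENGTH) ||
      any(mito_bp_b < 1 | mito_bp_b > MT_GENOME_LENGTH)) {
    abort("mitochondrial breakpoints must lie in 1..16,569.")
  }
  fwd <- circular_arc_length(mito_bp_a, mito_bp_b)
  rev <- circular_arc_length(mito_bp_b, mito_bp_a)
  as.integer(switch(orientation,
    a_to_b = fwd,
    b_to_a = rev,
    shorter = pmin(fwd, rev)
  ))
}

#' Flag events overlapping known NUMTs
#'
#' Each known NUMT interval is padded by `pad` (500 bp) on both sides; an
#' event is `known` when its refined nuclear breakpoint range (or its
#' cluster span when unrefined) overlaps any padded interval on the same
#' chromosome.
#'
#' @param events Event tibble.
#' @param known_numts Known-NUMT intervals from [read_bed()] (0-based
#'   half-open).
#' @param pad Padding in bp (default 500).
#' @return `events` with a logical `known` column.
#' @export
flag_known <- function(events, known_numts, pad = 500) {
  if (nrow(known_numts) == 0L) {
    return(dplyr::mutate(events, known = FALSE))
  }
  padded <- bed_to_1based(known_numts) |>
    dplyr::mutate(start = pmax(1, .data$start - pad), end = .data$end + pad)
  idx <- index_track(padded)
  s <- ifelse(!is.na(events$nuclear_bp_left),
              pmin(events$nuclear_bp_left, events$nuclear_bp_right),
              events$span_start)
  e <- ifelse(!is.na(events$nuclear_bp_left),
              pmax(events$nuclear_bp_left, events$nuclear_bp_right),
              events$span_end)
  dplyr::mutate(events,
                known = overlaps_any_interval(events$nuclear_chrom, s, e, idx))
}

#' Per-sample NUMT counts and cohort summary
#'
#' Counts the events carried by each sample (samples with none are included
#' with a zero count) and summarises the cohort mean and sample standard
#' deviation (n - 1 denominator).
#'
#' @param events Event tibble with `samples` list column.
#' @param samples Character vector of all cohort samples.
#' @return List with `per_sample` (tibble `sample_id`, `n_numts`) and
#'   `summary` (tibble `n_samples`, `mean`, `sd`).
#' @export
per_sample_numt_stats <- function(events, samples) {
  carriers <- unlist(events$samples)
  counts <- table(factor(carriers, levels = samples))
  per_sample <- tibble::tibble(sample_id = samples,
                               n_numts = as.integer(counts))
  list(
    per_sample = per_sample,
    summary = tibble::tibble(
      n_samples = length(samples),
      mean = mean(per_sample$n_numts),
      sd = sd(per_sample$n_numts)
    )
  )
}

#' Classify event population frequency
#'
#' Applies [frequency_category()] to event carrier counts over the
#' NUMT-retained cohort size.
#'
#' @param events Event tibble with `n_samples` carrier counts.
#' @param n_cohort NUMT-retained cohort size.
#' @return `events` with a `freq_category` column.
#' @export
classify_event_frequency <- function(events, n_cohort) {
  dplyr::mutate(events,
                freq_category = frequency_category(.data$n_samples, n_cohort))
}
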