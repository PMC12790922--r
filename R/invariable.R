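#' Positions altered by cohort variants
#'
#' Only SNVs and deletions change existing mitochondrial nucleotides, so
#' only they mark positions as variable: an SNV contributes its own
#' position; a left-anchored VCF deletion (e.g. ref `ACT`, alt `A` at
#' position p) contributes every deleted base, p+1 .. p+len(ref)-1 — the
#' anchor base itself is unchanged. Insertions contribute nothing here (see
#' [insertion_anchors()]).
#'
#' @param summaries Variant summaries from [aggregate_variants()] (needs
#'   `pos`, `ref`, `alt`, `vtype`).
#' @return Sorted integer set of 1-based variable positions.
#' @export
#' @examples
#' s <- tibble::tibble(pos = c(100L, 200L), ref = c("G", "ACT"),
#'                     alt = c("A", "A"), vtype = c("SNV", "deletion"))
#' variable_positions(s)
variable_positions <- function(summaries) {
  snv <- summaries$pos[summaries$vtype == "SNV"]
  dels <- summaries[summaries$vtype == "deletion", , drop = FALSE]
  del_pos <- purrr::map2(dels$pos, nchar(dels$ref) - nchar(dels$alt),
                         function(p, k) p + seq_len(k))
  sort(unique(as.integer(c(snv, unlist(del_pos)))))
}

#' Inter-base gaps opened by insertions
#'
#' An insertion anchored at position k inserts bases between k and k + 1; it
#' does not change any existing nucleotide but breaks the contiguity of the
#' reference run there. Returned as the set of anchors k ("gap after k").
#'
#' @param summaries Variant summaries (needs `pos`, `vtype`).
#' @return Sorted integer set of anchors; duplicates collapse.
#' @export
insertion_anchors <- function(summaries) {
  sort(unique(as.integer(summaries$pos[summaries$vtype == "insertion"])))
}

#' Maximal invariable intervals of the mitochondrial genome
#'
#' Splits the linear 1..`genome_len` sequence into maximal runs of positions
#' that are not variable, additionally broken at every insertion gap. The
#' 16,569 -> 1 adjacency of the circular molecule is deliberately not
#' joined: intervals are reported linearly. Length-1 runs are included so
#' "> 1 nt" and "> 10 nt" summaries can be derived by filtering on
#' `length`.
#'
#' @param variable_set Integer positions that are variable.
#' @param gap_set Integer insertion anchors (gap after each position k).
#' @param genome_len Genome length (default 16,569).
#' @return Tibble of intervals: `start`, `end` (1-based inclusive),
#'   `length`.
#' @export
invariable_intervals <- function(variable_set, gap_set = integer(0),
                                 genome_len = MT_GENOME_LENGTH) {
  if (any(variable_set < 1 | variable_set > genome_len) ||
      any(gap_set < 1 | gap_set > genome_len)) {
    abort("variable positions and gaps must lie within the genome.")
  }
  invariable <- setdiff(seq_len(genome_len), as.integer(variable_set))
  if (length(invariable) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0)))
  }
  ## A run breaks where consecutive invariable positions are non-adjacent or
  ## where an insertion gap sits between them.
  brk <- diff(invariable) > 1L | invariable[-length(invariable)] %in% gap_set
  run <- cumsum(c(0L, brk))
  tibble::tibble(
    start = as.integer(tapply(invariable, run, min)),
    end = as.integer(tapply(invariable, run, max))
  ) |>
    dplyr::mutate(length = .data$end - .data$start + 1L)
}

#' Region composition of invariable bases and intervals
#'
#' For each region class of the flattened annotation: the proportion of its
#' bases that are invariable, a one-tailed (upper) hypergeometric enrichment
#' p-value (drawing the cohort's invariable bases uniformly from the
#' genome), and a one-tailed rank-sum comparison of the lengths of
#' invariable intervals overlapping the class against intervals overlapping
#' other classes (alternative: this class harbours longer intervals).
#' Intervals overlapping several classes count for each.
#'
#' @param intervals Interval tibble from [invariable_intervals()].
#' @param region_table Flattened region table; default [mt_region_table()].
#' @param genome_len Genome length.
#' @return Tibble per `region_class`: `region_len`, `invariable_bases`,
#'   `proportion`, `p_hyper`, `n_intervals`, `median_len`, `p_ranksum`
#'   (NA when either side of the comparison is empty).
#' @export
interval_region_stats <- function(intervals,
                                  region_table = mt_region_table(),
                                  genome_len = MT_GENOME_LENGTH) {
  inv_pos <- unlist(purrr::map2(intervals$start, intervals$end, seq))
  ann <- annotate_region(inv_pos, region_table)
  per_class_inv <- dplyr::count(ann, .data$region_class,
                                name = "invariable_bases")
  class_len <- region_table |>
    dplyr::group_by(.data$region_class) |>
    dplyr::summarise(region_len = sum(.data$end - .data$start + 1),
                     .groups = "drop")
  k <- length(inv_pos)

  ## Region classes overlapped by each interval (an interval may span
  ## several tiles).
  iv_classes <- purrr::map2(intervals$start, intervals$end, function(s, e) {
    unique(region_table$region_class[region_table$end >= s &
                                       region_table$start <= e])
  })

  class_len |>
    dplyr::left_join(per_class_inv, by = "region_class") |>
    dplyr::mutate(
      invariable_bases = dplyr::coalesce(.data$invariable_bases, 0L),
      proportion = .data$invariable_bases / .data$region_len,
      p_hyper = phyper(.data$invariable_bases - 1, .data$region_len,
                       genome_len - .data$region_len, k, lower.tail = FALSE),
      n_intervals = purrr::map_int(
        .data$region_class,
        function(cl) sum(purrr::map_lgl(iv_classes, function(x) cl %in% x))),
      median_len = purrr::map_dbl(.data$region_class, function(cl) {
        inc <- purrr::map_lgl(iv_classes, function(x) cl %in% x)
        if (!any(inc)) NA_real_ else stats::median(intervals$length[inc])
      }),
      p_ranksum = purrr::map_dbl(.data$region_class, function(cl) {
        inc <- purrr::map_lgl(iv_classes, function(x) cl %in% x)
        x <- intervals$length[inc]
        y <- intervals$length[!inc]
        if (length(x) == 0L || length(y) == 0L) return(NA_real_)
        ## exact when small and tie-free, normal approximation otherwise
        suppressWarnings(
          wilcox.test(x, y, alternative = "greater")$p.value)
      })
    )
}

#' Intersect invariable intervals across cohorts
#'
#' Positionwise intersection of the invariable bases of two or more
#' cohorts, re-segmented into maximal runs and filtered to length strictly
#' greater than `min_len`. The operation is associative and commutative in
#' the cohort sets.
#'
#' @param interval_sets List (length >= 2) of interval tibbles from
#'   [invariable_intervals()].
#' @param min_len Keep intervals with `length > min_len` (default 10).
#' @param genome_len Genome length.
#' @return Interval tibble of shared invariable runs.
#' @export
intersect_interval_sets <- function(interval_sets, min_len = 10,
                                    genome_len = MT_GENOME_LENGTH) {
  if (length(interval_sets) < 2L) {
    abort("at least two cohort interval sets are required.")
  }
  covered <- purrr::map(interval_sets, function(iv) {
    unique(unlist(purrr::map2(iv$start, iv$end, seq)))
  })
  shared <- sort(Reduce(intersect, covered))
  if (length(shared) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0)))
  }
  ## Shared bases back into maximal runs, then the length filter. A base
  ## adjacency broken in any cohort is absent from `shared` only if the
  ## break removed a base; insertion gaps inside cohorts were already
  ## applied when each cohort's intervals were built, so re-segmentation on
  ## adjacency alone is not enough: a gap splits intervals without removing
  ## bases. Split wherever any cohort splits there.
  boundary_after <- sort(unique(unlist(
    purrr::map(interval_sets, function(iv) iv$end))))
  brk <- diff(shared) > 1L | shared[-length(shared)] %in% boundary_after
  run <- cumsum(c(0L, brk))
  tibble::tibble(
    start = as.integer(tapply(shared, run, min)),
    end = as.integer(tapply(shared, run, max))
  ) |>
    dplyr::mutate(length = .data$end - .data$start + 1L) |>
    dplyr::filter(.data$length > min_len)
}
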