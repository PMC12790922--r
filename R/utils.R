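## Internal helpers shared across modules.

## Unify mitochondrial contig naming: chrM and MT are accepted on input and
## normalised to "chrM" everywhere downstream.
normalize_chrom <- function(chrom) {
  ifelse(chrom %in% c("chrM", "MT", "chrMT", "M"), "chrM", chrom)
}

is_mito_chrom <- function(chrom) normalize_chrom(chrom) == "chrM"

## Primary nuclear contigs (GRCh38 naming).
primary_nuclear_chroms <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY")
}

## Circular mitochondrial arc length walking forward (clockwise) from `from`
## to `to` on a circle of length `len`. By the breakpoint convention used
## throughout, the arc from a to b spans (b - a) mod len bases; identical
## breakpoints denote a full-circle insertion of len - 1 bases (the junction
## base is not duplicated).
circular_arc_length <- function(from, to, len = MT_GENOME_LENGTH) {
  d <- (to - from) %% len
  ifelse(d == 0L, len - 1L, d)
}

## Positions on the forward arc from..to inclusive of `from`, wrapping at len.
circular_arc_positions <- function(from, arc_len, len = MT_GENOME_LENGTH) {
  ((from - 1L + seq_len(arc_len) - 1L) %% len) + 1L
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number, got %s.",
                  name, paste(class(x), collapse = "/")))
  }
}

## Derive a child RNG seed from a parent seed and a stage label, keeping the
## result inside 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage))
  as.integer((as.double(seed) * 7919 + offs * 131) %% .Machine$integer.max)
}

## Merge 1-based closed intervals (per chromosome already) into disjoint
## sorted runs. `start`/`end` numeric vectors.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(list(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

## Vectorised test: does closed interval [s, e] on `chrom` overlap any
## interval of `track` (tibble with chrom, start, end, 1-based closed,
## pre-merged per chromosome)? Uses findInterval on the merged starts; with
## disjoint sorted intervals the candidate with the largest start <= e is the
## only one that can overlap.
overlaps_any_interval <- function(chrom, s, e, track_by_chrom) {
  out <- logical(length(chrom))
  for (cn in unique(chrom)) {
    trk <- track_by_chrom[[cn]]
    idx <- which(chrom == cn)
    if (is.null(trk) || length(trk$start) == 0L) next
    j <- findInterval(e[idx], trk$start)
    hit <- j >= 1L
    hit[hit] <- trk$end[j[hit]] >= s[idx][hit]
    out[idx] <- hit
  }
  out
}

## Pre-merge a 1-based closed interval tibble into a per-chromosome list
## usable by overlaps_any_interval().
index_track <- function(track) {
  split(track, track$chrom) |>
    lapply(function(d) merge_intervals(d$start, d$end))
}
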