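#' Annotation of the human mitochondrial genome (rCRS)
#'
#' Returns the standard gene annotation of the revised Cambridge Reference
#' Sequence (NC_012920.1): 13 protein-coding genes, 22 tRNA genes, 2 rRNA
#' genes, and the D-loop control region (which wraps the origin and is
#' represented by its two linear spans, 16024-16569 and 1-576). Positions are
#' 1-based inclusive.
#'
#' With `flatten = TRUE` (the default) the raw annotation is resolved into a
#' non-overlapping tiling of positions 1..16,569: where features overlap,
#' precedence is tRNA > rRNA > protein_coding > D-loop; unannotated positions
#' become `intergenic` tiles. Ties within a class go to the feature with the
#' smaller start. The flattened table is what every `region_table` argument
#' in this package expects.
#'
#' @param flatten Resolve overlaps into a disjoint tiling covering the whole
#'   genome (default `TRUE`); `FALSE` returns the raw feature spans.
#' @return A tibble with columns `region_name`, `start`, `end`,
#'   `region_class` (one of `protein_coding`, `tRNA`, `rRNA`, `D-loop`,
#'   `intergenic`).
#' @export
#' @examples
#' tbl <- mt_region_table()
#' sum(tbl$end - tbl$start + 1) # covers all 16,569 positions
mt_region_table <- function(flatten = TRUE) {
  raw <- tibble::tribble(
    ~region_name, ~start, ~end, ~region_class,
    "D-loop",   16024L, 16569L, "D-loop",
    "D-loop",       1L,   576L, "D-loop",
    "MT-TF",      577L,   647L, "tRNA",
    "MT-RNR1",    648L,  1601L, "rRNA",
    "MT-TV",     1602L,  1670L, "tRNA",
    "MT-RNR2",   1671L,  3229L, "rRNA",
    "MT-TL1",    3230L,  3304L, "tRNA",
    "MT-ND1",    3307L,  4262L, "protein_coding",
    "MT-TI",     4263L,  4331L, "tRNA",
    "MT-TQ",     4329L,  4400L, "tRNA",
    "MT-TM",     4402L,  4469L, "tRNA",
    "MT-ND2",    4470L,  5511L, "protein_coding",
    "MT-TW",     5512L,  5579L, "tRNA",
    "MT-TA",     5587L,  5655L, "tRNA",
    "MT-TN",     5657L,  5729L, "tRNA",
    "MT-TC",     5761L,  5826L, "tRNA",
    "MT-TY",     5826L,  5891L, "tRNA",
    "MT-CO1",    5904L,  7445L, "protein_coding",
    "MT-TS1",    7446L,  7514L, "tRNA",
    "MT-TD",     7518L,  7585L, "tRNA",
    "MT-CO2",    7586L,  8269L, "protein_coding",
    "MT-TK",     8295L,  8364L, "tRNA",
    "MT-ATP8",   8366L,  8572L, "protein_coding",
    "MT-ATP6",   8527L,  9207L, "protein_coding",
    "MT-CO3",    9207L,  9990L, "protein_coding",
    "MT-TG",     9991L, 10058L, "tRNA",
    "MT-ND3",   10059L, 10404L, "protein_coding",
    "MT-TR",    10405L, 10469L, "tRNA",
    "MT-ND4L",  10470L, 10766L, "protein_coding",
    "MT-ND4",   10760L, 12137L, "protein_coding",
    "MT-TH",    12138L, 12206L, "tRNA",
    "MT-TS2",   12207L, 12265L, "tRNA",
    "MT-TL2",   12266L, 12336L, "tRNA",
    "MT-ND5",   12337L, 14148L, "protein_coding",
    "MT-ND6",   14149L, 14673L, "protein_coding",
    "MT-TE",    14674L, 14742L, "tRNA",
    "MT-CYB",   14747L, 15887L, "protein_coding",
    "MT-TT",    15888L, 15953L, "tRNA",
    "MT-TP",    15956L, 16023L, "tRNA"
  )
  if (!flatten) {
    return(raw)
  }
  flatten_region_table(raw)
}

## Resolve overlapping features into a disjoint tiling of 1..16,569 via
## per-position precedence, then collapse runs.
flatten_region_table <- function(raw) {
  rank <- c(tRNA = 1L, rRNA = 2L, protein_coding = 3L, `D-loop` = 4L,
            intergenic = 5L)
  pos_rank <- rep.int(rank[["intergenic"]], MT_GENOME_LENGTH)
  pos_feat <- rep.int(NA_integer_, MT_GENOME_LENGTH)
  for (i in seq_len(nrow(raw))) {
    span <- raw$start[i]:raw$end[i]
    r <- rank[[raw$region_class[i]]]
    take <- pos_rank[span] > r
    pos_rank[span[take]] <- r
    pos_feat[span[take]] <- i
  }
  key <- ifelse(is.na(pos_feat), 0L, pos_feat)
  run_end <- which(diff(key) != 0L)
  starts <- c(1L, run_end + 1L)
  ends <- c(run_end, MT_GENOME_LENGTH)
  feat <- key[starts]
  tibble::tibble(
    region_name = c("intergenic", raw$region_name)[feat + 1L],
    start = starts,
    end = ends,
    region_class = c("intergenic", raw$region_class)[feat + 1L]
  )
}

#' Annotate mitochondrial positions with their genomic region
#'
#' Maps 1-based rCRS positions to the flattened region tiling, yielding a
#' single deterministic label per position (overlaps already resolved by
#' [mt_region_table()] precedence).
#'
#' @param pos Integer vector of 1-based positions in 1..16,569.
#' @param region_table A flattened region table; default [mt_region_table()].
#' @return A tibble with `pos`, `region_name`, `region_class`.
#' @export
#' @examples
#' annotate_region(c(1555, 11778))
annotate_region <- function(pos, region_table = mt_region_table()) {
  if (any(is.na(pos)) || any(pos < 1L | pos > MT_GENOME_LENGTH)) {
    abort(sprintf("positions must lie in 1..%d on the mitochondrial genome.",
                  MT_GENOME_LENGTH))
  }
  idx <- findInterval(pos, region_table$start)
  if (any(idx < 1L) || any(pos > region_table$end[idx])) {
    abort("region_table does not tile the genome; use mt_region_table().")
  }
  tibble::tibble(
    pos = as.integer(pos),
    region_name = region_table$region_name[idx],
    region_class = region_table$region_class[idx]
  )
}
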