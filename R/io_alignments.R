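#' Read paired-end alignment evidence records
#'
#' Reads the alignment-derived evidence that feeds NUMT detection, in one of
#' two dialects:
#'
#' * `"tsv"` — tab-delimited with header, columns `read_id`, `sample_id`,
#'   `chrom`, `pos` (1-based leftmost), `strand` (`+`/`-`), `mate_chrom`,
#'   `mate_pos`, `is_split` (logical), `mapq`, and optionally `mate_strand`
#'   and `segments`. The `segments` column carries a split alignment as
#'   `chrom:start-end` blocks joined by `;` in read order (e.g.
#'   `chr1:9951-10000;chrM:3000-3049`), which is what split-read breakpoint
#'   refinement consumes.
#' * `"sam-text"` — headerless minimal SAM columns (QNAME FLAG RNAME POS
#'   MAPQ CIGAR RNEXT PNEXT ...). Split status is inferred from clipping
#'   (`S`/`H`) in the CIGAR, strand from the FLAG bits, and the CIGAR string
#'   is kept in `segments`.
#'
#' Records whose mate is unmapped are dropped. No mapping-quality filter is
#' applied here; that happens in [select_discordant()].
#'
#' @param path Input file path.
#' @param dialect `"tsv"` or `"sam-text"`.
#' @param sample_id Sample name for the SAM dialect (which carries none);
#'   defaults to the file base name.
#' @return A tibble with columns `read_id`, `sample_id`, `chrom`, `pos`,
#'   `strand`, `mate_chrom`, `mate_pos`, `mate_strand`, `is_split`,
#'   `segments`, `mapq`.
#' @export
read_alignment_records <- function(path, dialect = c("tsv", "sam-text"),
                                   sample_id = NULL) {
  if (length(dialect) > 1L) dialect <- dialect[1]
  if (!dialect %in% c("tsv", "sam-text")) {
    abort(sprintf("unknown alignment dialect '%s' (use 'tsv' or 'sam-text').",
                  dialect))
  }
  if (dialect == "tsv") {
    d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
    need <- c("read_id", "sample_id", "chrom", "pos", "strand",
              "mate_chrom", "mate_pos", "is_split", "mapq")
    missing_cols <- setdiff(need, names(d))
    if (length(missing_cols) > 0L) {
      abort(sprintf("tsv alignment dialect lacks columns: %s.",
                    paste(missing_cols, collapse = ", ")))
    }
    out <- tibble::tibble(
      read_id = d$read_id,
      sample_id = d$sample_id,
      chrom = d$chrom,
      pos = as.integer(d$pos),
      strand = d$strand,
      mate_chrom = d$mate_chrom,
      mate_pos = as.integer(d$mate_pos),
      mate_strand = if ("mate_strand" %in% names(d)) d$mate_strand else "+",
      is_split = toupper(d$is_split) %in% c("TRUE", "T", "1"),
      segments = if ("segments" %in% names(d)) d$segments else NA_character_,
      mapq = as.integer(d$mapq)
    )
    if (anyNA(out$pos) || any(out$pos < 1L)) {
      abort("malformed pos in alignment tsv (must be a positive integer).")
    }
  } else {
    d <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
    if (nrow(d) > 0L && ncol(d) < 8L) {
      abort("sam-text dialect needs at least the 8 leading SAM columns.")
    }
    if (is.null(sample_id)) {
      sample_id <- sub("\\.[^.]*$", "", basename(path))
    }
    flag <- as.integer(d[[2]])
    pos <- suppressWarnings(as.integer(d[[4]]))
    if (anyNA(pos)) abort("malformed POS in sam-text record.")
    out <- tibble::tibble(
      read_id = d[[1]],
      sample_id = sample_id,
      chrom = d[[3]],
      pos = pos,
      strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
      mate_chrom = ifelse(d[[7]] == "=", d[[3]], d[[7]]),
      mate_pos = suppressWarnings(as.integer(d[[8]])),
      mate_strand = ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
      is_split = stringr::str_detect(d[[6]], "[SH]"),
      segments = d[[6]],
      mapq = as.integer(d[[5]])
    )
    mate_unmapped <- bitwAnd(flag, 8L) > 0L | out$mate_chrom == "*"
    out <- out[!mate_unmapped, , drop = FALSE]
  }
  out |>
    dplyr::mutate(
      chrom = normalize_chrom(.data$chrom),
      mate_chrom = normalize_chrom(.data$mate_chrom)
    )
}

## Parse the "chrom:start-end;chrom:start-end" segment dialect into a tibble
## (one row per segment, read order preserved). Returns NULL if unparseable.
parse_segments <- function(segments) {
  if (is.na(segments) || !stringr::str_detect(segments, ":")) return(NULL)
  parts <- strsplit(segments, ";", fixed = TRUE)[[1]]
  m <- stringr::str_match(parts, "^([^:]+):(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) return(NULL)
  tibble::tibble(
    chrom = normalize_chrom(m[, 2]),
    start = as.integer(m[, 3]),
    end = as.integer(m[, 4])
  )
}
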