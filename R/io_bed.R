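#' Read a BED interval file
#'
#' Reads BED3+ (tab-delimited, no header): `chrom`, `start` (0-based
#' inclusive), `end` (0-based exclusive), and optionally a `name` (column 4)
#' and a `feature_class` label (column 5, e.g. LINE, SINE, simple_repeat).
#' Coordinates are validated, not coerced: empty or inverted intervals are a
#' hard error with the offending line number.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`,
#'   `feature_class` (missing optional columns filled with `NA`).
#' @seealso [write_bed()] for the inverse; round-trips are identity.
#' @export
read_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (nrow(d) == 0L) {
    return(tibble::tibble(chrom = character(0), start = double(0),
                          end = double(0), name = character(0),
                          feature_class = character(0)))
  }
  if (ncol(d) < 3L) abort("BED requires at least 3 columns.")
  start <- suppressWarnings(as.double(d[[2]]))
  end <- suppressWarnings(as.double(d[[3]]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0L) {
    abort(sprintf("invalid BED interval at line %d: start=%s end=%s (need 0 <= start < end).",
                  bad[1], d[[2]][bad[1]], d[[3]][bad[1]]))
  }
  tibble::tibble(
    chrom = d[[1]],
    start = start,
    end = end,
    name = if (ncol(d) >= 4L) d[[4]] else NA_character_,
    feature_class = if (ncol(d) >= 5L) d[[5]] else NA_character_
  )
}

#' Write intervals to a BED file
#'
#' Writes the tibble produced by [read_bed()] (columns `chrom`, `start`,
#' `end` and optionally `name`, `feature_class`) back to tab-delimited BED.
#' Optional columns are emitted only when any value is non-missing.
#'
#' @param intervals Interval tibble (0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(intervals) && any(!is.na(intervals$name))) {
    cols <- c(cols, "name")
    if ("feature_class" %in% names(intervals) && any(!is.na(intervals$feature_class))) {
      cols <- c(cols, "feature_class")
    }
  }
  out <- intervals[cols]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

## Convert a BED tibble (0-based half-open) to 1-based closed coordinates
## used internally. Conversion happens only at I/O boundaries.
bed_to_1based <- function(bed) {
  dplyr::mutate(bed, start = .data$start + 1, end = .data$end)
}
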