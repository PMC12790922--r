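#' Read a per-sample mitochondrial VCF into a tidy call table
#'
#' Parses a VCF (4.x) of mitochondrial variant calls with per-sample `AD` and
#' `DP` FORMAT fields, splits multi-allelic records into one row per
#' alternate allele (taking that allele's own AD entry), normalises the
#' contig name to `chrM` (both `chrM` and `MT` are accepted), and flags known
#' artifact positions without dropping them — filtering happens downstream in
#' [filter_variant_calls()].
#'
#' @param path Path to an uncompressed or bgzipped VCF file.
#' @param artifact_positions Integer vector of 1-based positions to flag;
#'   defaults to [mt_artifact_positions()].
#' @param sample_id Sample name to attach; defaults to the (single) sample
#'   column name in the VCF.
#' @return A tibble sorted by `pos` with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `filter`, `ad`, `dp`, `is_artifact`. Empty VCF bodies give
#'   a zero-row tibble.
#' @export
read_mt_vcf <- function(path, artifact_positions = mt_artifact_positions(),
                        sample_id = NULL) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  empty <- tibble::tibble(
    sample_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), filter = character(0),
    ad = integer(0), dp = integer(0), is_artifact = logical(0)
  )
  if (nrow(v@fix) == 0L) {
    return(empty)
  }
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  if (ncol(v@gt) < 2L) {
    abort("VCF has no sample column; per-sample AD/DP are required.")
  }
  if (is.null(sample_id)) sample_id <- colnames(v@gt)[2]

  fmt_keys <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  gt_vals <- strsplit(v@gt[, 2], ":", fixed = TRUE)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos) || any(pos < 1L)) {
    bad <- which(is.na(pos) | pos < 1L)[1]
    abort(sprintf("malformed POS at VCF record %d ('%s').", bad, fix$POS[bad]))
  }

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    keys <- fmt_keys[[i]]
    vals <- gt_vals[[i]]
    i_ad <- match("AD", keys)
    i_dp <- match("DP", keys)
    if (is.na(i_ad) || is.na(i_dp) || length(vals) < max(i_ad, i_dp)) {
      abort(sprintf(
        "record %s:%s %s>%s lacks AD/DP in its FORMAT/sample fields.",
        fix$CHROM[i], fix$POS[i], fix$REF[i], fix$ALT[i]))
    }
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ad_all <- suppressWarnings(as.integer(strsplit(vals[i_ad], ",")[[1]]))
    dp <- suppressWarnings(as.integer(vals[i_dp]))
    if (is.na(dp)) {
      abort(sprintf("record %s:%s has non-integer DP.", fix$CHROM[i], fix$POS[i]))
    }
    ## AD is the VCF convention (ref, alt1, alt2, ...); every alt must carry
    ## its own entry — proportional splitting is refused.
    if (length(ad_all) != length(alts) + 1L || anyNA(ad_all)) {
      abort(sprintf(
        "record %s:%s: AD must list one count per allele (ref + %d alt).",
        fix$CHROM[i], fix$POS[i], length(alts)))
    }
    tibble::tibble(
      sample_id = sample_id,
      chrom = normalize_chrom(fix$CHROM[i]),
      pos = pos[i],
      ref = toupper(fix$REF[i]),
      alt = toupper(alts),
      filter = fix$FILTER[i],
      ad = ad_all[-1],
      dp = dp
    )
  })
  out <- dplyr::bind_rows(rows)
  bad <- out$ad > out$dp | out$ad < 0L
  if (any(bad)) {
    abort(sprintf("record at pos %d has AD > DP (AD accounting error).",
                  out$pos[which(bad)[1]]))
  }
  out |>
    dplyr::mutate(is_artifact = .data$pos %in% artifact_positions) |>
    dplyr::arrange(.data$pos, .data$alt)
}

#' Check whether a VCF FILTER string denotes PASS
#'
#' Exact string comparison after splitting the FILTER field on `;`.
#'
#' @param filter Character vector of FILTER strings.
#' @return Logical vector.
#' @export
filter_is_pass <- function(filter) {
  purrr::map_lgl(strsplit(filter, ";", fixed = TRUE),
                 function(f) any(f == "PASS"))
}
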