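#' Plot the cohort VAF spectrum
#'
#' Histogram of per-call variant allele fractions with the heteroplasmy
#' classification boundaries (0.10 and 0.95) marked.
#'
#' @param calls Filtered call tibble with a `vaf` column.
#' @param bins Histogram bins (default 60).
#' @return A ggplot object.
#' @export
plot_vaf_spectrum <- function(calls, bins = 60) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$vaf)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = c(0.1, 0.95), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_continuous(limits = c(0, 1.02)) +
    ggplot2::labs(x = "variant allele fraction", y = "calls",
                  title = "Heteroplasmy spectrum") +
    ggplot2::theme_minimal()
}

#' Plot the ECDF of NUMT mitochondrial breakpoints
#'
#' Steeper stretches mark breakpoint-dense regions of the mitochondrial
#' genome; the diagonal is the uniform reference.
#'
#' @param breakpoints Integer vector of 1-based positions.
#' @return A ggplot object.
#' @export
plot_mito_breakpoint_ecdf <- function(breakpoints) {
  d <- tibble::tibble(pos = sort(breakpoints))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos)) +
    ggplot2::stat_ecdf(linewidth = 0.6) +
    ggplot2::geom_abline(slope = 1 / MT_GENOME_LENGTH, intercept = 0,
                         linetype = "dotted") +
    ggplot2::labs(x = "mtDNA position (bp)", y = "ECDF",
                  title = "NUMT mitochondrial breakpoints") +
    ggplot2::theme_minimal()
}

#' Plot invariable-interval length distributions by region class
#'
#' @param intervals Interval tibble from [invariable_intervals()].
#' @param region_table Flattened region table.
#' @return A ggplot object.
#' @export
plot_invariable_lengths <- function(intervals,
                                    region_table = mt_region_table()) {
  cls <- purrr::map2_chr(intervals$start, intervals$end, function(s, e) {
    hit <- region_table$region_class[region_table$end >= s &
                                       region_table$start <= e]
    hit[1]
  })
  d <- dplyr::mutate(intervals, region_class = cls)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region_class,
                                  y = .data$length)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "invariable interval length (bp)") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of an association scan
#'
#' @param object An `mt_assoc_scan` object.
#' @param thresholds Significance thresholds to draw; default
#'   [significance_thresholds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mt_assoc_scan
#' @export
autoplot.mt_assoc_scan <- function(object,
                                   thresholds = significance_thresholds(),
                                   ...) {
  d <- dplyr::filter(object$results, !is.na(.data$p_value)) |>
    dplyr::mutate(idx = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx,
                                  y = -log10(.data$p_value))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(thresholds$primary),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(thresholds$stringent),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "nuclear variant index", y = "-log10 p",
                  title = object$meta$mt_variant) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
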