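#' Plot run statistics
#'
#' Read-length histogram with the N50 marked, the standard one-look summary
#' of an amplicon run.
#'
#' @param object A `"run_stats"` object.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.run_stats <- function(object, bins = 60, ...) {
  df <- tibble(length = object$lengths)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = NA) +
    ggplot2::geom_vline(xintercept = object$n50, linetype = "dashed") +
    ggplot2::annotate("text", x = object$n50, y = Inf, hjust = -0.1,
                      vjust = 1.5, label = sprintf("N50 = %d", object$n50)) +
    ggplot2::labs(x = "read length (bp)", y = "reads",
                  title = sprintf("%d reads, mean length %.0f bp",
                                  object$n_reads, object$mean_length))
}

#' Plot a genotype call's ranked pair list
#'
#' Total exon mismatches for the top-ranked allele pairs — the ranked list a
#' reviewer scans when a call is flagged for manual review.
#'
#' @param object A `"genotype_call"`.
#' @param top_n Pairs shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genotype_call <- function(object, top_n = 8, ...) {
  df <- head(tidy(object), top_n) |>
    dplyr::mutate(pair = paste(.data$reported_a, .data$reported_b, sep = " / "))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pair, -.data$rank),
                                   y = .data$total)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "total exon mismatches",
                  title = sprintf("best call: %s / %s (%s)",
                                  object$best$reported_a,
                                  object$best$reported_b, object$zygosity))
}

#' Plot an allele-frequency report
#'
#' @param object A `"frequency_report"`.
#' @param top_n Alleles shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frequency_report <- function(object, top_n = 15, ...) {
  df <- head(object, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$allele, .data$percent), y = .data$percent)) +
    ggplot2::geom_col(fill = "darkred") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("%% (%s denominator)",
                                        attr(object, "denominator_mode")))
}
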