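#' Plot a methylation proximity profile
#'
#' Mean CpH methylation level as a function of signed distance from the
#' center CpGs (5'->3' on the center's strand).
#'
#' @param object A `cphmm_profile` from [proximity_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cphmm_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Position relative to center CpG (bp, 5'→3')",
                  y = "Mean CpH methylation level",
                  title = sprintf("Methylation around %s centers (n = %d)",
                                  attr(object, "center_kind"),
                                  attr(object, "n_centers"))) +
    ggplot2::theme_minimal()
}

#' Plot an FDR calibration curve
#'
#' Empirical false discovery rate against the p-value cutoff grid, with
#' the FDR target and the recommended cutoff marked.
#'
#' @param object A `cphmm_fdr` from [calibrate_fdr()].
#' @param fdr_max FDR target line. Default 0.01.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cphmm_fdr <- function(object, fdr_max = 0.01, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$fdr)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = fdr_max, linetype = "dashed", colour = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "P-value cutoff", y = "Empirical FDR (null calls / real calls)") +
    ggplot2::theme_minimal()
  rec <- attr(object, "recommended_cutoff")
  if (!is.na(rec)) p <- p + ggplot2::geom_vline(xintercept = rec, linetype = "dotted")
  p
}

#' Plot per-bin methylation ratios coloured by HMM state
#'
#' CpG read ratio against CpH read ratio for every detected bin, coloured
#' by decoded state: P bins should fall on a positively sloped cloud, N
#' bins on a negatively sloped one, U bins around the genome-wide CpH
#' rate.
#'
#' @param object A `cphmm_segmentation` from [segment_methylome()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cphmm_segmentation <- function(object, ...) {
  df <- dplyr::filter(object$bins, .data$detected, !is.na(.data$state))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mh, y = .data$mg, colour = .data$state)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::scale_colour_manual(values = c(P = "#2166ac", N = "#b2182b", U = "grey55")) +
    ggplot2::labs(x = "CpH methylated-read ratio (per bin)",
                  y = "CpG methylated-read ratio (per bin)",
                  colour = "State") +
    ggplot2::theme_minimal()
}

#' Plot DMR overlap fractions per annotation
#'
#' @param overlaps Output of [overlap_fraction_table()].
#' @return A ggplot bar chart of the fraction of each annotation covered
#'   by DMRs, with the whole-genome fraction as a reference line.
#' @export
plot_overlap_fractions <- function(overlaps) {
  wg <- overlaps$fraction_of_annotation[overlaps$annotation_name == "whole_genome"]
  df <- dplyr::filter(overlaps, .data$annotation_name != "whole_genome")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$annotation_name,
                                                      -.data$fraction_of_annotation),
                                   y = .data$fraction_of_annotation)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_hline(yintercept = wg, linetype = "dashed", colour = "#b2182b") +
    ggplot2::labs(x = NULL, y = "Fraction of annotation covered by DMRs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
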