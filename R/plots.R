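# ggplot2 views of the main result types.

#' Plot an annotated read as a block ideogram
#'
#' @param annotation An `array_annotation`.
#' @return A ggplot object.
#' @export
plot_annotation <- function(annotation) {
  b <- annotation$blocks
  ggplot2::ggplot(b) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = 1, fill = .data$label)) +
    ggplot2::geom_text(
      data = filter(b, .data$kind == "sat"),
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = 1.15,
                   label = .data$strand), size = 3) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(0, 1.3)) +
    ggplot2::labs(x = "position (bp)", fill = NULL,
                  title = sprintf("%s (%s%s)", annotation$read_id,
                                  annotation$array_type %||% "unannotated",
                                  if (annotation$direction_switch) ", direction switch" else "")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_variation_profile
#' @param object A `variation_profile`.
#' @param ... Ignored.
#' @export
autoplot.variation_profile <- function(object, ...) plot_variation_profile(object)

#' Plot a per-position variation profile
#'
#' @param profile A `variation_profile` from [per_position_variation()].
#' @return A ggplot object.
#' @export
plot_variation_profile <- function(profile) {
  ggplot2::ggplot(profile$profile,
                  ggplot2::aes(x = .data$position, y = 100 * .data$variant_fraction)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = sprintf("%s consensus position", profile$sat_class),
                  y = "% monomers variant",
                  title = sprintf("Per-position variation (%d monomers)",
                                  profile$n_monomers)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_phasing
#' @param object A `phasing_profile`.
#' @param ... Ignored.
#' @export
autoplot.phasing_profile <- function(object, ...) plot_phasing(object)

#' Plot a coverage autocorrelation (phasing) profile
#'
#' @param profile A `phasing_profile` from [phasing()].
#' @return A ggplot object.
#' @export
plot_phasing <- function(profile) {
  p <- ggplot2::ggplot(profile$acf, ggplot2::aes(x = .data$lag, y = .data$rho)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::labs(x = "lag (bp)", y = "coverage autocorrelation",
                  title = if (profile$phased) {
                    sprintf("Phased: period %d bp, score %.2f",
                            profile$period, profile$score)
                  } else sprintf("Unphased (score %.2f)", profile$score)) +
    ggplot2::theme_minimal()
  if (profile$phased) {
    p <- p + ggplot2::geom_vline(xintercept = profile$period,
                                 linetype = "dashed", color = "firebrick")
  }
  p
}

#' Plot fold enrichment per satellite class
#'
#' @param enrichment An `enrichment_table` (or row-bound tables carrying a
#'   `mark` column).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  has_mark <- "mark" %in% names(enrichment)
  p <- ggplot2::ggplot(enrichment,
                       ggplot2::aes(x = .data$sat_class, y = .data$fold)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "fold enrichment (ChIP / input)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (has_mark) p <- p + ggplot2::facet_wrap(~mark, scales = "free_y")
  p
}
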