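#' Plot a lane profile with detected bands
#'
#' @param object A `lane_profile`.
#' @param bands Optional band tibble from [detect_bands()] /
#'   [quantify_lane()]; detected bands are shaded and labelled with their
#'   fraction (and identity, if assigned).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.lane_profile <- function(object, bands = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$position, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "migration (px)", y = "intensity (a.u.)",
                  title = attr(object, "lane_id")) +
    ggplot2::theme_minimal()
  if (!is.null(bands) && nrow(bands) > 0L) {
    lab <- if ("identity" %in% names(bands)) {
      sprintf("%s\n%.0f%%", bands$identity, bands$fraction)
    } else sprintf("%.0f%%", bands$fraction)
    p <- p +
      ggplot2::geom_rect(
        data = bands, inherit.aes = FALSE, alpha = 0.15, fill = "steelblue",
        ggplot2::aes(xmin = .data$left, xmax = .data$right,
                     ymin = -Inf, ymax = Inf)) +
      ggplot2::annotate("text", x = bands$center,
                        y = max(object$intensity) * 1.02, label = lab,
                        size = 2.8, vjust = 0)
  }
  p
}

#' Plot the residual wild-type distribution of a classified cohort
#'
#' Bar chart of assays per residual-wild-type bin, filled by final ACMG
#' class, mirroring the cohort overview figure of a splice-assay study.
#'
#' @param object An `msa_classification` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.msa_classification <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin,
                                       fill = .data$final_class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "residual wild-type transcript bin", y = "variants",
                  fill = "final class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
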