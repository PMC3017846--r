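#' Plot MFEI against G+C content for candidate precursors
#'
#' Scatter of the two composition criteria over all evaluated candidates,
#' with the acceptance region (MFEI above threshold, G+C within bounds)
#' outlined; points are coloured by verdict.
#'
#' @param object A `mircane_precursor_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mircane_precursor_result <- function(object, ...) {
  rep <- object$report
  if (nrow(rep) == 0) {
    abort("nothing to plot: the pipeline evaluated no candidates")
  }
  cfg <- object$config
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$gc_percent, y = .data$mfei,
                                    colour = .data$verdict)) +
    ggplot2::annotate("rect",
                      xmin = cfg$gc_range[1], xmax = cfg$gc_range[2],
                      ymin = cfg$mfei_min, ymax = Inf,
                      alpha = 0.08, fill = "forestgreen") +
    ggplot2::geom_hline(yintercept = cfg$mfei_min, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = cfg$gc_range, linetype = "dotted") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(accept = "forestgreen",
                                            reject = "grey40")) +
    ggplot2::labs(x = "G+C content of trimmed stem-loop (%)",
                  y = "MFEI (built-in energy model)",
                  colour = "verdict") +
    ggplot2::theme_minimal()
}

#' Plot the score decomposition of predicted target sites
#'
#' Stacked bars of the G:U wobble, mismatch and bulge contributions to each
#' accepted site's complementarity score, with the acceptance cutoff drawn.
#'
#' @param object A `mircane_target_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mircane_target_result <- function(object, ...) {
  hits <- object$hits
  if (nrow(hits) == 0) {
    abort("nothing to plot: no target sites were accepted")
  }
  long <- hits |>
    mutate(site = paste0(.data$family, " @ ", .data$target_id, ":",
                         .data$site_start),
           `G:U (0.5)` = 0.5 * .data$n_gu,
           `mismatch (1.0)` = 1 * .data$n_mismatch,
           `bulge (1.5)` = 1.5 * .data$n_bulge) |>
    tidyr::pivot_longer(c("G:U (0.5)", "mismatch (1.0)", "bulge (1.5)"),
                        names_to = "component", values_to = "points")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site, y = .data$points,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$config$target_threshold,
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "complementarity score (points)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Draw a candidate hairpin as a paired-arm diagram
#'
#' Simple arc-free rendering: position along the sequence on the x axis,
#' with segments joining paired bases, and the mature span highlighted.
#'
#' @param fold A `mircane_fold`.
#' @param mature_start,mature_len Optional mature span to highlight.
#' @return A ggplot object.
#' @export
plot_hairpin <- function(fold, mature_start = NULL, mature_len = NULL) {
  stopifnot(inherits(fold, "mircane_fold"))
  n <- length(fold$pairing)
  i <- seq_len(n)
  arcs <- tibble(from = i, to = fold$pairing)[fold$pairing > i, ]
  arcs$h <- (arcs$to - arcs$from) / 2
  p <- ggplot2::ggplot() +
    ggplot2::geom_curve(data = arcs,
                        ggplot2::aes(x = .data$from, xend = .data$to,
                                     y = 0, yend = 0),
                        curvature = -0.5, alpha = 0.5, colour = "steelblue") +
    ggplot2::geom_segment(ggplot2::aes(x = 1, xend = n, y = 0, yend = 0)) +
    ggplot2::labs(x = "position (nt)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(mature_start) && !is.null(mature_len)) {
    p <- p + ggplot2::annotate("segment", x = mature_start,
                               xend = mature_start + mature_len - 1,
                               y = 0, yend = 0, linewidth = 2,
                               colour = "firebrick")
  }
  p
}
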