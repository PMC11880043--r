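#' Plot a hydropathy profile
#'
#' Line plot of the sliding-window Kyte-Doolittle score with the classic
#' 1.6 threshold for membrane-spanning stretches; optional transmembrane
#' segments are shaded.
#'
#' @param object A `qty_hydropathy` from [hydropathy_profile()].
#' @param segments Optional segment tibble (`start`, `end`) to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qty_hydropathy <- function(object, segments = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$score))
  if (!is.null(segments) && nrow(segments) > 0) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_hline(yintercept = 1.6, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Residue (window center)",
      y = sprintf("Mean hydropathy (window %d)", attr(object, "window"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-record QTY variation percentages
#'
#' Paired bars of transmembrane and overall variation for each design.
#'
#' @param object A `qty_tbl` from [qty_apply()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qty_tbl <- function(object, ...) {
  long <- object %>%
    as_tibble() %>%
    select("id", "tm_pct", "overall_pct") %>%
    tidyr::pivot_longer(c("tm_pct", "overall_pct"),
                        names_to = "scope", values_to = "pct") %>%
    mutate(scope = ifelse(.data$scope == "tm_pct",
                          "Transmembrane", "Overall"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$id, y = .data$pct,
                                     fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Sequence variation (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a per-residue surface comparison
#'
#' Per-residue SASA change between a native model and its analog, coloured
#' by whether the residue left the hydrophobic class.
#'
#' @param object A `qty_surface_delta` from [compare_surfaces()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qty_surface_delta <- function(object, ...) {
  ggplot2::ggplot(object$residues,
                  ggplot2::aes(x = .data$resno, y = .data$delta_area,
                               fill = .data$class_changed)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Residue", y = expression(Delta * "SASA (" * ring(A)^2 * ")"),
                  fill = "Left hydrophobic class") +
    ggplot2::theme_minimal()
}
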