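#' Plot MKSE surfaces
#'
#' Median entropy (with a median-absolute-deviation ribbon) as a function of
#' the scale factor, one panel per partition cardinality, colored by group —
#' the standard way of reading an MKSE surface.
#'
#' @param surfaces An [mkse()] surface tibble.
#' @param cardinalities Which partition cardinalities to facet (default: the
#'   even ones present).
#' @return A ggplot object.
#' @export
plot_mkse <- function(surfaces, cardinalities = NULL) {
  cardinalities <- cardinalities %||%
    intersect(unique(surfaces$n), seq(2L, max(surfaces$n), by = 2L))
  df <- surfaces |>
    dplyr::filter(.data$n %in% cardinalities) |>
    dplyr::group_by(.data$group, .data$tau, .data$n) |>
    dplyr::summarise(
      med = median(.data$entropy),
      mad_ = stats::mad(.data$entropy),
      .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$med,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$med - .data$mad_,
                                      ymax = .data$med + .data$mad_),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~n, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression("scale factor" ~ tau),
                  y = "MKSE (bits/symbol)",
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mkse_tbl <- function(object, ...) plot_mkse(object, ...)

#' Heatmap of a comparison grid
#'
#' `-log10` p-values over the `(tau, n)` grid with significant cells
#' outlined, mirroring the usual presentation of multiscale test grids.
#'
#' @param object An `mkse_grid_test` from [mkse_mann_whitney()] or
#'   [mkse_kruskal_wallis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mkse_grid_test <- function(object, ...) {
  df <- object$grid
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$n,
                                   fill = -log10(.data$p))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$significant),
                        shape = 8, size = 1.5, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p))) +
    ggplot2::labs(
      x = expression("scale factor" ~ tau), y = "partition cardinality n",
      title = sprintf("%s: %s (threshold %g)", object$test,
                      paste(object$groups, collapse = " vs "),
                      object$alpha_corrected)) +
    ggplot2::theme_minimal()
}
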