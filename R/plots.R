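#' Layer-profile bar plot of a group comparison
#'
#' Reproduces the standard reporting figure: per region, grouped bars of
#' the AD and control means per retinal layer with standard-error bars
#' and significance stars above each significant pair.
#'
#' @param comparisons output of [compare_groups()] (layer mode).
#' @param value_lab y-axis label.
#' @return a ggplot object.
#' @export
plot_layer_profile <- function(comparisons, value_lab = "positive pixels (%)") {
  stopifnot(all(c("region", "layer", "mean_ad", "mean_control") %in%
                  names(comparisons)))
  key <- if ("layer" %in% names(comparisons)) "layer" else "layer_group"
  long <- comparisons |>
    tidyr::pivot_longer(c("mean_ad", "mean_control"),
                        names_to = "group", values_to = "mean") |>
    dplyr::mutate(group = ifelse(.data$group == "mean_ad", "AD", "control"),
                  se = ifelse(.data$group == "AD", .data$se_ad,
                              .data$se_control),
                  layer = factor(.data[[key]], levels = unique(
                    c(retinal_layers(), "inner", "outer"))))
  stars <- comparisons |>
    dplyr::mutate(layer = factor(.data[[key]], levels = levels(long$layer)),
                  y = pmax(.data$mean_ad + dplyr::coalesce(.data$se_ad, 0),
                           .data$mean_control +
                             dplyr::coalesce(.data$se_control, 0)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$layer, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25,
      na.rm = TRUE) +
    ggplot2::geom_text(data = stars,
                       ggplot2::aes(x = .data$layer, y = .data$y,
                                    label = .data$stars),
                       inherit.aes = FALSE, vjust = -0.5, size = 5) +
    ggplot2::facet_wrap(~region) +
    ggplot2::scale_fill_manual(values = c(AD = "#c0392b", control = "#2980b9")) +
    ggplot2::labs(x = NULL, y = value_lab, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Colocalization contrast bar plot
#'
#' Per group and region, pairs of bars per layer: the percentage of
#' amyloid-positive pixels inside (green) versus outside (black) the
#' marker footprint, with stars marking significant paired contrasts.
#'
#' @param coloc_tests output of [paired_coloc_test()].
#' @return a ggplot object.
#' @export
plot_coloc_profile <- function(coloc_tests) {
  long <- coloc_tests |>
    tidyr::pivot_longer(c("mean_p_pos", "mean_p_neg"),
                        names_to = "side", values_to = "mean") |>
    dplyr::mutate(side = ifelse(.data$side == "mean_p_pos",
                                "marker-positive", "marker-negative"),
                  layer = factor(.data$layer, levels = retinal_layers()))
  stars <- coloc_tests |>
    dplyr::mutate(layer = factor(.data$layer, levels = retinal_layers()),
                  y = pmax(.data$mean_p_pos, .data$mean_p_neg))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$layer, y = .data$mean,
                                     fill = .data$side)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_text(data = stars,
                       ggplot2::aes(x = .data$layer, y = .data$y,
                                    label = .data$stars),
                       inherit.aes = FALSE, vjust = -0.5, size = 5) +
    ggplot2::facet_grid(group ~ region) +
    ggplot2::scale_fill_manual(values = c("marker-positive" = "#27ae60",
                                          "marker-negative" = "#2c3e50")) +
    ggplot2::labs(x = NULL, y = "amyloid-positive pixels (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
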