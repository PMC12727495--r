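#' Plot a consolidation as incremental-correction bars
#'
#' Bar chart of the reporting-decade means: for each revised component the
#' baseline estimate, the signed corrections, and the consolidated
#' estimate, with 1-sigma error bars -- the standard "waterfall" view of a
#' budget revision.
#'
#' @param object a `"gcb_consolidation"`.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_line
#'   geom_ribbon geom_hline geom_point facet_wrap labs theme_minimal
#' @export
autoplot.gcb_consolidation <- function(object, ...) {
  td <- tidy(object)
  bars <- td |>
    filter(.data$component %in% c("E_LUC", "S_LAND", "S_OCEAN", "B_IM")) |>
    mutate(
      stage = factor(.data$stage, c("baseline", "consolidated")),
      component = factor(
        .data$component, c("E_LUC", "S_LAND", "S_OCEAN", "B_IM")
      )
    )
  ggplot(bars, aes(x = .data$stage, y = .data$value, fill = .data$stage)) +
    geom_col(width = 0.6, show.legend = FALSE) +
    geom_errorbar(
      aes(
        ymin = .data$value - .data$sigma,
        ymax = .data$value + .data$sigma
      ),
      width = 0.2
    ) +
    facet_wrap(~component, scales = "free_y") +
    labs(
      x = NULL, y = "GtC/yr",
      title = sprintf(
        "Budget revision, %d-%d decadal means",
        object$decade[1], object$decade[2]
      )
    ) +
    theme_minimal()
}

#' @export
ggplot2::autoplot

#' Plot a budget-imbalance series with its significance band
#'
#' Annual imbalance with the +/- k sigma band derived from the
#' atmospheric-growth uncertainty; years outside the band carry a
#' statistically significant imbalance.
#'
#' @param band tibble from [bim_band()].
#' @param k band half-width used (display only).
#' @return A ggplot object.
#' @export
plot_bim_band <- function(band, k = 1) {
  ggplot(band, aes(x = .data$year, y = .data$value)) +
    geom_ribbon(
      aes(
        ymin = -k * .data$band_sigma,
        ymax = k * .data$band_sigma
      ),
      fill = "grey80"
    ) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    geom_line() +
    geom_point(aes(colour = .data$significant), size = 1.5) +
    labs(
      x = NULL, y = "Budget imbalance (GtC/yr)",
      colour = sprintf("|B_IM| > %g sigma", k)
    ) +
    theme_minimal()
}

#' Plot a regional flux decomposition
#'
#' Grouped bars per region for the CO2-fertilisation sink, climate-impact
#' source, land-use source and the net flux (with its quadrature sigma).
#'
#' @param regions tibble from [regional_decomposition()].
#' @return A ggplot object.
#' @export
plot_regional_decomposition <- function(regions) {
  long <- regions |>
    mutate(co2 = .data$co2, climate = -.data$climate, luc = -.data$luc) |>
    tidyr::pivot_longer(
      c("co2", "climate", "luc", "net"),
      names_to = "term", values_to = "flux"
    ) |>
    mutate(term = factor(.data$term, c("co2", "climate", "luc", "net")))
  err <- filter(long, .data$term == "net")
  ggplot(long, aes(x = .data$region, y = .data$flux, fill = .data$term)) +
    geom_col(position = "dodge") +
    geom_errorbar(
      data = err,
      aes(
        ymin = .data$flux - .data$net_sigma,
        ymax = .data$flux + .data$net_sigma
      ),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    geom_hline(yintercept = 0, colour = "grey40") +
    labs(x = NULL, y = "GtC/yr (sink positive)", fill = NULL) +
    theme_minimal()
}
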