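#' Plot yearly yield by cell
#'
#' Bar chart of per-cell yield faceted by season, with the farm-mean yield
#' as a dashed reference line and zero-harvest cells marked, mirroring the
#' standard cell-size yield panel.
#'
#' @param dataset A `farm_dataset` with a yield panel.
#' @return A ggplot object.
#' @export
plot_yield <- function(dataset) {
  stopifnot(inherits(dataset, "farm_dataset"), !is.null(dataset$yield))
  df <- tidy.farm_dataset(dataset)
  means <- farm_mean_yield(dataset)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_id, y = .data$yield_mg_ha)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$yield_mg_ha),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_point(data = filter(df, .data$zero_harvest),
                        ggplot2::aes(y = 0), shape = 4, size = 2,
                        colour = "grey50") +
    ggplot2::facet_wrap(~year) +
    ggplot2::labs(x = NULL, y = "Yield (Mg/ha)",
                  title = paste("Cell yields, farm", dataset$farm_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @describeIn bienniality Diverging bar chart of per-unit bienniality
#'   magnitude (negative bars are phase-inverted units).
#' @param object A `cellfarm_bienniality` table.
#' @param ... Unused.
#' @method autoplot cellfarm_bienniality
#' @export
autoplot.cellfarm_bienniality <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$unit_id, .data$MB),
                                       y = .data$MB, fill = .data$MB > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e7d32", `FALSE` = "#c62828")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Bienniality magnitude (Mg/ha)") +
    ggplot2::theme_minimal()
}

#' @describeIn compare_strategies Dodged bar chart of uniform vs localized
#'   totals per target year, faceted by nutrient.
#' @param object A `cellfarm_comparison` table.
#' @param ... Unused.
#' @method autoplot cellfarm_comparison
#' @export
autoplot.cellfarm_comparison <- function(object, ...) {
  long <- object |>
    pivot_longer(c("um_total_kg", "lm_total_kg"),
                 names_to = "strategy", values_to = "total_kg") |>
    mutate(strategy = ifelse(.data$strategy == "um_total_kg",
                             "Uniform", "Localized (cell)"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$target_year),
                                     y = .data$total_kg,
                                     fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~nutrient, scales = "free_y") +
    ggplot2::labs(x = "Recommendation year", y = "Total recommended (kg)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn profitability Year-by-unit profitability heat map (green
#'   gains, red losses).
#' @param object A `cellfarm_profit` table.
#' @param ... Unused.
#' @method autoplot cellfarm_profit
#' @export
autoplot.cellfarm_profit <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$year),
                                       y = .data$unit_id,
                                       fill = .data$profit_usd_ha)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "#c62828", mid = "white",
                                  high = "#2e7d32", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Profit (USD/ha)") +
    ggplot2::theme_minimal()
}
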