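#' Nutrient-export coefficients per bag of processed coffee
#'
#' Whole-plant nutrient demand per 60-kg bag of processed coffee, the basis
#' of export dosing: 0.60 kg of P2O5 and 5.90 kg of K2O per bag per hectare.
#'
#' @param bag_kg Mass of one bag of processed coffee, kg.
#' @param p2o5_per_bag,k2o_per_bag Nutrient demand per bag, kg.
#' @return A named list of class `export_coefficients`.
#' @export
#' @examples
#' export_coefficients()
export_coefficients <- function(bag_kg = 60, p2o5_per_bag = 0.60,
                                k2o_per_bag = 5.90) {
  stopifnot(bag_kg > 0, p2o5_per_bag > 0, k2o_per_bag > 0)
  structure(list(bag_kg = bag_kg, p2o5_per_bag = p2o5_per_bag,
                 k2o_per_bag = k2o_per_bag),
            class = "export_coefficients")
}

#' Default coffee price and exchange-rate series, 2018-2021
#'
#' Yearly average price of coffee in USD per 60-kg bag and the average
#' BRL-per-USD exchange rate for the study window of the two Minas Gerais
#' farms the package ships defaults for.
#'
#' @return A tibble `year`, `price_usd_per_bag`, `fx_brl_per_usd`.
#' @export
default_price_series <- function() {
  tibble(
    year = 2018:2021,
    price_usd_per_bag = c(120, 107, 105, 178),
    fx_brl_per_usd = c(3.6542, 3.9451, 5.1558, 5.3950)
  )
}

#' Default production-cost ledger, 2018-2021 (farm 1)
#'
#' Yearly coffee production cost in USD per hectare at three nested levels:
#' effective operating cost (operations only), total operating cost
#' (+ depreciation) and total cost (+ return on capital).
#'
#' @return A long tibble `year`, `category`, `usd_per_ha`.
#' @export
default_cost_ledger <- function() {
  tibble(
    year = rep(2018:2021, times = 3),
    category = rep(cost_summary_levels, each = 4),
    usd_per_ha = c(
      2583, 2393, 1831, 1750,   # effective operating
      3266, 3025, 2315, 2212,   # total operating
      3637, 3369, 2577, 2463    # total
    )
  )
}

#' Default farm-average soil profile
#'
#' Farm-average values of the fifteen-attribute soil panel for the two study
#' farms over 2018-2021, used as generator defaults and for farm-level
#' recomputations when per-cell data are unavailable.
#'
#' @param farm `1` or `2`.
#' @return A long tibble `year`, `attribute`, `value`, `unit`.
#' @export
default_soil_profile <- function(farm = 1) {
  stopifnot(farm %in% c(1, 2))
  units <- c(pH = "-", P_rem = "mg/dm3", P = "mg/dm3", K = "mg/dm3",
             Ca = "cmolc/dm3", Mg = "cmolc/dm3", H_Al = "cmolc/dm3",
             CEC = "cmolc/dm3", OM = "g/kg", S = "mg/dm3", Mn = "mg/dm3",
             Fe = "mg/dm3", Cu = "mg/dm3", Zn = "mg/dm3", B = "mg/dm3")
  vals_f1 <- list(
    pH = c(5.47, 5.67, 5.03, 5.62), P_rem = c(20.02, 21.12, 23.89, 20.81),
    P = c(3.01, 17.29, 9.71, 8.16), K = c(63.47, 89.53, 73.00, 78.60),
    Ca = c(3.02, 2.87, 2.09, 3.83), Mg = c(0.84, 0.74, 0.52, 0.83),
    H_Al = c(3.83, 3.32, 4.89, 3.53), CEC = c(7.94, 7.08, 7.68, 8.36),
    OM = c(30.60, 31.20, 16.70, 22.10), S = c(4.22, 6.60, 4.98, 5.07),
    Mn = c(17.18, 19.79, 11.73, 17.37), Fe = c(53.03, 58.47, 62.43, 64.79),
    Cu = c(0.77, 1.18, 1.08, 0.93), Zn = c(1.36, 1.79, 2.56, 1.98),
    B = c(0.47, 0.69, 0.34, 0.45)
  )
  vals_f2 <- list(
    pH = c(5.07, 5.67, 5.41, 5.43), P_rem = c(14.44, 16.29, 22.10, 15.39),
    P = c(3.43, 7.19, 1.50, 13.09), K = c(77.30, 98.65, 63.00, 101.90),
    Ca = c(1.39, 2.10, 1.97, 2.92), Mg = c(0.37, 0.59, 0.54, 0.76),
    H_Al = c(5.00, 3.45, 3.21, 4.12), CEC = c(6.96, 6.43, 5.88, 8.05),
    OM = c(28.10, 31.90, 17.70, 21.30), S = c(4.13, 3.57, 3.58, 4.62),
    Mn = c(8.33, 8.54, 5.51, 10.25), Fe = c(55.97, 41.52, 42.49, 66.10),
    Cu = c(1.19, 0.94, 1.00, 1.64), Zn = c(1.36, 2.90, 0.94, 3.04),
    B = c(0.76, 0.57, 0.39, 0.36)
  )
  vals <- if (farm == 1) vals_f1 else vals_f2
  tibble(
    year = rep(2018:2021, times = length(vals)),
    attribute = rep(names(vals), each = 4),
    value = unlist(vals, use.names = FALSE),
    unit = unname(units[rep(names(vals), each = 4)])
  )
}

#' Default soil-availability recommendation table
#'
#' Fallback dose table used when a unit (farm or cell) has no reference-year
#' yield to drive export dosing -- typically after skeletonization pruning
#' ("zero-harvest"). Doses are resolved from the soil test value of the
#' nutrient (P for P2O5, K for K2O, mg dm-3) and an expected-yield class in
#' 60-kg bags per hectare derived from the unit's positive-yield history.
#'
#' The shipped table is *reverse-engineered*, not an official guideline: the
#' per-hectare doses (P2O5 18 and 25 kg ha-1; K2O 225 and 300 kg ha-1) are
#' those recoverable from the study farms' published totals, and the class
#' breakpoints (soil P at 10 and 20 mg dm-3, soil K at 120 mg dm-3, yield
#' classes split at 30 bags ha-1) were chosen so the farms' average soil
#' values resolve to those doses. Supply your own table (same columns) for
#' production use; official regional recommendation tables are out of scope.
#'
#' @return A tibble with columns `nutrient` (`P2O5`/`K2O`), `soil_attribute`,
#'   `soil_class_lower`, `soil_class_upper`, `soil_class_label`,
#'   `yield_class_lower_bags`, `yield_class_upper_bags`, `yield_class_label`,
#'   `dose_kg_ha`. Class intervals are `[lower, upper)` and exhaustive over
#'   the positive reals.
#' @seealso [lookup_dose()]
#' @export
default_recommendation_table <- function() {
  tribble_rows <- list(
    # nutrient, soil lo, soil hi, soil label, yield lo, yield hi, yield label, dose
    list("P2O5", 0, 10, "low", 0, 30, "up_to_30_bags", 25.0),
    list("P2O5", 10, Inf, "sufficient", 0, 30, "up_to_30_bags", 0.0),
    list("P2O5", 0, 10, "low", 30, Inf, "over_30_bags", 30.0),
    list("P2O5", 10, 20, "medium", 30, Inf, "over_30_bags", 18.0),
    list("P2O5", 20, Inf, "sufficient", 30, Inf, "over_30_bags", 0.0),
    list("K2O", 0, 120, "low_medium", 0, 30, "up_to_30_bags", 225.0),
    list("K2O", 120, Inf, "sufficient", 0, 30, "up_to_30_bags", 0.0),
    list("K2O", 0, 120, "low_medium", 30, Inf, "over_30_bags", 300.0),
    list("K2O", 120, Inf, "sufficient", 30, Inf, "over_30_bags", 0.0)
  )
  out <- list_rbind(map(tribble_rows, \(r) {
    tibble(nutrient = r[[1]],
           soil_attribute = if (r[[1]] == "P2O5") "P" else "K",
           soil_class_lower = r[[2]], soil_class_upper = r[[3]],
           soil_class_label = r[[4]],
           yield_class_lower_bags = r[[5]], yield_class_upper_bags = r[[6]],
           yield_class_label = r[[7]], dose_kg_ha = r[[8]])
  }))
  validate_recommendation_table(out)
}

# Doses must be non-negative and monotone non-increasing in soil availability
# within each (nutrient, yield class); classes must tile (0, Inf).
validate_recommendation_table <- function(table) {
  require_columns(table, c("nutrient", "soil_class_lower", "soil_class_upper",
                           "yield_class_lower_bags", "yield_class_upper_bags",
                           "dose_kg_ha"), "recommendation_table")
  if (any(table$dose_kg_ha < 0)) {
    cellfarm_abort("recommendation doses must be >= 0")
  }
  chk <- table |>
    group_by(.data$nutrient, .data$yield_class_lower_bags) |>
    arrange(.data$soil_class_lower, .by_group = TRUE) |>
    summarise(
      monotone = all(diff(.data$dose_kg_ha) <= 0),
      tiles = first(.data$soil_class_lower) == 0 &&
        is.infinite(last(.data$soil_class_upper)) &&
        all(head(.data$soil_class_upper, -1) ==
              .data$soil_class_lower[-1]),
      .groups = "drop"
    )
  if (!all(chk$monotone)) {
    cellfarm_abort("doses must be non-increasing in soil availability within a yield class")
  }
  if (!all(chk$tiles)) {
    cellfarm_abort("soil classes must tile (0, Inf) without gaps within a yield class")
  }
  table
}
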