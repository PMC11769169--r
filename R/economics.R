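#' Revenue per hectare from yield and bag price
#'
#' Coffee is priced per 60-kg bag of processed grain:
#' `revenue = yield * 1000 / bag_kg * price`.
#'
#' @param yield_mg_ha Yield, Mg ha-1 (>= 0; vectorized).
#' @param price_usd_per_bag Price, USD per bag (> 0).
#' @param bag_kg Bag mass, kg (default 60).
#' @return Revenue in USD ha-1.
#' @export
#' @examples
#' revenue(3.11, 120)  # 6220 USD/ha
revenue <- function(yield_mg_ha, price_usd_per_bag, bag_kg = 60) {
  stopifnot(all(yield_mg_ha >= 0), all(price_usd_per_bag > 0), bag_kg > 0)
  yield_mg_ha * 1000 / bag_kg * price_usd_per_bag
}

#' Cost-allocation policy
#'
#' Maps each cost category to how it is charged to cells:
#' `per_hectare_uniform` (every cell pays the per-hectare figure),
#' `harvested_cells_only` (charged only to cells with a harvest that year)
#' or `proportional_to_yield` (scaled by the cell's share of farm yield per
#' hectare). The default charges everything uniformly; flag the harvesting
#' category `harvested_cells_only` to exempt skeletonized cells from
#' harvest costs.
#'
#' @param ... Named category flags, e.g.
#'   `allocation_policy(harvesting = "harvested_cells_only")`.
#' @param .default Flag for categories not named.
#' @return A list of class `allocation_policy`.
#' @export
allocation_policy <- function(..., .default = "per_hectare_uniform") {
  flags <- list(...)
  ok <- c("per_hectare_uniform", "harvested_cells_only", "proportional_to_yield")
  stopifnot(.default %in% ok, all(unlist(flags) %in% ok))
  structure(list(flags = flags, default = .default), class = "allocation_policy")
}

policy_flag <- function(policy, category) {
  policy$flags[[category]] %||% policy$default
}

# Categories making up each nested cost level when a breakdown is present.
level_categories <- function(categories, cost_level) {
  ops <- setdiff(categories, c(cost_summary_levels, "depreciation",
                               "return_on_capital"))
  switch(cost_level,
    effective = ops,
    total_operating = c(ops, intersect("depreciation", categories)),
    total = c(ops, intersect(c("depreciation", "return_on_capital"), categories))
  )
}

#' Allocate yearly production cost to a cell
#'
#' Resolves the USD-per-hectare cost charged to one cell in one year at a
#' nested cost level: `effective` (operations), `total_operating`
#' (+ depreciation) or `total` (+ return on capital). With the default
#' all-uniform policy the ledger's summary figure for the level is returned
#' directly; with category flags and a category breakdown present, each
#' category is charged according to its flag.
#'
#' @param ledger Cost ledger tibble (`year`, `category`, `usd_per_ha`).
#' @param year Calendar year.
#' @param policy An [allocation_policy()].
#' @param cost_level `"total"` (default), `"total_operating"` or
#'   `"effective"`.
#' @param harvested Did the cell harvest that year? (drives
#'   `harvested_cells_only` flags).
#' @param yield_share Cell yield divided by farm-mean yield (drives
#'   `proportional_to_yield` flags; default 1).
#' @return Cost in USD ha-1.
#' @export
allocate_cost <- function(ledger, year, policy = allocation_policy(),
                          cost_level = c("total", "total_operating", "effective"),
                          harvested = TRUE, yield_share = 1) {
  cost_level <- arg_match(cost_level)
  yr <- filter(as_tibble(ledger), .data$year == !!year)
  if (!nrow(yr)) {
    cellfarm_abort(paste0("cost ledger has no entries for year ", year))
  }
  summary_cat <- switch(cost_level,
    effective = "effective_operating",
    total_operating = "total_operating",
    total = "total_cost"
  )
  breakdown <- filter(yr, !.data$category %in% cost_summary_levels)
  uses_flags <- length(policy$flags) > 0 || policy$default != "per_hectare_uniform"

  if (!uses_flags || !nrow(breakdown)) {
    if (uses_flags && !nrow(breakdown)) {
      warn("allocation flags set but ledger has no category breakdown; using the summary level uniformly")
    }
    hit <- filter(yr, .data$category == summary_cat)
    if (!nrow(hit)) {
      cellfarm_abort(paste0("cost level '", summary_cat,
                            "' absent from ledger for year ", year))
    }
    return(hit$usd_per_ha)
  }

  cats <- level_categories(unique(breakdown$category), cost_level)
  rows <- filter(breakdown, .data$category %in% cats)
  sum(map_dbl(seq_len(nrow(rows)), \(i) {
    base <- rows$usd_per_ha[i]
    switch(policy_flag(policy, rows$category[i]),
      per_hectare_uniform = base,
      harvested_cells_only = if (harvested) base else 0,
      proportional_to_yield = base * yield_share
    )
  }))
}

#' Yearly profitability per cell or farm
#'
#' One record per unit and year: revenue from yield and the year's bag
#' price, allocated cost at the chosen level, and profit = revenue - cost.
#' Zero-harvest units earn no revenue but still pay the crop-maintenance
#' cost, so skeletonized seasons show up as negative profit.
#'
#' @param dataset A `farm_dataset` with yield, prices and costs panels.
#' @param level `"cell"` or `"farm"` (farm-level yields are plain cell
#'   means, matching the composite-sample convention).
#' @param policy An [allocation_policy()].
#' @param cost_level Passed to [allocate_cost()]; default `"total"`.
#' @return A tibble of class `cellfarm_profit`: `unit_id`, `year`,
#'   `yield_mg_ha`, `revenue_usd_ha`, `cost_usd_ha`, `profit_usd_ha`.
#' @export
profitability <- function(dataset, level = c("cell", "farm"),
                          policy = allocation_policy(),
                          cost_level = "total") {
  stopifnot(inherits(dataset, "farm_dataset"), !is.null(dataset$yield),
            !is.null(dataset$prices), !is.null(dataset$costs))
  level <- arg_match(level)

  base <- if (level == "farm") {
    farm_mean_yield(dataset) |>
      mutate(unit_id = dataset$farm_id, harvested = .data$yield_mg_ha > 0)
  } else {
    dataset$yield |>
      transmute(unit_id = .data$cell_id, year = .data$year,
                yield_mg_ha = .data$yield_mg_ha,
                harvested = !.data$zero_harvest & .data$yield_mg_ha > 0)
  }

  farm_year_mean <- farm_mean_yield(dataset) |>
    select("year", farm_yield = "yield_mg_ha")
  missing_years <- setdiff(unique(base$year), dataset$prices$year)
  if (length(missing_years)) {
    cellfarm_abort(paste0("price series missing year(s): ",
                          paste(missing_years, collapse = ", ")))
  }

  out <- base |>
    left_join(dataset$prices, by = "year") |>
    left_join(farm_year_mean, by = "year") |>
    mutate(
      revenue_usd_ha = revenue(.data$yield_mg_ha, .data$price_usd_per_bag),
      cost_usd_ha = map_dbl(row_number(), \(i) allocate_cost(
        dataset$costs, year[i], policy, cost_level,
        harvested = harvested[i],
        yield_share = if (farm_yield[i] > 0) yield_mg_ha[i] / farm_yield[i] else 0
      )),
      profit_usd_ha = .data$revenue_usd_ha - .data$cost_usd_ha
    ) |>
    select("unit_id", "year", "yield_mg_ha", "revenue_usd_ha",
           "cost_usd_ha", "profit_usd_ha") |>
    arrange(.data$unit_id, .data$year)
  structure(out, class = c("cellfarm_profit", class(out)),
            level = level, farm_id = dataset$farm_id)
}

#' Convert Brazilian reais to US dollars at a year's average rate
#'
#' @param amount_brl Amount in BRL (vectorized).
#' @param year Calendar year present in `rates`.
#' @param rates A price series tibble with `year` and `fx_brl_per_usd`
#'   (default: the shipped 2018-2021 series).
#' @return `amount_brl / rate(year)`, USD.
#' @export
#' @examples
#' convert_currency(100, 2020)  # 19.3956...
convert_currency <- function(amount_brl, year, rates = default_price_series()) {
  hit <- filter(as_tibble(rates), .data$year == !!year)
  if (!nrow(hit)) {
    cellfarm_abort(paste0("no exchange rate for year ", year))
  }
  amount_brl / hit$fx_brl_per_usd
}

#' Cumulative profit and yearly sign pattern per unit
#'
#' Sums yearly per-hectare profit for each unit and reports the per-year
#' sign vector, the summary behind "which cells lost money over the study".
#'
#' @param records A profitability table from [profitability()].
#' @return A tibble `unit_id`, `n_years`, `cumulative_profit_usd_ha`,
#'   `signs` (e.g. `"+-++"`, in year order), `all_negative`, `any_negative`.
#' @export
cumulative_profit <- function(records) {
  require_columns(records, c("unit_id", "year", "profit_usd_ha"), "profit records")
  if (!nrow(records)) cellfarm_abort("empty profit table")
  records |>
    as_tibble() |>
    arrange(.data$unit_id, .data$year) |>
    group_by(.data$unit_id) |>
    summarise(
      n_years = n(),
      cumulative_profit_usd_ha = sum(.data$profit_usd_ha),
      signs = paste(ifelse(.data$profit_usd_ha > 0, "+",
                           ifelse(.data$profit_usd_ha < 0, "-", "0")),
                    collapse = ""),
      all_negative = all(.data$profit_usd_ha < 0),
      any_negative = any(.data$profit_usd_ha < 0),
      .groups = "drop"
    )
}

#' @method glance cellfarm_profit
#' @export
glance.cellfarm_profit <- function(x, ...) {
  cum <- cumulative_profit(x)
  tibble(
    farm_id = attr(x, "farm_id"),
    level = attr(x, "level"),
    n_units = nrow(cum),
    n_units_cumulative_loss = sum(cum$cumulative_profit_usd_ha < 0),
    total_profit_usd_ha = sum(x$profit_usd_ha)
  )
}
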