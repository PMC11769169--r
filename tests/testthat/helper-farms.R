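# Fixture builders. `printed_farm()` reconstructs a study farm at farm
# resolution (one cell spanning the whole area) from its published yearly
# mean yields, soil averages, cost ledger and price series -- the only
# values available outside the appendix. `toy_farm()` is a small fully
# synthetic multi-cell farm with hand-computable numbers.

printed_farm <- function(farm = 1) {
  area <- if (farm == 1) 82.88 else 72.12
  yields <- if (farm == 1) c(3.11, 0.76, 2.08, 1.07) else c(2.36, 0.29, 2.05, 0.00)
  zh <- if (farm == 1) rep(FALSE, 4) else c(FALSE, FALSE, FALSE, TRUE)
  id <- paste0("farm", farm)
  cells <- tibble::tibble(cell_id = id, farm_id = as.character(farm),
                          area_ha = area)
  yld <- tibble::tibble(cell_id = id, year = 2018:2021,
                        yield_mg_ha = yields, zero_harvest = zh)
  soil <- default_soil_profile(farm) |>
    dplyr::mutate(cell_id = id) |>
    dplyr::select(cell_id, year, attribute, value, unit)
  farm_dataset(cells, yield = yld, soil = soil,
               costs = default_cost_ledger(), prices = default_price_series())
}

# Published farm/year/nutrient recommendation totals (kg) with the published
# difference and percent columns, used as *inputs* to the comparison
# arithmetic (per-cell doses live in an unavailable appendix).
published_totals <- function() {
  tibble::tribble(
    ~farm_id, ~nutrient, ~target_year, ~um_total_kg, ~lm_total_kg, ~difference_kg_pub, ~pct_pub,
    "1", "P2O5", 2019,  2575.85,  2604.56,    28.71,   1.11,
    "1", "P2O5", 2020,  1491.79,  1345.39,  -146.40,  -9.81,
    "1", "P2O5", 2021,  1720.06,  1793.09,    73.03,   4.25,
    "1", "P2O5", 2022,   888.08,  1578.56,   690.49,  77.75,
    "1", "K2O",  2019, 25329.19, 24931.94,  -397.25,  -1.57,
    "1", "K2O",  2020, 24863.10, 14037.45, -10825.65, -43.54,
    "1", "K2O",  2021, 16913.95, 17632.04,   718.09,   4.25,
    "1", "K2O",  2022,  8732.76, 13455.99,  4723.24,  54.09,
    "2", "P2O5", 2019,  1700.50,  1841.42,   140.92,   8.29,
    "2", "P2O5", 2020,  1803.00,  1575.37,  -227.63, -12.63,
    "2", "P2O5", 2021,  1477.91,  1541.26,    63.35,   4.29,
    "2", "P2O5", 2022,     0.00,  1228.76,  1228.76, 100.00,
    "2", "K2O",  2019, 16721.61, 18107.33,  1385.72,   8.29,
    "2", "K2O",  2020, 16227.00, 12410.81, -3816.19, -23.52,
    "2", "K2O",  2021, 14532.80, 15155.73,   622.93,   4.29,
    "2", "K2O",  2022, 16227.00, 16292.85,    65.85,   0.41
  )
}

toy_farm <- function(n_cells = 3, base = c(3, 2, 1), areas = c(2, 4, 6)) {
  stopifnot(length(base) == n_cells, length(areas) == n_cells)
  ids <- paste0("c", seq_len(n_cells))
  cells <- tibble::tibble(cell_id = ids, farm_id = "toy", area_ha = areas)
  yld <- tidyr::expand_grid(cell_id = ids, year = 2018:2021) |>
    dplyr::mutate(
      yield_mg_ha = rep(base, each = 4) * rep(c(1.5, 0.5, 1.5, 0.5), n_cells),
      zero_harvest = FALSE
    )
  farm_dataset(cells, yield = yld, costs = default_cost_ledger(),
               prices = default_price_series())
}

# one random farm with strictly positive yields (export basis everywhere)
random_positive_farm <- function(n_cells, years = 2018:2021) {
  ids <- paste0("c", seq_len(n_cells))
  cells <- tibble::tibble(cell_id = ids, farm_id = "rand",
                          area_ha = runif(n_cells, 0.5, 12))
  yld <- tidyr::expand_grid(cell_id = ids, year = years) |>
    dplyr::mutate(yield_mg_ha = runif(dplyr::n(), 0.1, 6),
                  zero_harvest = FALSE)
  farm_dataset(cells, yield = yld)
}
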