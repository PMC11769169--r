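test_that("revenue converts yield to bags at the year's price", {
  expect_equal(revenue(0, 120), 0)
  expect_equal(revenue(3.11, 120), 6220)
  expect_equal(revenue(1.07, 178), 3174 + 1 / 3)
})

test_that("cost allocation honours levels, policies and flags", {
  ledger <- default_cost_ledger()
  expect_equal(allocate_cost(ledger, 2019, cost_level = "total"), 3369)
  expect_equal(allocate_cost(ledger, 2019, cost_level = "effective"), 2393)
  expect_error(allocate_cost(ledger, 1999), "no entries")

  breakdown <- tibble::tibble(
    year = 2019,
    category = c("pruning", "harvesting", "depreciation", "return_on_capital"),
    usd_per_ha = c(1000, 500, 300, 200)
  )
  pol <- allocation_policy(harvesting = "harvested_cells_only")
  expect_equal(allocate_cost(breakdown, 2019, pol, "total", harvested = TRUE),
               2000)
  expect_equal(allocate_cost(breakdown, 2019, pol, "total", harvested = FALSE),
               1500)
  expect_equal(allocate_cost(breakdown, 2019, pol, "effective",
                             harvested = FALSE), 1000)
  pol2 <- allocation_policy(harvesting = "proportional_to_yield")
  expect_equal(allocate_cost(breakdown, 2019, pol2, "total",
                             yield_share = 0.5), 1750)
})

test_that("farm-1 profitability reproduces the published yearly ladder and signs", {
  prof <- profitability(printed_farm(1), level = "farm")
  expect_equal(prof$profit_usd_ha[prof$year == 2019],
               0.76 * 1000 / 60 * 107 - 3369)  # ~ -2013.67
  expect_equal(sign(prof$profit_usd_ha), c(1, -1, 1, 1))
  expect_equal(prof$profit_usd_ha, prof$revenue_usd_ha - prof$cost_usd_ha)
})

test_that("zero-harvest cells earn nothing but still pay maintenance", {
  cells <- tibble::tibble(cell_id = c("a", "b"), farm_id = "f",
                          area_ha = c(1, 1))
  yld <- tidyr::expand_grid(cell_id = c("a", "b"), year = 2018:2019) |>
    dplyr::mutate(yield_mg_ha = c(2, 0, 2, 1),
                  zero_harvest = c(FALSE, TRUE, FALSE, FALSE))
  farm <- farm_dataset(cells, yield = yld, costs = default_cost_ledger(),
                       prices = default_price_series())
  prof <- profitability(farm, level = "cell")
  zh <- dplyr::filter(prof, unit_id == "a", year == 2019)
  expect_equal(zh$revenue_usd_ha, 0)
  expect_equal(zh$profit_usd_ha, -zh$cost_usd_ha)
})

test_that("farm profit is the area-weighted mean of cell profits under uniform costs", {
  sim <- simulate_farm(simulation_config(seed = 31))
  cellp <- profitability(sim$farm, level = "cell")
  joined <- dplyr::left_join(cellp, sim$farm$cells, by = c(unit_id = "cell_id"))
  by_year <- joined |>
    dplyr::group_by(year) |>
    dplyr::summarise(
      wprofit = sum(profit_usd_ha * area_ha) / sum(area_ha),
      wyield = sum(yield_mg_ha * area_ha) / sum(area_ha))
  # recompute farm profit from the area-weighted yield: same cost per ha
  direct <- revenue(by_year$wyield, default_price_series()$price_usd_per_bag) -
    sapply(2018:2021, \(y) allocate_cost(default_cost_ledger(), y))
  expect_equal(by_year$wprofit, direct)
})

test_that("currency conversion divides by the year's rate and round-trips", {
  expect_equal(convert_currency(0, 2019), 0)
  expect_equal(convert_currency(100, 2020), 100 / 5.1558)
  expect_equal(convert_currency(3.6542, 2018), 1)
  expect_error(convert_currency(1, 1990), "no exchange rate")
  for (yr in 2018:2021) {
    rate <- default_price_series()$fx_brl_per_usd[default_price_series()$year == yr]
    expect_equal(convert_currency(123.45, yr) * rate, 123.45)
  }
})

test_that("cumulative profit sums years and reports sign patterns", {
  rec <- tibble::tibble(unit_id = "u", year = 2018:2020,
                        profit_usd_ha = c(100, -50, 25))
  cum <- cumulative_profit(rec)
  expect_equal(cum$cumulative_profit_usd_ha, 75)
  expect_equal(cum$signs, "+-+")
  expect_false(cum$all_negative)
  expect_true(cum$any_negative)

  allneg <- tibble::tibble(unit_id = "u", year = 2018:2019,
                           profit_usd_ha = c(-10, -20))
  expect_true(cumulative_profit(allneg)$all_negative)
  zero <- tibble::tibble(unit_id = "u", year = 2018, profit_usd_ha = 0)
  expect_equal(cumulative_profit(zero)$cumulative_profit_usd_ha, 0)
  expect_error(cumulative_profit(rec[0, ]), "empty")
})
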