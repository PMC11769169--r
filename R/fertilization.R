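#' Export-based fertilizer dose
#'
#' Nutrient-export dosing replaces what the previous crop removed: the
#' reference yield is expressed in 60-kg bags per hectare and multiplied by
#' the per-bag whole-plant demand (0.60 kg P2O5, 5.90 kg K2O by default).
#'
#' @param reference_yield Reference-year yield, Mg ha-1 (>= 0; vectorized).
#' @param nutrient `"P2O5"` or `"K2O"`.
#' @param coeff An [export_coefficients()] object.
#' @return Dose in kg ha-1: `(reference_yield * 1000 / bag_kg) * per_bag`.
#' @export
#' @examples
#' export_dose(3.11, "P2O5")  # 31.10 kg/ha
#' export_dose(0.60, "K2O")   # 59.00 kg/ha
export_dose <- function(reference_yield, nutrient,
                        coeff = export_coefficients()) {
  per_bag <- switch(nutrient,
    P2O5 = coeff$p2o5_per_bag,
    K2O = coeff$k2o_per_bag,
    cellfarm_abort(paste0("unknown nutrient '", nutrient,
                          "'; expected P2O5 or K2O"))
  )
  stopifnot(all(reference_yield >= 0))
  (reference_yield * 1000 / coeff$bag_kg) * per_bag
}

#' Soil-availability lookup dose
#'
#' Fallback dosing for units without a usable reference yield (typically
#' after skeletonization): the dose is read from a recommendation table by
#' the soil test value of the nutrient and an expected-yield class in 60-kg
#' bags per hectare. An uncovered (soil, yield) combination is an error,
#' never a silent zero.
#'
#' @param soil_value Soil test value, mg dm-3 (P for P2O5, K for K2O).
#' @param expected_yield_bags Expected yield, bags ha-1, from the unit's
#'   yield history.
#' @param nutrient `"P2O5"` or `"K2O"`.
#' @param table A recommendation table; see [default_recommendation_table()].
#' @return A one-row tibble `dose_kg_ha`, `soil_class`, `yield_class`.
#' @export
lookup_dose <- function(soil_value, expected_yield_bags, nutrient,
                        table = default_recommendation_table()) {
  validate_recommendation_table(table)
  stopifnot(length(soil_value) == 1, length(expected_yield_bags) == 1,
            soil_value >= 0, expected_yield_bags >= 0)
  hit <- table |>
    filter(.data$nutrient == !!nutrient,
           .data$soil_class_lower <= soil_value,
           soil_value < .data$soil_class_upper,
           .data$yield_class_lower_bags <= expected_yield_bags,
           expected_yield_bags < .data$yield_class_upper_bags)
  if (nrow(hit) != 1) {
    cellfarm_abort(paste0(
      "recommendation table does not cover nutrient=", nutrient,
      ", soil_value=", soil_value, ", expected_yield_bags=",
      round(expected_yield_bags, 2),
      if (nrow(hit) > 1) " (overlapping classes)" else " (gap)"))
  }
  tibble(dose_kg_ha = hit$dose_kg_ha,
         soil_class = hit$soil_class_label %||% NA_character_,
         yield_class = hit$yield_class_label %||% NA_character_)
}

# Expected yield (bags/ha) from the positive-yield history up to and
# including the reference year. Skeletonized (zero) seasons reflect pruning
# management, not yield potential, so they are excluded from the expectation.
expected_yield_bags <- function(yields, bag_kg = 60) {
  pos <- yields[is.finite(yields) & yields > 0]
  if (!length(pos)) return(0)
  mean(pos) * 1000 / bag_kg
}

#' Fertilizer recommendation under uniform or localized management
#'
#' Computes next-season P2O5 and K2O doses for every cell of a farm. Data of
#' the reference year (`target_year - 1`) drive the doses of `target_year`.
#' Two strategies:
#' * **UM** (uniform management): one farm-wide dose per nutrient from the
#'   farm-average reference yield (area-weighted) and farm-average soil
#'   values, applied to every hectare;
#' * **LM_cell** (localized management): a per-cell dose from that cell's
#'   own reference yield and soil values.
#'
#' Dose basis per unit: `export` when the unit's reference yield exceeds
#' `yield_threshold` and the season is not flagged zero-harvest; otherwise
#' the soil-availability `lookup` fallback is used with the unit's
#' positive-yield history as expected yield. The default threshold of 0
#' switches to lookup only for true zero-harvest units; raise it to treat
#' skeletonization-depressed reference seasons as non-representative (e.g.
#' 1 Mg ha-1 reproduces the published management pattern of the two study
#' farms).
#'
#' @param dataset A `farm_dataset` with yield (and, when lookup can trigger,
#'   soil) panels.
#' @param target_year Year the recommendation is for; `target_year - 1` must
#'   be in the yield panel.
#' @param strategy `"UM"` or `"LM_cell"`.
#' @param nutrients Character subset of `c("P2O5", "K2O")`.
#' @param coeff [export_coefficients()].
#' @param table Recommendation table for the lookup fallback; only required
#'   when some unit needs it.
#' @param yield_threshold Mg ha-1; export basis requires reference yield
#'   strictly above this.
#' @param include_zero_harvest Include zero-harvest cells in the UM
#'   farm-mean reference yield (default TRUE).
#' @param um_weight How the UM farm-mean reference yield aggregates cells:
#'   `"area"` (area-weighted, default) or `"none"` (plain mean of the
#'   composite cell values). Under pure export dosing an area-weighted UM
#'   mean makes UM and LM_cell farm totals coincide exactly (export dosing
#'   is linear in yield); a plain mean lets them diverge on farms whose
#'   large and small cells yield differently.
#' @return A tibble of class `cellfarm_doses`: one row per cell and
#'   nutrient with `farm_id`, `unit_id`, `target_year`, `nutrient`,
#'   `strategy`, `basis`, `reference_yield_mg_ha`, `area_ha`, `dose_kg_ha`,
#'   `dose_kg_total` (= dose_kg_ha * area_ha), `soil_class`, `yield_class`.
#' @export
recommend <- function(dataset, target_year, strategy = c("UM", "LM_cell"),
                      nutrients = c("P2O5", "K2O"),
                      coeff = export_coefficients(),
                      table = default_recommendation_table(),
                      yield_threshold = 0,
                      include_zero_harvest = TRUE,
                      um_weight = c("area", "none")) {
  stopifnot(inherits(dataset, "farm_dataset"), !is.null(dataset$yield))
  strategy <- arg_match(strategy)
  nutrients <- match.arg(nutrients, several.ok = TRUE)
  ref_year <- target_year - 1
  if (!ref_year %in% dataset$yield$year) {
    cellfarm_abort(paste0("reference year ", ref_year,
                          " is absent from the yield panel"))
  }

  cells <- dataset$cells
  yld <- tidy.farm_dataset(dataset)

  if (strategy == "UM") {
    series <- farm_mean_yield(dataset, weight = arg_match(um_weight),
                              include_zero_harvest = include_zero_harvest)
    ref <- filter(series, .data$year == ref_year)
    ref_yield <- ref$yield_mg_ha
    ref_zero <- ref$zero_harvest
    hist <- filter(series, .data$year <= ref_year)$yield_mg_ha
    soil_value_of <- function(attr) {
      farm_soil_mean(dataset, attr, ref_year)
    }
    unit_dose <- function(nutrient) {
      one_dose(nutrient, ref_yield, ref_zero, hist, soil_value_of,
               coeff, table, yield_threshold)
    }
    doses <- list_rbind(map(nutrients, unit_dose))
    out <- tidyr::expand_grid(cell_id = cells$cell_id,
                              nutrient = nutrients) |>
      left_join(doses, by = "nutrient") |>
      left_join(select(cells, "cell_id", "area_ha"), by = "cell_id")
  } else {
    per_cell <- function(cid, nutrient) {
      cy <- filter(yld, .data$cell_id == cid)
      ref <- filter(cy, .data$year == ref_year)
      hist <- filter(cy, .data$year <= ref_year)$yield_mg_ha
      soil_value_of <- function(attr) cell_soil_value(dataset, cid, attr, ref_year)
      one_dose(nutrient, ref$yield_mg_ha, ref$zero_harvest, hist,
               soil_value_of, coeff, table, yield_threshold) |>
        mutate(cell_id = cid)
    }
    grid <- tidyr::expand_grid(cell_id = cells$cell_id, nutrient = nutrients)
    out <- list_rbind(map2(grid$cell_id, grid$nutrient, per_cell)) |>
      left_join(select(cells, "cell_id", "area_ha"), by = "cell_id")
  }

  out <- out |>
    mutate(
      farm_id = dataset$farm_id,
      unit_id = .data$cell_id,
      target_year = target_year,
      strategy = strategy,
      dose_kg_total = .data$dose_kg_ha * .data$area_ha
    ) |>
    select("farm_id", "unit_id", "target_year", "nutrient", "strategy",
           "basis", "reference_yield_mg_ha", "area_ha", "dose_kg_ha",
           "dose_kg_total", "soil_class", "yield_class") |>
    arrange(.data$nutrient, .data$unit_id)
  structure(out, class = c("cellfarm_doses", class(out)))
}

# Dose for one unit and nutrient; soil_value_of is called lazily so purely
# export-based runs never require a soil panel.
one_dose <- function(nutrient, ref_yield, ref_zero, hist, soil_value_of,
                     coeff, table, yield_threshold) {
  use_export <- isTRUE(ref_yield > yield_threshold) && !isTRUE(ref_zero)
  if (use_export) {
    tibble(nutrient = nutrient, basis = "export",
           reference_yield_mg_ha = ref_yield,
           dose_kg_ha = export_dose(ref_yield, nutrient, coeff),
           soil_class = NA_character_, yield_class = NA_character_)
  } else {
    if (is.null(table)) {
      cellfarm_abort("lookup basis required but no recommendation table configured")
    }
    attr <- if (nutrient == "P2O5") "P" else "K"
    sv <- soil_value_of(attr)
    hit <- lookup_dose(sv, expected_yield_bags(hist, coeff$bag_kg), nutrient,
                       table)
    tibble(nutrient = nutrient, basis = "lookup",
           reference_yield_mg_ha = ref_yield,
           dose_kg_ha = hit$dose_kg_ha,
           soil_class = hit$soil_class, yield_class = hit$yield_class)
  }
}

farm_soil_mean <- function(dataset, attr, year) {
  if (is.null(dataset$soil)) {
    cellfarm_abort(paste0("soil panel required for lookup dosing (attribute ",
                          attr, ", year ", year, ")"))
  }
  v <- dataset$soil |>
    filter(.data$attribute == attr, .data$year == !!year) |>
    pull("value")
  if (!length(v)) {
    cellfarm_abort(paste0("no soil '", attr, "' values for year ", year))
  }
  mean(v)
}

cell_soil_value <- function(dataset, cid, attr, year) {
  if (is.null(dataset$soil)) {
    cellfarm_abort(paste0("soil panel required for lookup dosing (cell ",
                          cid, ", attribute ", attr, ")"))
  }
  v <- dataset$soil |>
    filter(.data$cell_id == cid, .data$attribute == attr,
           .data$year == !!year) |>
    pull("value")
  if (!length(v)) {
    cellfarm_abort(paste0("no soil '", attr, "' value for cell ", cid,
                          ", year ", year))
  }
  mean(v)
}

#' Percentage-difference convention for strategy totals
#'
#' `pct = 100 * (lm - um) / um` when `um > 0`; `100` when `um = 0` and
#' `lm > 0` (localized management recommends where uniform management
#' recommends nothing); `0` when both totals are zero.
#'
#' @param um_total_kg,lm_total_kg Farm totals in kg (vectorized).
#' @return Percent difference of the localized total relative to uniform.
#' @export
pct_difference <- function(um_total_kg, lm_total_kg) {
  stopifnot(length(um_total_kg) == length(lm_total_kg))
  dplyr::case_when(
    um_total_kg > 0 ~ 100 * (lm_total_kg - um_total_kg) / um_total_kg,
    lm_total_kg > 0 ~ 100,
    .default = 0
  )
}

#' Compare uniform and localized recommendation totals
#'
#' Aggregates two dose tables (or accepts pre-aggregated totals) and reports,
#' per farm, target year and nutrient: both totals, their difference
#' (localized minus uniform, kg) and the percent difference under the
#' [pct_difference()] convention.
#'
#' @param um,lm Dose tables from [recommend()] (any mix of cells), or
#'   tibbles already carrying `um_total_kg` / `lm_total_kg` columns along
#'   with `farm_id`, `target_year`, `nutrient`.
#' @return A tibble of class `cellfarm_comparison` with `farm_id`,
#'   `target_year`, `nutrient`, `um_total_kg`, `lm_total_kg`,
#'   `difference_kg`, `pct`.
#' @export
compare_strategies <- function(um, lm) {
  um_t <- totals_of(um, "um_total_kg")
  lm_t <- totals_of(lm, "lm_total_kg")
  keys <- c("farm_id", "target_year", "nutrient")
  if (!identical(nrow(um_t), nrow(lm_t)) ||
      nrow(anti_join(um_t, lm_t, by = keys)) > 0) {
    cellfarm_abort("UM and LM tables cover different farm/year/nutrient keys")
  }
  out <- inner_join(um_t, lm_t, by = keys) |>
    mutate(
      difference_kg = .data$lm_total_kg - .data$um_total_kg,
      pct = pct_difference(.data$um_total_kg, .data$lm_total_kg)
    ) |>
    arrange(.data$farm_id, .data$nutrient, .data$target_year)
  structure(out, class = c("cellfarm_comparison", class(out)))
}

totals_of <- function(x, total_col) {
  keys <- c("farm_id", "target_year", "nutrient")
  if (total_col %in% names(x)) {
    return(select(as_tibble(x), all_of(c(keys, total_col))))
  }
  require_columns(x, c(keys, "dose_kg_total"), "doses")
  x |>
    as_tibble() |>
    group_by(across(all_of(keys))) |>
    summarise("{total_col}" := sum(.data$dose_kg_total), .groups = "drop")
}

#' Multi-year mean of strategy percent differences
#'
#' Arithmetic mean of the yearly percent differences between localized and
#' uniform totals, the summary used to state whether localized management
#' raised or lowered a nutrient's recommendation over a study window.
#'
#' @param pcts Non-empty numeric vector of yearly percent differences.
#' @return Their arithmetic mean.
#' @export
#' @examples
#' mean_pct_over_years(c(8.29, -12.63, 4.29, 100.00))  # ~25.00
mean_pct_over_years <- function(pcts) {
  if (!length(pcts)) cellfarm_abort("empty percent vector")
  mean(pcts)
}

#' @method glance cellfarm_comparison
#' @export
glance.cellfarm_comparison <- function(x, ...) {
  x |>
    group_by(.data$farm_id, .data$nutrient) |>
    summarise(
      n_years = n(),
      mean_pct = mean_pct_over_years(.data$pct),
      total_difference_kg = sum(.data$difference_kg),
      .groups = "drop"
    )
}
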