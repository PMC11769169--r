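#' Assemble a validated farm dataset
#'
#' A `farm_dataset` bundles the tabular panels of a cell-size study: one row
#' per cell (descriptors), yield by cell and season, soil and leaf attribute
#' panels in long form, a yearly cost ledger and a price/exchange series.
#' Every panel is a tibble; optional panels may be `NULL`. All type
#' invariants are checked at construction time, so downstream verbs can
#' assume a well-formed object.
#'
#' @param cells Tibble with columns `cell_id`, `farm_id`, `area_ha` (> 0) and
#'   optionally `variety`, `row_spacing_m`, `plant_spacing_m`.
#' @param yield Optional tibble `cell_id`, `year`, `yield_mg_ha` (>= 0),
#'   `zero_harvest` (logical). A `zero_harvest` season must carry yield 0.
#' @param soil,leaf Optional long panels `cell_id`, `year`, `attribute`,
#'   `value`, `unit`; attributes are restricted to the package's fixed soil
#'   vocabulary (`pH`, `P_rem`, `P`, `K`, `Ca`, `Mg`, `H_Al`, `CEC`, `OM`,
#'   `S`, `Mn`, `Fe`, `Cu`, `Zn`, `B`) for `soil`; `leaf` attributes are free.
#' @param costs Optional cost ledger `year`, `category`, `usd_per_ha`.
#'   Categories may include the nested summary levels `effective_operating`,
#'   `total_operating` and `total_cost` (which must be non-decreasing in that
#'   order within a year) plus any operational breakdown.
#' @param prices Optional tibble `year`, `price_usd_per_bag`,
#'   `fx_brl_per_usd`, both strictly positive.
#' @param geometry Optional tibble `cell_id`, `feature` (list-column of
#'   GeoJSON feature lists), as produced by [attach_geometry()].
#' @param farm_id Farm identifier; defaults to the single `farm_id` found in
#'   `cells`.
#'
#' @return An object of class `farm_dataset`.
#' @seealso [read_farm()], [simulate_farm()], [validate_farm()]
#' @export
#' @examples
#' cells <- tibble::tibble(cell_id = c("c1", "c2"), farm_id = "f1",
#'                         area_ha = c(4, 6))
#' yld <- tidyr::expand_grid(cell_id = c("c1", "c2"), year = 2018:2021)
#' yld$yield_mg_ha <- rep(c(3, 1, 2.5, 0.5), each = 2)
#' yld$zero_harvest <- FALSE
#' farm_dataset(cells, yield = yld)
farm_dataset <- function(cells, yield = NULL, soil = NULL, leaf = NULL,
                         costs = NULL, prices = NULL, geometry = NULL,
                         farm_id = NULL) {
  cells <- as_tibble(cells)
  x <- structure(
    list(
      farm_id = farm_id %||% unique(cells$farm_id)[1],
      cells = cells,
      yield = if (!is.null(yield)) as_tibble(yield),
      soil = if (!is.null(soil)) as_tibble(soil),
      leaf = if (!is.null(leaf)) as_tibble(leaf),
      costs = if (!is.null(costs)) as_tibble(costs),
      prices = if (!is.null(prices)) as_tibble(prices),
      geometry = if (!is.null(geometry)) as_tibble(geometry)
    ),
    class = "farm_dataset"
  )
  validate_farm(x)
}

#' Check every invariant of a farm dataset
#'
#' Called by [farm_dataset()] and [read_farm()]; exported so that externally
#' assembled objects can be re-checked after manipulation. Errors name the
#' offending cell, year or column.
#'
#' @param x A `farm_dataset`.
#' @return `x`, invisibly-validated (returned unchanged).
#' @export
validate_farm <- function(x) {
  stopifnot(inherits(x, "farm_dataset"))
  cells <- x$cells
  require_columns(cells, c("cell_id", "farm_id", "area_ha"), "cells")
  if (anyDuplicated(cells$cell_id)) {
    dup <- cells$cell_id[duplicated(cells$cell_id)][1]
    cellfarm_abort(paste0("duplicate cell_id within farm: '", dup, "'"))
  }
  bad_area <- cells$cell_id[!is.finite(cells$area_ha) | cells$area_ha <= 0]
  if (length(bad_area)) {
    cellfarm_abort(paste0("area_ha must be strictly positive; offending cell(s): ",
                          paste(bad_area, collapse = ", ")))
  }
  for (sp in intersect(c("row_spacing_m", "plant_spacing_m"), names(cells))) {
    bad <- cells$cell_id[!is.na(cells[[sp]]) & cells[[sp]] <= 0]
    if (length(bad)) {
      cellfarm_abort(paste0(sp, " must be > 0; offending cell(s): ",
                            paste(bad, collapse = ", ")))
    }
  }

  if (!is.null(x$yield)) {
    yld <- x$yield
    require_columns(yld, c("cell_id", "year", "yield_mg_ha", "zero_harvest"), "yield")
    check_known_cells(yld$cell_id, cells$cell_id, "yield")
    dup <- duplicated(yld[c("cell_id", "year")])
    if (any(dup)) {
      k <- yld[dup, ][1, ]
      cellfarm_abort(paste0("duplicate (cell, year) yield row: cell '",
                            k$cell_id, "', year ", k$year))
    }
    neg <- !is.na(yld$yield_mg_ha) & yld$yield_mg_ha < 0
    if (any(neg)) {
      k <- yld[neg, ][1, ]
      cellfarm_abort(paste0("negative yield for cell '", k$cell_id,
                            "', year ", k$year))
    }
    zh_bad <- yld$zero_harvest %in% TRUE & yld$yield_mg_ha != 0
    if (any(zh_bad)) {
      k <- yld[zh_bad, ][1, ]
      cellfarm_abort(paste0("zero_harvest flagged but yield non-zero: cell '",
                            k$cell_id, "', year ", k$year))
    }
  }

  if (!is.null(x$soil)) {
    soil <- x$soil
    require_columns(soil, c("cell_id", "year", "attribute", "value"), "soil")
    unknown <- setdiff(unique(soil$attribute), soil_attribute_vocabulary)
    if (length(unknown)) {
      cellfarm_abort(paste0("unknown soil attribute(s): ",
                            paste(unknown, collapse = ", "),
                            "; expected one of: ",
                            paste(soil_attribute_vocabulary, collapse = ", ")))
    }
    check_known_cells(soil$cell_id, cells$cell_id, "soil")
  }
  if (!is.null(x$leaf)) {
    require_columns(x$leaf, c("cell_id", "attribute", "value"), "leaf")
    check_known_cells(x$leaf$cell_id, cells$cell_id, "leaf")
  }

  if (!is.null(x$costs)) {
    require_columns(x$costs, c("year", "category", "usd_per_ha"), "costs")
    lv <- x$costs |>
      filter(.data$category %in% cost_summary_levels) |>
      pivot_wider(id_cols = "year", names_from = "category",
                  values_from = "usd_per_ha")
    if (all(cost_summary_levels %in% names(lv))) {
      bad <- lv$year[lv$effective_operating > lv$total_operating |
                       lv$total_operating > lv$total_cost]
      if (length(bad)) {
        cellfarm_abort(paste0(
          "cost levels must satisfy effective_operating <= total_operating ",
          "<= total_cost; violated in year(s): ", paste(bad, collapse = ", ")))
      }
    }
  }

  if (!is.null(x$prices)) {
    require_columns(x$prices, c("year", "price_usd_per_bag", "fx_brl_per_usd"),
                    "prices")
    if (any(x$prices$price_usd_per_bag <= 0) || any(x$prices$fx_brl_per_usd <= 0)) {
      cellfarm_abort("prices and exchange rates must be strictly positive")
    }
  }

  yrs <- farm_years(x)
  if (length(yrs) && is.unsorted(yrs, strictly = TRUE)) {
    cellfarm_abort("years must be strictly increasing integers")
  }
  x
}

require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    cellfarm_abort(paste0("table '", table, "' is missing mandatory column(s): ",
                          paste(missing, collapse = ", ")),
                   class = "cellfarm_schema_error")
  }
  invisible(df)
}

check_known_cells <- function(ids, known, table) {
  unknown <- setdiff(unique(ids), known)
  if (length(unknown)) {
    cellfarm_abort(paste0("table '", table, "' references cell(s) absent from ",
                          "the descriptor table: ", paste(unknown, collapse = ", ")))
  }
  invisible(NULL)
}

farm_years <- function(x) {
  if (is.null(x$yield)) integer() else sort(unique(x$yield$year))
}

#' @export
print.farm_dataset <- function(x, ...) {
  cat("<farm_dataset> farm '", x$farm_id, "'\n", sep = "")
  cat("  cells: ", nrow(x$cells), " (", round(sum(x$cells$area_ha), 2),
      " ha)\n", sep = "")
  yrs <- farm_years(x)
  if (length(yrs)) cat("  yield years: ", paste(range(yrs), collapse = "-"), "\n", sep = "")
  for (p in c("soil", "leaf", "costs", "prices", "geometry")) {
    if (!is.null(x[[p]])) cat("  ", p, ": ", nrow(x[[p]]), " rows\n", sep = "")
  }
  invisible(x)
}

#' Tidy a farm dataset into a long cell-by-year table
#'
#' Returns the yield panel joined with the cell descriptors: one row per cell
#' and season with area, variety and yield. This is the canonical input shape
#' for ad-hoc dplyr/ggplot2 work outside the packaged verbs.
#'
#' @param x A `farm_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per (cell, year).
#' @method tidy farm_dataset
#' @export
tidy.farm_dataset <- function(x, ...) {
  if (is.null(x$yield)) {
    return(as_tibble(x$cells))
  }
  x$yield |>
    left_join(x$cells, by = "cell_id") |>
    relocate("farm_id", "cell_id", "area_ha", "year") |>
    arrange(.data$cell_id, .data$year)
}

#' One-row summary of a farm dataset
#'
#' @param x A `farm_dataset`.
#' @param ... Unused.
#' @return A tibble with one row: farm id, cell count, total area, year span
#'   and which optional panels are present.
#' @method glance farm_dataset
#' @export
glance.farm_dataset <- function(x, ...) {
  yrs <- farm_years(x)
  tibble(
    farm_id = x$farm_id,
    n_cells = nrow(x$cells),
    total_area_ha = sum(x$cells$area_ha),
    first_year = if (length(yrs)) min(yrs) else NA_integer_,
    last_year = if (length(yrs)) max(yrs) else NA_integer_,
    has_soil = !is.null(x$soil),
    has_leaf = !is.null(x$leaf),
    has_costs = !is.null(x$costs),
    has_prices = !is.null(x$prices),
    has_geometry = !is.null(x$geometry)
  )
}

# Farm-level yearly yield series. Unweighted cell mean by default (each cell
# contributes one composite value); area-weighted on request.
farm_mean_yield <- function(x, weight = c("none", "area"),
                            include_zero_harvest = TRUE) {
  weight <- arg_match(weight)
  stopifnot(!is.null(x$yield))
  df <- tidy.farm_dataset(x)
  if (!include_zero_harvest) df <- filter(df, !.data$zero_harvest)
  df |>
    group_by(year = .data$year) |>
    summarise(
      yield_mg_ha = if (weight == "area") {
        sum(.data$yield_mg_ha * .data$area_ha) / sum(.data$area_ha)
      } else {
        mean(.data$yield_mg_ha)
      },
      zero_harvest = all(.data$zero_harvest),
      .groups = "drop"
    )
}
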