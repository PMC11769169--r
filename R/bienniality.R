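#' Convert harvested coffee volume to yield
#'
#' Field harvest is measured as total wet volume per cell; ten-odd 2-L
#' calibration samples are dried and weighed to give a volume-to-mass
#' conversion factor, and the cell total is converted to Mg per hectare of
#' processed coffee.
#'
#' @param total_volume_l Total harvested volume for the cell, litres (>= 0).
#' @param calibration Data frame with columns `sample_volume_l` and
#'   `dry_mass_kg`, at least one row.
#' @param area_ha Cell area in hectares (> 0).
#' @param processing_factor Mass retained through grain processing, in
#'   (0, 1]. Default 1 (no processing loss assumed); set from local practice.
#' @return Yield in Mg ha-1:
#'   `total_volume_l * mean(dry_mass_kg / sample_volume_l) * processing_factor / (1000 * area_ha)`.
#' @export
#' @examples
#' calib <- data.frame(sample_volume_l = rep(2, 10), dry_mass_kg = rep(0.5, 10))
#' volume_to_yield(40000, calib, area_ha = 10, processing_factor = 0.5)
volume_to_yield <- function(total_volume_l, calibration, area_ha,
                            processing_factor = 1) {
  if (is.null(calibration) || nrow(calibration) < 1) {
    cellfarm_abort("at least one calibration sample (volume, dry mass) is required")
  }
  require_columns(calibration, c("sample_volume_l", "dry_mass_kg"), "calibration")
  stopifnot(total_volume_l >= 0, all(calibration$sample_volume_l > 0),
            all(calibration$dry_mass_kg >= 0),
            processing_factor > 0, processing_factor <= 1)
  if (!is.finite(area_ha) || area_ha <= 0) {
    cellfarm_abort("area_ha must be strictly positive")
  }
  factor_kg_l <- mean(calibration$dry_mass_kg / calibration$sample_volume_l)
  total_volume_l * factor_kg_l * processing_factor / (1000 * area_ha)
}

#' Split four seasons into the high- and low-bearing pair
#'
#' Biennial bearing alternates reproductive (high) and vegetative (low)
#' seasons; the bienniality magnitude needs the four study years split into
#' the two high and two low years. With `pairing = "auto"` the split follows
#' calendar-year parity: the parity (even/odd years) with the larger mean
#' yield is the high pair. An explicit pairing is returned verbatim.
#'
#' @param yields Named numeric vector of yields (names are calendar years),
#'   or a data frame with `year` and `yield_mg_ha`. Exactly four years.
#' @param pairing `"auto"`, or a list with integer vectors `high` and `low`.
#' @return A list with `high` and `low` (two years each) and `method`.
#' @export
classify_years <- function(yields, pairing = "auto") {
  if (is.data.frame(yields)) {
    yields <- setNames(yields$yield_mg_ha, yields$year)
  }
  years <- as.integer(names(yields))
  if (length(years) < 4) {
    cellfarm_abort("exactly four years are required for a bienniality evaluation")
  }
  if (length(years) > 4) {
    cellfarm_abort("more than four years supplied; evaluate in four-year windows")
  }
  if (is.list(pairing)) {
    stopifnot(length(pairing$high) == 2, length(pairing$low) == 2)
    if (!setequal(c(pairing$high, pairing$low), years)) {
      cellfarm_abort("explicit pairing must use exactly the supplied years")
    }
    return(list(high = as.integer(pairing$high), low = as.integer(pairing$low),
                method = "explicit"))
  }
  even <- years[years %% 2 == 0]
  odd <- years[years %% 2 == 1]
  if (length(even) != 2 || length(odd) != 2) {
    cellfarm_abort("auto pairing needs two even and two odd calendar years; supply an explicit pairing")
  }
  m_even <- mean(yields[as.character(even)])
  m_odd <- mean(yields[as.character(odd)])
  if (isTRUE(all.equal(m_even, m_odd))) {
    cellfarm_abort("parity means are tied; supply an explicit pairing")
  }
  if (m_even > m_odd) {
    list(high = sort(even), low = sort(odd), method = "auto")
  } else {
    list(high = sort(odd), low = sort(even), method = "auto")
  }
}

#' Magnitude of bienniality
#'
#' The bienniality magnitude of a production unit is the mean yield of its
#' two high-bearing seasons minus the mean of its two low-bearing seasons:
#' `MB = (P1 + P2)/2 - (P3 + P4)/2`, in Mg ha-1. Negative values indicate a
#' unit whose biennial phase is inverted relative to the assumed pairing.
#'
#' @param p1,p2 Yields of the two high-bearing seasons, Mg ha-1.
#' @param p3,p4 Yields of the two low-bearing seasons, Mg ha-1.
#' @return MB in Mg ha-1 (vectorized).
#' @export
#' @examples
#' magnitude_bienniality(3.11, 2.08, 0.76, 1.07)  # 1.68
magnitude_bienniality <- function(p1, p2, p3, p4) {
  stopifnot(all(c(p1, p2, p3, p4) >= 0))
  (p1 + p2) / 2 - (p3 + p4) / 2
}

#' Bienniality magnitude per cell or for the whole farm
#'
#' Classifies the four study seasons into high/low pairs (farm-level means
#' drive the `"auto"` classification so all cells share one pairing) and
#' computes the bienniality magnitude per unit. Zero-harvest seasons enter
#' as 0 Mg ha-1, not missing: a skeletonized season is a real low season.
#'
#' @param dataset A `farm_dataset` with a four-year yield panel.
#' @param level `"cell"` (one row per cell) or `"farm"` (single row computed
#'   from yearly farm-mean yields).
#' @param pairing `"auto"` or an explicit `list(high =, low =)` of years.
#' @param weight Farm-level aggregation of cell yields: `"none"` (plain
#'   mean, default -- each composite cell value counts once) or `"area"`.
#' @return A tibble of class `cellfarm_bienniality` with columns `unit_id`,
#'   `P1`, `P2`, `P3`, `P4`, `MB`, `pairing_used`.
#' @export
bienniality <- function(dataset, level = c("cell", "farm"), pairing = "auto",
                        weight = c("none", "area")) {
  stopifnot(inherits(dataset, "farm_dataset"), !is.null(dataset$yield))
  level <- arg_match(level)
  weight <- arg_match(weight)

  farm_series <- farm_mean_yield(dataset, weight = weight)
  pr <- classify_years(setNames(farm_series$yield_mg_ha, farm_series$year),
                       pairing)
  pairing_label <- paste0("high:", paste(pr$high, collapse = "+"),
                          "|low:", paste(pr$low, collapse = "+"))

  unit_mb <- function(unit_id, yields) {
    y <- setNames(yields$yield_mg_ha, yields$year)
    tibble(
      unit_id = unit_id,
      P1 = unname(y[as.character(pr$high[1])]),
      P2 = unname(y[as.character(pr$high[2])]),
      P3 = unname(y[as.character(pr$low[1])]),
      P4 = unname(y[as.character(pr$low[2])]),
      pairing_used = pairing_label
    )
  }

  out <- if (level == "farm") {
    unit_mb(dataset$farm_id, farm_series)
  } else {
    dataset$yield |>
      group_by(.data$cell_id) |>
      group_map(\(df, key) unit_mb(key$cell_id, df)) |>
      list_rbind()
  }
  out <- out |>
    mutate(MB = magnitude_bienniality(.data$P1, .data$P2, .data$P3, .data$P4)) |>
    relocate("unit_id", "P1", "P2", "P3", "P4", "MB", "pairing_used")
  structure(out, class = c("cellfarm_bienniality", class(out)),
            level = level, farm_id = dataset$farm_id)
}

#' @method glance cellfarm_bienniality
#' @export
glance.cellfarm_bienniality <- function(x, ...) {
  tibble(
    farm_id = attr(x, "farm_id"),
    level = attr(x, "level"),
    n_units = nrow(x),
    mean_MB = mean(x$MB),
    min_MB = min(x$MB),
    max_MB = max(x$MB),
    n_inverted_phase = sum(x$MB < 0)
  )
}
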