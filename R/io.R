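#' Read a farm dataset from CSV files
#'
#' Reads the long/tidy CSV schemas of a cell-size study and returns a
#' validated [farm_dataset()]. Only `cells.csv` is mandatory; missing
#' optional panels are recorded as absent with a warning, never an error.
#'
#' Expected schemas (column order free, decimal separator "."):
#' * `cells.csv`: cell_id, farm_id, area_ha, variety, row_spacing_m, plant_spacing_m
#' * `yield.csv`: cell_id, year, yield_mg_ha, zero_harvest
#' * `soil.csv` / `leaf.csv`: cell_id, year, attribute, value, unit
#' * `costs.csv`: year, category, usd_per_ha
#' * `prices.csv`: year, price_usd_per_bag, fx_brl_per_usd
#'
#' Files exported from Brazilian-locale software must be normalized to "."
#' decimals first; a numeric column containing "," decimals is rejected with
#' a message naming the column.
#'
#' @param paths Either a directory containing the CSVs under their canonical
#'   names, or a named list/vector with any of `cells`, `yield`, `soil`,
#'   `leaf`, `costs`, `prices` pointing at files.
#' @param config Optional named list (e.g. parsed from YAML) reserved for
#'   reader options; currently only `farm_id` (filter `cells` to one farm).
#' @return A validated `farm_dataset`.
#' @export
read_farm <- function(paths, config = list()) {
  if (length(paths) == 1 && is.character(paths) && is.null(names(paths)) &&
      dir.exists(paths)) {
    nm <- c("cells", "yield", "soil", "leaf", "costs", "prices")
    paths <- setNames(file.path(paths, paste0(nm, ".csv")), nm)
    paths <- paths[file.exists(paths)]
  }
  paths <- as.list(paths)
  if (is.null(paths$cells)) {
    cellfarm_abort("a 'cells' file is mandatory", class = "cellfarm_schema_error")
  }

  tabs <- map(paths, read_cellfarm_csv)
  if (!is.null(config$farm_id)) {
    tabs$cells <- filter(tabs$cells, .data$farm_id == config$farm_id)
  }
  for (p in c("yield", "soil", "leaf", "costs", "prices")) {
    if (!is.null(tabs[[p]]) && nrow(tabs[[p]]) == 0) {
      warn(paste0("panel '", p, "' is empty; recorded as absent"))
      tabs[[p]] <- NULL
    }
  }
  if (!is.null(tabs$yield)) {
    require_columns(tabs$yield, c("cell_id", "year", "yield_mg_ha"), "yield")
    tabs$yield$zero_harvest <-
      as.logical(tabs$yield$zero_harvest %||% (tabs$yield$yield_mg_ha == 0))
  }
  farm_dataset(cells = tabs$cells, yield = tabs$yield, soil = tabs$soil,
               leaf = tabs$leaf, costs = tabs$costs, prices = tabs$prices)
}

read_cellfarm_csv <- function(path) {
  # a bare "," must not be silently eaten as a grouping mark
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        locale = readr::locale(grouping_mark = " "))
  # guard against Brazilian-locale exports: "1,23" survives as character
  for (col in names(df)) {
    v <- df[[col]]
    if (is.character(v) && any(grepl("^-?[0-9]+,[0-9]+$", v))) {
      cellfarm_abort(paste0(
        "column '", col, "' in ", basename(path),
        " uses ',' as decimal separator; normalize to '.' before reading"),
        class = "cellfarm_schema_error")
    }
  }
  if ("cell_id" %in% names(df)) df$cell_id <- as.character(df$cell_id)
  if ("farm_id" %in% names(df)) df$farm_id <- as.character(df$farm_id)
  if ("year" %in% names(df)) df$year <- as.integer(df$year)
  df
}

#' Attach GeoJSON cell polygons to a farm dataset
#'
#' Joins the features of a GeoJSON FeatureCollection to the cells by their
#' `cell_id` property. Geometries are carried opaquely (WGS84 pass-through,
#' no reprojection); cells without a matching feature stay valid in
#' tabular-only mode, and features without a matching cell are skipped with
#' a warning.
#'
#' @param dataset A `farm_dataset`.
#' @param geojson Path to a GeoJSON file, or an already-parsed
#'   FeatureCollection list (as from `jsonlite::read_json`).
#' @return The dataset with a `geometry` tibble (`cell_id`, `feature`).
#' @export
attach_geometry <- function(dataset, geojson) {
  stopifnot(inherits(dataset, "farm_dataset"))
  if (is.character(geojson)) {
    geojson <- jsonlite::read_json(geojson)
  }
  if (!identical(geojson$type, "FeatureCollection")) {
    cellfarm_abort("geojson must be a FeatureCollection")
  }
  feats <- geojson$features
  ids <- map_chr(feats, \(f) {
    id <- f$properties$cell_id
    if (is.null(id)) {
      cellfarm_abort("feature without a 'cell_id' property")
    }
    as.character(id)
  })
  bad_geom <- map_lgl(feats, \(f) is.null(f$geometry$type))
  if (any(bad_geom)) {
    cellfarm_abort(paste0("invalid geometry in feature '", ids[bad_geom][1], "'"))
  }
  known <- ids %in% dataset$cells$cell_id
  if (any(!known)) {
    warn(paste0("skipping feature(s) with unknown cell_id: ",
                paste(ids[!known], collapse = ", ")))
  }
  unmatched <- setdiff(dataset$cells$cell_id, ids)
  if (length(unmatched)) {
    warn(paste0(length(unmatched), " cell(s) without geometry remain ",
                "tabular-only: ", paste(unmatched, collapse = ", ")))
  }
  dataset$geometry <- tibble(cell_id = ids[known], feature = feats[known])
  validate_farm(dataset)
}

#' Write result tables to CSV (and GeoJSON when geometry is present)
#'
#' Writes one CSV per named table with stable column order and full numeric
#' precision (display rounding to 2 decimals is a reporting convention, not
#' applied to stored values). When `geometry` is supplied, each table that
#' has a `cell_id` column is additionally written as a GeoJSON
#' FeatureCollection with the table's columns injected as feature
#' properties.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param geometry Optional geometry tibble (`cell_id`, `feature`) from
#'   [attach_geometry()], or a `farm_dataset` carrying one.
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(tables, out_dir, geometry = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (inherits(geometry, "farm_dataset")) geometry <- geometry$geometry
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (nm in names(tables)) {
    tab <- as_tibble(tables[[nm]])
    csv <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tab, csv)
    written <- c(written, csv)
    if (!is.null(geometry) && "cell_id" %in% names(tab)) {
      gj <- file.path(out_dir, paste0(nm, ".geojson"))
      write_geojson_table(tab, geometry, gj)
      written <- c(written, gj)
    }
  }
  invisible(written)
}

write_geojson_table <- function(tab, geometry, path) {
  feats <- map(seq_len(nrow(geometry)), \(i) {
    f <- geometry$feature[[i]]
    rows <- tab[tab$cell_id == geometry$cell_id[i], , drop = FALSE]
    props <- as.list(f$properties %||% list())
    if (nrow(rows) == 1) {
      props <- utils::modifyList(props, as.list(rows))
    } else if (nrow(rows) > 1) {
      # map-like export of a cell x year table: one property per year row
      for (j in seq_len(nrow(rows))) {
        r <- as.list(rows[j, setdiff(names(rows), c("cell_id", "year"))])
        suffix <- if ("year" %in% names(rows)) paste0("_", rows$year[j]) else paste0("_", j)
        names(r) <- paste0(names(r), suffix)
        props <- utils::modifyList(props, r)
      }
    }
    f$properties <- props
    f
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
}
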