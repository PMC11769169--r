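#' Descriptive statistics of an attribute panel
#'
#' Minimum, mean, maximum, sample standard deviation (n - 1 denominator) and
#' coefficient of variation per attribute-year group, the screening summary
#' used to judge spatio-temporal heterogeneity among cells. CV is undefined
#' (flagged, not infinite) when the group mean is zero, and sd/cv are
#' undefined for singleton groups.
#'
#' @param panel Long tibble with a `value` column and grouping columns; by
#'   default grouped by any of `attribute` and `year` present. A yield panel
#'   can be passed with `value_col = "yield_mg_ha"`.
#' @param group_by Character vector of grouping columns.
#' @param value_col Name of the value column.
#' @return A tibble: groups, `n`, `min`, `mean`, `max`, `sd`, `cv_percent`,
#'   `cv_defined`.
#' @export
#' @examples
#' describe_panel(tibble::tibble(attribute = "P", year = 2018, value = 1:3))
describe_panel <- function(panel,
                           group_by = intersect(c("attribute", "year"),
                                                names(panel)),
                           value_col = "value") {
  panel <- as_tibble(panel)
  if (!nrow(panel)) cellfarm_abort("empty panel")
  require_columns(panel, value_col, "panel")
  panel |>
    group_by(across(all_of(group_by))) |>
    summarise(
      n = sum(!is.na(.data[[value_col]])),
      min = min(.data[[value_col]], na.rm = TRUE),
      mean = mean(.data[[value_col]], na.rm = TRUE),
      max = max(.data[[value_col]], na.rm = TRUE),
      sd = if (n > 1) sd(.data[[value_col]], na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      cv_defined = .data$n > 1 & .data$mean != 0,
      cv_percent = ifelse(.data$cv_defined, 100 * .data$sd / .data$mean,
                          NA_real_)
    )
}

#' Significance-masked Pearson correlation of a cell-by-attribute panel
#'
#' Product-moment correlation between every pair of attributes across the
#' cells of one farm, with a two-sided p-value from the t transform on
#' n - 2 degrees of freedom and a significance flag at `alpha`. Missing
#' values are handled pairwise-complete; pairs with fewer than three
#' complete observations are marked not computable rather than dropped.
#'
#' @param panel Wide data frame: one row per cell, one numeric column per
#'   attribute (e.g. soil attributes plus yield). Non-numeric columns such
#'   as `cell_id` are ignored.
#' @param alpha Significance level (default 0.05).
#' @return A long tibble of class `cellfarm_correlation`: `attribute_x`,
#'   `attribute_y`, `n`, `r`, `p_value`, `significant`, `computable`,
#'   including the unit diagonal; symmetric in x/y.
#' @export
pearson_matrix <- function(panel, alpha = 0.05) {
  panel <- as_tibble(panel)
  num <- panel |> select(where(is.numeric))
  vars <- names(num)
  if (length(vars) < 2) cellfarm_abort("need at least two numeric attributes")
  grid <- tidyr::expand_grid(attribute_x = vars, attribute_y = vars)
  out <- list_rbind(pmap(grid, \(attribute_x, attribute_y) {
    x <- num[[attribute_x]]
    y <- num[[attribute_y]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (attribute_x == attribute_y) {
      return(tibble(attribute_x, attribute_y, n = n, r = 1, p_value = 0,
                    computable = n >= 3))
    }
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble(attribute_x, attribute_y, n = n, r = NA_real_,
                    p_value = NA_real_, computable = FALSE))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson",
                   alternative = "two.sided")
    tibble(attribute_x, attribute_y, n = n, r = unname(ct$estimate),
           p_value = ct$p.value, computable = TRUE)
  }))
  out <- mutate(out,
                significant = .data$computable & !is.na(.data$p_value) &
                  .data$p_value < alpha)
  structure(out, class = c("cellfarm_correlation", class(out)), alpha = alpha)
}

#' @method glance cellfarm_correlation
#' @export
glance.cellfarm_correlation <- function(x, ...) {
  off <- filter(x, .data$attribute_x < .data$attribute_y)
  tibble(
    alpha = attr(x, "alpha"),
    n_pairs = nrow(off),
    n_computable = sum(off$computable),
    n_significant = sum(off$significant),
    max_abs_r = if (any(!is.na(off$r))) max(abs(off$r), na.rm = TRUE) else NA_real_
  )
}
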