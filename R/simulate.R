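#' Configuration for the synthetic-farm generator
#'
#' Collects every knob of [simulate_farm()] with defaults shaped like the
#' two Minas Gerais study farms: 15 cells of a few hectares each, four
#' consecutive seasons of alternating biennial yields with cell-level
#' heterogeneity, skeletonization ("zero-harvest") events in low seasons,
#' a fifteen-attribute soil panel with farm-1-like 2018 means, and the
#' shipped cost ledger and price series.
#'
#' Yield model per cell c and season t:
#' `yield = max(0, b_c * (1 + s_t * phase_c * a_c) + eps)`, with `s_t`
#' alternating +1/-1 from the first year, base yield `b_c` lognormal around
#' `base_yield_mean` with CV `base_yield_cv`, relative amplitude `a_c`
#' normal around `amplitude_mean` truncated to [0, 0.95], `phase_c = -1`
#' with probability `phase_inversion_prob`, and
#' `eps ~ Normal(0, noise_sd^2)`. In low seasons a cell is skeletonized
#' (yield forced to 0, flag set) with probability `zero_harvest_prob`.
#'
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param n_cells Number of cells.
#' @param mean_area_ha Mean cell area; areas are lognormal with CV
#'   `area_cv` (or pass `areas_ha` for a fixed list).
#' @param area_cv,areas_ha See `mean_area_ha`.
#' @param years Four consecutive calendar years.
#' @param base_yield_mean,base_yield_cv Cell base yield b_c, Mg ha-1.
#' @param amplitude_mean,amplitude_cv Cell biennial amplitude a_c in [0, 1).
#' @param phase_inversion_prob Probability a cell's biennial phase is
#'   inverted relative to the farm.
#' @param noise_sd Additive yield noise, Mg ha-1.
#' @param zero_harvest_prob Per-cell skeletonization probability in each
#'   low season.
#' @param soil_means Named numeric vector of soil-attribute means (default:
#'   the shipped farm-1 2018 profile); `soil_cv` the common lognormal CV.
#' @param soil_cv See `soil_means`.
#' @param costs,prices Ledger/price tibbles (shipped defaults).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cells = 15,
                              mean_area_ha = 5.5,
                              area_cv = 0.4,
                              areas_ha = NULL,
                              years = 2018:2021,
                              base_yield_mean = 1.8,
                              base_yield_cv = 0.35,
                              amplitude_mean = 0.5,
                              amplitude_cv = 0.3,
                              phase_inversion_prob = 0.1,
                              noise_sd = 0.2,
                              zero_harvest_prob = 0.2,
                              soil_means = NULL,
                              soil_cv = 0.3,
                              costs = default_cost_ledger(),
                              prices = default_price_series()) {
  if (is.null(soil_means)) {
    prof <- filter(default_soil_profile(1), .data$year == 2018)
    soil_means <- setNames(prof$value, prof$attribute)
  }
  cfg <- list(seed = as.integer(seed), n_cells = n_cells,
              mean_area_ha = mean_area_ha, area_cv = area_cv,
              areas_ha = areas_ha, years = as.integer(years),
              base_yield_mean = base_yield_mean, base_yield_cv = base_yield_cv,
              amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
              phase_inversion_prob = phase_inversion_prob,
              noise_sd = noise_sd, zero_harvest_prob = zero_harvest_prob,
              soil_means = soil_means, soil_cv = soil_cv,
              costs = costs, prices = prices)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_cells >= 1, length(cfg$years) == 4,
            all(diff(cfg$years) == 1))
  if (cfg$amplitude_mean < 0 || cfg$amplitude_mean >= 1) {
    cellfarm_abort("amplitude_mean must lie in [0, 1)")
  }
  for (p in c("phase_inversion_prob", "zero_harvest_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      cellfarm_abort(paste0(p, " must lie in [0, 1]"))
    }
  }
  for (p in c("base_yield_cv", "amplitude_cv", "area_cv", "soil_cv",
              "noise_sd")) {
    if (cfg[[p]] < 0) cellfarm_abort(paste0(p, " must be >= 0"))
  }
  if (!is.null(cfg$areas_ha) && (length(cfg$areas_ha) != cfg$n_cells ||
                                 any(cfg$areas_ha <= 0))) {
    cellfarm_abort("areas_ha must give one positive area per cell")
  }
  invisible(cfg)
}

# lognormal draw parameterized by arithmetic mean and CV; degenerate at the
# mean when cv = 0
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a farm dataset with known ground truth
#'
#' Draws a complete [farm_dataset()] -- cells, four-season yield panel with
#' biennial alternation and skeletonization events, soil panel, cost ledger
#' and price series -- together with the generating parameters per cell, so
#' pipeline estimates can be checked against truth. See
#' [simulation_config()] for the model.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `farm` (a validated `farm_dataset`) and
#'   `truth` (tibble: `cell_id`, `area_ha`, `base_yield`, `amplitude`,
#'   `phase`, `mb_true` = `2 * amplitude * base_yield * phase`, plus the
#'   zero-harvest event count); attribute `farm_mb_true` is the plain cell
#'   mean of `mb_true`.
#' @export
#' @examples
#' sim <- simulate_farm(simulation_config(seed = 42, noise_sd = 0,
#'                                        zero_harvest_prob = 0))
#' bienniality(sim$farm, level = "farm")
simulate_farm <- function(config = simulation_config()) {
  cfg <- validate_simulation_config(config)
  withr_seed <- cfg$seed
  old <- globalenv()$.Random.seed
  set.seed(withr_seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  ids <- sprintf("cell_%02d", seq_len(cfg$n_cells))
  areas <- cfg$areas_ha %||%
    rlnorm_mean_cv(cfg$n_cells, cfg$mean_area_ha, cfg$area_cv)
  b <- rlnorm_mean_cv(cfg$n_cells, cfg$base_yield_mean, cfg$base_yield_cv)
  a <- pmin(pmax(rnorm(cfg$n_cells, cfg$amplitude_mean,
                       cfg$amplitude_mean * cfg$amplitude_cv), 0), 0.95)
  phase <- ifelse(runif(cfg$n_cells) < cfg$phase_inversion_prob, -1, 1)

  s <- rep(c(1, -1), length.out = 4)  # first study year is a high season
  grid <- tidyr::expand_grid(cell = seq_len(cfg$n_cells), t = 1:4)
  eps <- rnorm(nrow(grid), 0, cfg$noise_sd)
  raw <- pmax(0, b[grid$cell] * (1 + s[grid$t] * phase[grid$cell] * a[grid$cell]) + eps)
  low_season <- s[grid$t] * phase[grid$cell] < 0
  zh <- low_season & runif(nrow(grid)) < cfg$zero_harvest_prob
  yield <- tibble(
    cell_id = ids[grid$cell],
    year = cfg$years[grid$t],
    yield_mg_ha = ifelse(zh, 0, raw),
    zero_harvest = zh
  )

  soil <- tidyr::expand_grid(cell_id = ids, year = cfg$years,
                             attribute = names(cfg$soil_means)) |>
    mutate(
      value = rlnorm_mean_cv(n(), 1, cfg$soil_cv) *
        unname(cfg$soil_means[.data$attribute]),
      unit = "as_configured"
    )

  cells <- tibble(cell_id = ids, farm_id = "synthetic_farm",
                  area_ha = areas, variety = "synthetic")
  farm <- farm_dataset(cells, yield = yield, soil = soil,
                       costs = cfg$costs, prices = cfg$prices)

  truth <- tibble(
    cell_id = ids, area_ha = areas, base_yield = b, amplitude = a,
    phase = phase, mb_true = 2 * a * b * phase,
    n_zero_harvest = as.vector(tapply(zh, grid$cell, sum))
  )
  structure(list(farm = farm, truth = truth),
            class = "cellfarm_simulation",
            farm_mb_true = mean(truth$mb_true))
}

#' Parameter-recovery report over seeded replicates
#'
#' Replicates the generator `n_reps` times (seeds `seed + 1 ... seed +
#' n_reps`), runs the bienniality estimator on each replicate and compares
#' the farm-level estimate with the generator truth
#' `mean(2 * amplitude * base_yield * phase)`; also verifies on each
#' replicate that localized-management farm totals equal the per-cell
#' dose-times-area sum (conservation) and that profit = revenue - cost
#' holds on every record.
#'
#' @param config A [simulation_config()]; its `seed` anchors the replicate
#'   seeds.
#' @param n_reps Number of replicates (>= 2).
#' @param target_year Recommendation year used for the conservation check.
#' @return A one-row tibble: `n_reps`, `mean_mb_error`, `mc_se`,
#'   `ci_lower`/`ci_upper` (95% Monte-Carlo interval for the mean error),
#'   `unbiased` (0 inside the interval), `max_conservation_error_kg`,
#'   `max_profit_identity_error`.
#' @export
recovery_report <- function(config = simulation_config(), n_reps = 200,
                            target_year = NULL) {
  stopifnot(n_reps >= 2)
  per_rep <- map(seq_len(n_reps), \(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_farm(cfg)
    ty <- target_year %||% (cfg$years[2])
    mb_hat <- bienniality(sim$farm, level = "farm")$MB
    doses <- recommend(sim$farm, target_year = ty, strategy = "LM_cell")
    cons <- doses |>
      left_join(select(sim$farm$cells, "cell_id", cell_area = "area_ha"),
                by = c(unit_id = "cell_id")) |>
      summarise(err = max(abs(.data$dose_kg_total -
                                .data$dose_kg_ha * .data$cell_area))) |>
      pull("err")
    prof <- profitability(sim$farm, level = "cell")
    tibble(
      mb_error = mb_hat - attr(sim, "farm_mb_true"),
      conservation_error = cons,
      profit_identity_error = max(abs(prof$profit_usd_ha -
                                        (prof$revenue_usd_ha - prof$cost_usd_ha)))
    )
  }) |> list_rbind()

  mean_err <- mean(per_rep$mb_error)
  se <- sd(per_rep$mb_error) / sqrt(n_reps)
  tibble(
    n_reps = n_reps,
    mean_mb_error = mean_err,
    mc_se = se,
    ci_lower = mean_err - qnorm(0.975) * se,
    ci_upper = mean_err + qnorm(0.975) * se,
    unbiased = (mean_err - qnorm(0.975) * se) <= 0 &
      0 <= (mean_err + qnorm(0.975) * se),
    max_conservation_error_kg = max(per_rep$conservation_error),
    max_profit_identity_error = max(per_rep$profit_identity_error)
  )
}
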