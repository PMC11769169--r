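calib <- function(vol = 2, mass = 0.5, n = 10) {
  data.frame(sample_volume_l = rep(vol, n), dry_mass_kg = rep(mass, n))
}

test_that("volume-to-yield conversion follows the calibration factor", {
  # 10 x (2 L, 0.5 kg) -> 0.25 kg/L; 40000 L * 0.25 * 0.5 / (1000 * 10 ha)
  expect_equal(volume_to_yield(40000, calib(), area_ha = 10,
                               processing_factor = 0.5), 0.50)
  expect_equal(volume_to_yield(0, calib(), area_ha = 10), 0)
  # homogeneity in volume
  y1 <- volume_to_yield(12345, calib(), area_ha = 7)
  y2 <- volume_to_yield(2 * 12345, calib(), area_ha = 7)
  expect_equal(y2, 2 * y1)
  expect_error(volume_to_yield(100, calib(), area_ha = 0), "positive")
  expect_error(volume_to_yield(100, calib()[0, ], area_ha = 1), "calibration")
})

test_that("auto pairing picks the higher-mean parity and ties demand explicit pairing", {
  f1 <- c(`2018` = 3.11, `2019` = 0.76, `2020` = 2.08, `2021` = 1.07)
  pr <- classify_years(f1, "auto")
  expect_equal(pr$high, c(2018L, 2020L))
  expect_equal(pr$low, c(2019L, 2021L))

  inv <- c(`2018` = 1, `2019` = 3, `2020` = 1, `2021` = 3)
  expect_equal(classify_years(inv)$high, c(2019L, 2021L))

  expect_error(classify_years(c(`2018` = 2, `2019` = 2, `2020` = 2,
                                `2021` = 2)), "tied")
  expect_error(classify_years(f1[1:3]), "four years")

  exp_pair <- list(high = c(2019, 2021), low = c(2018, 2020))
  got <- classify_years(f1, exp_pair)
  expect_equal(got$high, c(2019L, 2021L))
  expect_equal(got$method, "explicit")
})

test_that("bienniality magnitude matches the published farm-level values", {
  expect_equal(magnitude_bienniality(5, 5, 5, 5), 0)
  expect_equal(magnitude_bienniality(3.11, 2.08, 0.76, 1.07), 1.68)
  expect_equal(magnitude_bienniality(2.36, 2.05, 0.29, 0.00), 2.06)
})

test_that("MB obeys antisymmetry, translation and scale laws", {
  set.seed(101)
  for (i in 1:50) {
    p <- runif(4, 0, 8)
    c0 <- runif(1, 0, 5)
    k <- runif(1, 0.1, 4)
    mb <- magnitude_bienniality(p[1], p[2], p[3], p[4])
    expect_equal(magnitude_bienniality(p[3], p[4], p[1], p[2]), -mb)
    expect_equal(magnitude_bienniality(p[1] + c0, p[2] + c0,
                                       p[3] + c0, p[4] + c0), mb)
    expect_equal(magnitude_bienniality(k * p[1], k * p[2],
                                       k * p[3], k * p[4]), k * mb)
  }
})

test_that("farm- and cell-level tables share one pairing and respect zero-harvest zeros", {
  f2 <- printed_farm(2)
  farm_tab <- bienniality(f2, level = "farm")
  expect_equal(farm_tab$MB, 2.06)
  expect_equal(farm_tab$P4, 0)  # skeletonized 2021 enters as 0, not NA
  expect_match(farm_tab$pairing_used, "high:2018\\+2020")

  flat <- simulate_farm(simulation_config(seed = 5, amplitude_mean = 0,
                                          amplitude_cv = 0, noise_sd = 0,
                                          zero_harvest_prob = 0,
                                          phase_inversion_prob = 0))
  # amplitude 0 means no parity signal: pairing must be given explicitly
  tab <- bienniality(flat$farm, level = "cell",
                     pairing = list(high = c(2018, 2020), low = c(2019, 2021)))
  expect_true(all(tab$MB == 0))

  toy <- toy_farm()
  fwd <- bienniality(toy, level = "cell")
  rev <- bienniality(toy, level = "cell",
                     pairing = list(high = c(2019, 2021),
                                    low = c(2018, 2020)))
  expect_equal(rev$MB, -fwd$MB)
  expect_equal(glance(fwd)$n_units, 3)
})
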