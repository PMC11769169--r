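test_that("descriptive rows use sample sd and flag undefined CV", {
  p <- tibble::tibble(attribute = "P", year = 2018, value = 1:3)
  d <- describe_panel(p)
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$cv_percent, 50)
  expect_true(d$min <= d$mean && d$mean <= d$max)

  const <- describe_panel(tibble::tibble(attribute = "K", value = c(5, 5, 5)))
  expect_equal(const$sd, 0)
  expect_equal(const$cv_percent, 0)

  single <- describe_panel(tibble::tibble(attribute = "B", value = 3))
  expect_false(single$cv_defined)
  expect_true(is.na(single$sd))

  zero_mean <- describe_panel(tibble::tibble(attribute = "Z",
                                             value = c(-1, 0, 1)))
  expect_false(zero_mean$cv_defined)
  expect_true(is.na(zero_mean$cv_percent))

  expect_error(describe_panel(p[0, ]), "empty")
})

test_that("pearson entries match the product-moment oracle with t-based p-values", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  pm <- pearson_matrix(tibble::tibble(x = x, y = y))
  entry <- dplyr::filter(pm, attribute_x == "x", attribute_y == "y")

  # brute-force product-moment arithmetic
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(entry$r, 0.6)
  expect_equal(entry$r, r_oracle)
  t_stat <- r_oracle * sqrt(2) / sqrt(1 - r_oracle^2)
  expect_equal(entry$p_value, 2 * stats::pt(-abs(t_stat), df = 2))

  perfect <- pearson_matrix(tibble::tibble(a = 1:5, b = 1:5, c = -(1:5)))
  expect_equal(dplyr::filter(perfect, attribute_x == "a",
                             attribute_y == "b")$r, 1)
  expect_equal(dplyr::filter(perfect, attribute_x == "a",
                             attribute_y == "c")$r, -1)
})

test_that("correlation matrix is symmetric, unit-diagonal, bounded and affine-invariant", {
  set.seed(77)
  panel <- tibble::as_tibble(as.data.frame(matrix(rnorm(60), ncol = 4,
                                                  dimnames = list(NULL, c("w", "x", "y", "z")))))
  pm <- pearson_matrix(panel)
  wide <- tidyr::pivot_wider(dplyr::select(pm, 1:2, r),
                             names_from = attribute_y, values_from = r)
  m <- unname(as.matrix(wide[, -1]))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_true(all(abs(m) <= 1 + 1e-12))

  scaled <- dplyr::mutate(panel, x = 3 * x + 7, y = -2 * y + 1)
  pm2 <- pearson_matrix(scaled)
  r12 <- function(p, a, b) dplyr::filter(p, attribute_x == a,
                                         attribute_y == b)$r
  expect_equal(r12(pm2, "w", "x"), r12(pm, "w", "x"))          # positive scale
  expect_equal(r12(pm2, "w", "y"), -r12(pm, "w", "y"))         # sign flip
})

test_that("short or missing-riddled pairs are marked not computable", {
  panel <- tibble::tibble(x = c(1, 2, NA, NA, NA), y = c(2, 1, NA, NA, NA),
                          z = c(1, 2, 3, 4, 5))
  pm <- pearson_matrix(panel)
  short <- dplyr::filter(pm, attribute_x == "x", attribute_y == "y")
  expect_false(short$computable)
  expect_true(is.na(short$r))
  ok <- dplyr::filter(pm, attribute_x == "x", attribute_y == "z")
  expect_equal(ok$n, 2)  # pairwise-complete count
  g <- glance(pm)
  expect_equal(g$n_pairs, 3)
  expect_true(g$n_significant <= g$n_computable)
})
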