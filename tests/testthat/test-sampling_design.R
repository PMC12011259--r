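test_that("stratum_table validates weights and SDs", {
  st <- stratum_table(c("a", "b"), c(0.6, 0.4), c(20, 30))
  expect_s3_class(st, "stratum_table")
  expect_error(stratum_table(c("a", "b"), c(0.6, 0.5), c(1, 1)), "sum to 1")
  expect_error(stratum_table(c("a", "a"), c(0.5, 0.5), c(1, 1)), "unique")
  expect_error(stratum_table("a", 1, -2), "non-negative")
})

test_that("required_plot_count matches the direct arithmetic oracle", {
  st <- stratum_table(c("a", "b"), c(0.6, 0.4), c(20, 30))
  cfg <- sampling_config(total_area = 100, plot_area = 0.08, error_bound = 5)
  n <- required_plot_count(st, cfg)
  raw_expected <- oracle_plot_count(100, 0.08, 1.645, 5,
                                    c(0.6, 0.4), c(20, 30))
  expect_equal(attr(n, "raw"), raw_expected, tolerance = 1e-12)
  expect_identical(as.integer(n), as.integer(ceiling(raw_expected)))
})

test_that("zero-variance strata trigger the minimum with a warning", {
  st <- stratum_table(c("a", "b"), c(0.5, 0.5), c(0, 0))
  cfg <- sampling_config(100, 0.08, error_bound = 5)
  expect_warning(n <- required_plot_count(st, cfg), "zero")
  expect_identical(as.integer(n), 1L)
  expect_equal(attr(n, "raw"), 0)
})

test_that("adjust_plot_count implements the finite-population correction", {
  expect_identical(as.integer(adjust_plot_count(100, 400)), 80L)
  # n = N halves the count
  expect_equal(attr(adjust_plot_count(50, 50), "raw"), 25)
  # no correction in the infinite-population limit
  expect_equal(attr(adjust_plot_count(100, 1e12), "raw"), 100,
               tolerance = 1e-9)
  # never exceeds the raw count
  for (n in c(3, 31, 250)) for (N in c(40, 1000))
    expect_lte(attr(adjust_plot_count(n, N), "raw"), n)
})

test_that("simplified_plot_count: worked value, scaling law, N->inf limit", {
  st1 <- stratum_table("all", 1, 20)
  n <- simplified_plot_count(st1, t_val = 1.645, error_bound = 5)
  expect_equal(attr(n, "raw"), (1.645 / 5)^2 * 400, tolerance = 1e-12)
  expect_identical(as.integer(n), 44L)
  # doubling E quarters the raw count
  n2 <- simplified_plot_count(st1, t_val = 1.645, error_bound = 10)
  expect_equal(attr(n2, "raw"), attr(n, "raw") / 4, tolerance = 1e-12)
  expect_error(simplified_plot_count(st1, 1.645, 0), "error_bound")
})

test_that("finite and simplified formulas agree as plot_area -> 0", {
  st <- stratum_table(c("a", "b"), c(0.7, 0.3), c(12, 35))
  cfg <- sampling_config(total_area = 1e8, plot_area = 0.01, error_bound = 4)
  n_full <- required_plot_count(st, cfg)
  n_simple <- simplified_plot_count(st, 1.645, 4)
  expect_lte(abs(as.integer(n_full) - as.integer(n_simple)), 1L)
})

test_that("required_plot_count is monotone in E, t and S_i", {
  st <- stratum_table(c("a", "b"), c(0.6, 0.4), c(20, 30))
  raw <- function(E, t = 1.645, s2 = 30) {
    sti <- stratum_table(c("a", "b"), c(0.6, 0.4), c(20, s2))
    cfg <- sampling_config(100, 0.08, reliability_index = t, error_bound = E)
    attr(required_plot_count(sti, cfg), "raw")
  }
  Es <- c(2, 3, 5, 8, 12)
  expect_true(all(diff(vapply(Es, raw, numeric(1))) <= 0))
  ts <- c(1.0, 1.3, 1.645, 2.0)
  expect_true(all(diff(vapply(ts, function(t) raw(5, t = t),
                              numeric(1))) >= 0))
  ss <- c(10, 20, 40, 80)
  expect_true(all(diff(vapply(ss, function(s) raw(5, s2 = s),
                              numeric(1))) >= 0))
})

test_that("allocate_plots: symmetry, worked cases, zero-SD strata", {
  st_sym <- stratum_table(c("a", "b"), c(0.5, 0.5), c(7, 7))
  expect_identical(allocate_plots(10, st_sym), c(a = 5L, b = 5L))
  # W*S products 12 and 12 split evenly
  st_eq <- stratum_table(c("a", "b"), c(0.6, 0.4), c(20, 30))
  expect_identical(allocate_plots(10, st_eq), c(a = 5L, b = 5L))
  # 5:15 ratio with largest-remainder rounding
  st <- stratum_table(c("a", "b"), c(0.5, 0.5), c(10, 30))
  expect_identical(allocate_plots(8, st), c(a = 2L, b = 6L))
  # zero-SD stratum receives nothing
  st0 <- stratum_table(c("a", "b"), c(0.5, 0.5), c(0, 10))
  expect_identical(allocate_plots(5, st0), c(a = 0L, b = 5L))
  expect_error(allocate_plots(5, stratum_table(c("a"), 1, 0)), "zero")
  expect_warning(allocate_plots(1, st), "below the number of strata")
})

test_that("allocation conserves the total over random configurations", {
  withr::with_seed(42, {
    for (rep in 1:200) {
      st <- random_strata(sample(2:8, 1))
      n <- sample(1:500, 1)
      alloc <- suppressWarnings(allocate_plots(n, st))
      expect_identical(sum(alloc), as.integer(n))
      # proportionality before rounding: counts within 1 of the quota
      quota <- n * st$area_weight * st$stock_sd /
        sum(st$area_weight * st$stock_sd)
      expect_true(all(abs(alloc - quota) < 1))
    }
  })
})

test_that("design_sampling wires count, adjustment and allocation together", {
  st <- stratum_table(c("a", "b"), c(0.6, 0.4), c(20, 30))
  cfg <- sampling_config(100, 0.08, error_bound = 5)
  des <- design_sampling(st, cfg)
  expect_identical(des$n, 62L)
  expect_true(des$fpc_applied)  # 62 plots of 0.08 hm2 < 5% of 100 hm2
  expect_identical(des$n_adjusted,
                   as.integer(adjust_plot_count(62, 100 / 0.08)))
  expect_identical(sum(des$allocation), des$n_adjusted)
  des_never <- design_sampling(st, cfg, fpc = "never")
  expect_identical(des_never$n_adjusted, des_never$n)
})

test_that("error_bound_from_relative is the weighted-mean precision", {
  st <- stratum_table(c("a", "b"), c(0.6, 0.4), c(20, 30))
  expect_equal(error_bound_from_relative(st, c(50, 100)),
               0.1 * (0.6 * 50 + 0.4 * 100))
})
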