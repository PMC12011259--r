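make_ledger <- function(b_by_year, cf = 0.5, area = 1,
                        pool = "tree_AA", stratum = "S1") {
  carbon_ledger(data.frame(stratum = stratum, species = "fir", age_class = 1,
                           year = as.integer(names(b_by_year)),
                           pool = pool, biomass = unname(b_by_year),
                           cf = cf, area = area, stringsAsFactors = FALSE))
}

test_that("pool_carbon_stock is the validated triple product", {
  expect_equal(pool_carbon_stock(0, 0.5, 10), 0)
  expect_equal(pool_carbon_stock(100, 0.5, 2), 100)
  # linear in each argument
  expect_equal(pool_carbon_stock(50, 0.5, 2), pool_carbon_stock(100, 0.5, 2) / 2)
  expect_equal(pool_carbon_stock(100, 0.5, 4), pool_carbon_stock(100, 0.5, 2) * 2)
  expect_error(pool_carbon_stock(10, 1.2, 1), "carbon fraction")
  expect_error(pool_carbon_stock(10, 0, 1), "carbon fraction")
  expect_error(pool_carbon_stock(-1, 0.5, 1), "non-negative")
})

test_that("the 44/12 operator converts and preserves sign", {
  expect_equal(stock_change_co2e(12, 0), 44)
  expect_equal(stock_change_co2e(0, 12), -44)
  expect_equal(stock_change_co2e(7, 7), 0)
  # antisymmetry
  withr::with_seed(3, for (i in 1:10) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 100)
    expect_equal(stock_change_co2e(a, b), -stock_change_co2e(b, a))
  })
})

test_that("shrub_pool_change equals differenced stock conversion", {
  expect_equal(shrub_pool_change(0, 0.5, 3), 0)
  expect_equal(shrub_pool_change(12, 0.5, 1), 22)
  withr::with_seed(4, for (i in 1:10) {
    b1 <- runif(1, 0, 50); b0 <- runif(1, 0, 50)
    cf <- runif(1, 0.3, 0.6); a <- runif(1, 0.5, 10)
    expect_equal(shrub_pool_change(b1 - b0, cf, a),
                 stock_change_co2e(pool_carbon_stock(b1, cf, a),
                                   pool_carbon_stock(b0, cf, a)),
                 tolerance = 1e-12)
  })
})

test_that("carbon_ledger validates pools and rejects duplicate keys", {
  led <- make_ledger(c("2019" = 10, "2020" = 12))
  expect_equal(led$carbon_stock, c(5, 6))
  dup <- rbind(as.data.frame(led)[, 1:8], as.data.frame(led)[1, 1:8])
  expect_error(carbon_ledger(dup), "duplicated")
  bad <- as.data.frame(led)[, 1:8]; bad$pool <- "soil"
  expect_error(carbon_ledger(bad), "unknown pool")
})

test_that("project_stock_change sums pools and handles missing keys", {
  expect_equal(project_stock_change(make_ledger(c("2019" = 10)), 2025), 0)
  # single entry, B 10 -> 12 t/hm2, CF 0.5, A 1: (44/12) * (6 - 5)
  led <- make_ledger(c("2019" = 10, "2020" = 12))
  expect_equal(project_stock_change(led, 2020), 44 / 12)
  # AA + BB across two strata add up
  df <- expand.grid(stratum = c("S1", "S2"), pool = c("tree_AA", "tree_BB"),
                    year = 2019:2020, stringsAsFactors = FALSE)
  df$species <- "fir"; df$age_class <- 1; df$cf <- 0.5; df$area <- 2
  df$biomass <- ifelse(df$year == 2019, 10, 13)
  led2 <- carbon_ledger(df)
  expect_equal(project_stock_change(led2, 2020), 4 * (44 / 12) * 3 * 0.5 * 2)
  # permutation invariance of ledger row order
  perm <- carbon_ledger(df[sample(nrow(df)), ])
  expect_equal(project_stock_change(perm, 2020),
               project_stock_change(led2, 2020))
  # key present in one year only counts as zero stock, with a warning
  half <- carbon_ledger(df[!(df$stratum == "S2" & df$year == 2019), ])
  expect_warning(chg <- project_stock_change(half, 2020), "only one")
  expect_equal(chg, 2 * (44 / 12) * 3 * 0.5 * 2 + 2 * (44 / 12) * 13 * 0.5 * 2)
})

test_that("ghg, baseline and net sink follow the accounting identity", {
  expect_equal(ghg_emissions(0, 0), 0)
  expect_equal(ghg_emissions(3, 2), 5)
  expect_error(ghg_emissions(-1, 0), "non-negative")
  expect_equal(baseline_change(NULL, 2020), 0)
  bsl <- data.frame(stratum = "b1", year = 2020, delta_aa = 2, delta_bb = 1)
  expect_equal(baseline_change(bsl, 2020), 3)
  expect_equal(baseline_change(baseline_cleared(2019:2025), 2022), 0)

  led <- make_ledger(c("2019" = 10, "2020" = 22))  # delta C = 6 t C -> 22 t CO2e
  acct <- project_account(led,
                          ghg = data.frame(year = 2020, fuel = 3,
                                           fertilizer = 2),
                          leakage = 1,
                          baseline = data.frame(stratum = "b", year = 2020,
                                                delta_aa = 4, delta_bb = 2))
  expect_equal(net_carbon_sink(acct, 2020), 22 - 5 - 1 - 6)
  # project no better than baseline nets to zero
  acct0 <- project_account(led, baseline = data.frame(
    stratum = "b", year = 2020, delta_aa = 22, delta_bb = 0))
  expect_equal(net_carbon_sink(acct0, 2020), 0)
  expect_error(net_carbon_sink(acct, 2030), "no entries")
})

test_that("yearly sinks telescope to the endpoint stock change", {
  withr::with_seed(77, {
    years <- 2015:2022
    b <- cumsum(c(20, runif(length(years) - 1, -2, 6)))  # non-monotone path
    led <- make_ledger(stats::setNames(b, years))
    ghg <- data.frame(year = years[-1], fuel = runif(7, 0, 1),
                      fertilizer = runif(7, 0, 1))
    acct <- project_account(led, ghg = ghg, leakage = 0.2)
    ser <- net_carbon_sink_series(acct)
    endpoint <- stock_change_co2e(pool_carbon_stock(b[8], 0.5, 1),
                                  pool_carbon_stock(b[1], 0.5, 1))
    expect_equal(sum(ser$C_P),
                 endpoint - sum(ghg$fuel + ghg$fertilizer) - 0.2 * 7,
                 tolerance = 1e-9)
    # sign convention: growth years are sinks, shrink years sources
    expect_equal(ser$delta_C_P > 0, diff(b) > 0)
  })
})

test_that("ledger CSV round-trips through read_carbon_ledger", {
  led <- make_ledger(c("2019" = 10, "2020" = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(led)[, 1:8], path, row.names = FALSE)
  back <- read_carbon_ledger(path)
  expect_equal(back$carbon_stock, led$carbon_stock)
  expect_equal(project_stock_change(back, 2020), 44 / 12)
})
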