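# Synthetic stands, inventories and project ledgers.
#
# A growth scenario fixes monotone age->DBH and age->height curves, a
# power-law biomass allometry with lognormal multiplicative noise, and an
# annual mortality rate. All generators are seeded and restore the caller's
# RNG stream, so every run is reproducible. The ledger simulator also
# returns its analytically known net sink so the accounting pipeline can be
# round-trip tested against a closed form.

#' Define a growth scenario
#'
#' Curves are monotone piecewise-linear interpolations through the supplied
#' (age, DBH) and (age, height) anchors and must be strictly increasing.
#' Tree-level variation is lognormal and multiplicative (positivity
#' preserved): `D = curve(age) * exp(N(0, dbh_sd^2))`, and biomass
#' `M = a D^b exp(N(0, noise_sd^2))`.
#'
#' @param species Canonical species name.
#' @param ages Anchor ages, years, strictly increasing.
#' @param dbh Anchor mean DBH values, cm, strictly increasing.
#' @param height Anchor mean heights, m, strictly increasing.
#' @param a,b Biomass allometry `M = a D^b` (kg from cm); defaults 0.1 and
#'   2.4.
#' @param noise_sd Lognormal sigma of the biomass residual, default 0.1.
#' @param dbh_sd,height_sd Lognormal sigmas of tree-level DBH/height
#'   variation, default 0.1.
#' @param mortality_rate Annual mortality probability, default 0.005.
#' @param region Region code 0-5, default 0.
#' @param seed Integer seed (mandatory; all draws are reproducible).
#' @return List of class `"growth_scenario"` with callable `dbh_curve` and
#'   `height_curve`.
#' @export
growth_scenario <- function(species = "Cunninghamia lanceolata",
                            ages, dbh, height,
                            a = 0.1, b = 2.4,
                            noise_sd = 0.1, dbh_sd = 0.1, height_sd = 0.1,
                            mortality_rate = 0.005, region = 0L, seed) {
  if (missing(seed)) stopf("`seed` is required")
  if (length(ages) < 2L || length(dbh) != length(ages) ||
      length(height) != length(ages))
    stopf("ages, dbh and height must be equal-length anchor vectors (>= 2)")
  if (any(diff(ages) <= 0)) stopf("anchor ages must be strictly increasing")
  if (any(diff(dbh) <= 0) || any(diff(height) <= 0))
    stopf("growth curves must be strictly increasing over the age range")
  assert_positive(dbh, "dbh"); assert_positive(height, "height")
  assert_number(a, "a", lower = 0, allow_zero_lower = FALSE)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(dbh_sd, "dbh_sd", lower = 0)
  assert_number(height_sd, "height_sd", lower = 0)
  assert_number(mortality_rate, "mortality_rate", lower = 0, upper = 1)
  if (!region %in% 0:5) stopf("region must be an integer code 0-5")
  structure(list(species = species,
                 age_range = range(ages),
                 dbh_curve = stats::approxfun(ages, dbh),
                 height_curve = stats::approxfun(ages, height),
                 a = a, b = b, noise_sd = noise_sd,
                 dbh_sd = dbh_sd, height_sd = height_sd,
                 mortality_rate = mortality_rate,
                 region = as.integer(region), seed = as.integer(seed)),
            class = "growth_scenario")
}

#' Chinese-fir growth scenario anchored to the packaged reference table
#'
#' Anchors the DBH and height curves to the packaged per-age mean DBH /
#' mean height table for Cunninghamia lanceolata (ages 5-22).
#'
#' @param seed Integer seed.
#' @param ... Further arguments passed to [growth_scenario()].
#' @return A `"growth_scenario"`.
#' @export
chinese_fir_scenario <- function(seed, ...) {
  tab <- utils::read.csv(fc_extdata("table2_carbon_predictions.csv"))
  h <- tab$mean_height
  # the reference heights tie once (12.87 m at ages 18 and 19); repair the
  # tied anchor to the midpoint of its neighbours so the curve is strictly
  # increasing, leaving every other anchor exact
  for (i in seq_along(h)[-c(1, length(h))])
    if (h[i] <= h[i - 1]) h[i] <- (h[i - 1] + h[i + 1]) / 2
  growth_scenario(species = "Cunninghamia lanceolata",
                  ages = tab$age, dbh = tab$mean_dbh,
                  height = h, seed = seed, ...)
}

check_age <- function(scenario, age) {
  if (any(age < scenario$age_range[1]) || any(age > scenario$age_range[2]))
    stopf("age %s outside the scenario range [%g, %g]",
          paste(unique(age[age < scenario$age_range[1] |
                             age > scenario$age_range[2]]), collapse = ", "),
          scenario$age_range[1], scenario$age_range[2])
  invisible(age)
}

#' Analytic moments of the simulated DBH distribution
#'
#' Mean and SD of `curve(age) * exp(N(0, dbh_sd^2))`; the independent yard
#' stick for Monte-Carlo checks of [simulate_stand()].
#'
#' @param scenario A [growth_scenario()].
#' @param age Stand age, years.
#' @return List with `mean` and `sd` in cm.
#' @export
dbh_moments <- function(scenario, age) {
  stopifnot(inherits(scenario, "growth_scenario"))
  check_age(scenario, age)
  mu <- scenario$dbh_curve(age)
  s2 <- scenario$dbh_sd^2
  list(mean = mu * exp(s2 / 2),
       sd = mu * sqrt(exp(s2) * (exp(s2) - 1)))
}

#' Simulate a monitoring-plot inventory
#'
#' Draws `n_trees` stems at the given stand age: DBH and height lognormal
#' around the scenario curves, biomass `a D^b exp(eps)`, survival Bernoulli
#' with per-year mortality compounded over the stand age. Deterministic for
#' a given seed.
#'
#' @param scenario A [growth_scenario()].
#' @param n_trees Number of stems (> 0).
#' @param age Stand age in years, inside the scenario's age range.
#' @param plot_id,stratum_id,year Plot metadata.
#' @param area Plot area, hm2, default 0.08.
#' @param seed Seed override; defaults to the scenario seed.
#' @return A [plot_inventory()].
#' @export
#' @examples
#' sc <- growth_scenario(ages = c(5, 20), dbh = c(8, 16), height = c(5, 13),
#'                       seed = 1)
#' simulate_stand(sc, n_trees = 10, age = 10)
simulate_stand <- function(scenario, n_trees, age, plot_id = "P1",
                           stratum_id = "S1", year = 2020L, area = 0.08,
                           seed = scenario$seed) {
  stopifnot(inherits(scenario, "growth_scenario"))
  if (!is.numeric(n_trees) || n_trees < 1L) stopf("n_trees must be positive")
  check_age(scenario, age)
  n <- as.integer(n_trees)
  trees <- with_seed(seed, {
    dbh <- scenario$dbh_curve(age) * exp(stats::rnorm(n, 0, scenario$dbh_sd))
    height <- scenario$height_curve(age) *
      exp(stats::rnorm(n, 0, scenario$height_sd))
    biomass <- scenario$a * dbh^scenario$b *
      exp(stats::rnorm(n, 0, scenario$noise_sd))
    alive <- stats::runif(n) < (1 - scenario$mortality_rate)^age
    data.frame(tree_id = sprintf("%s-%04d", plot_id, seq_len(n)),
               species = scenario$species,
               dbh = dbh, height = height, age = age,
               region = scenario$region,
               biomass = biomass, alive = alive,
               stringsAsFactors = FALSE)
  })
  plot_inventory(plot_id, area, stratum_id, year, trees)
}

#' Simulate a multi-year project ledger with known truth
#'
#' Builds tree AA/BB pool ledger entries per stratum and year from the
#' scenario's growth trajectory (per-hectare biomass = planting density x
#' `a D(age)^b`, belowground via the root-shoot ratio, a fixed lognormal
#' productivity factor per stratum), and computes the analytically known net
#' sink per year directly from the generated biomass series — a closed-form
#' oracle for [net_carbon_sink_series()].
#'
#' @param scenario A [growth_scenario()].
#' @param strata A [stratum_table()].
#' @param years Consecutive accounting years (length >= 2).
#' @param initial_age Stand age in the first year; default the scenario's
#'   youngest anchor.
#' @param age_step Years of growth per accounting year; `0` freezes the
#'   stand (zero-growth scenario, true sink 0). Default 1.
#' @param total_area Project area, hm2 (split across strata by area
#'   weight), default 100.
#' @param stems_per_ha Planting density, stems/hm2, default 1600.
#' @param cf Carbon fraction, default 0.5.
#' @param root_shoot Root-shoot ratio for the BB pool, default 0.25.
#' @param seed Seed override; defaults to the scenario seed.
#' @return List with `ledger` (a [carbon_ledger()]), `account`
#'   (a [project_account()] with zero GHG/leakage and cleared baseline),
#'   and `truth` (data.frame `year`, `C_P` in t CO2e).
#' @export
simulate_project_ledger <- function(scenario, strata, years,
                                    initial_age = scenario$age_range[1],
                                    age_step = 1, total_area = 100,
                                    stems_per_ha = 1600, cf = 0.5,
                                    root_shoot = 0.25,
                                    seed = scenario$seed) {
  stopifnot(inherits(scenario, "growth_scenario"))
  strata <- as_stratum_table(strata)
  if (length(years) < 2L) stopf("at least two accounting years are required")
  assert_number(age_step, "age_step", lower = 0)
  ages <- initial_age + age_step * (seq_along(years) - 1)
  check_age(scenario, ages)
  # fixed per-stratum productivity factor (site quality heterogeneity)
  f <- with_seed(seed,
                 exp(stats::rnorm(nrow(strata), 0, scenario$noise_sd)))
  area_i <- strata$area_weight * total_area
  rows <- list(); k <- 1L
  b_aa <- matrix(0, nrow(strata), length(years))  # t d.m./hm2
  for (i in seq_len(nrow(strata))) {
    for (ti in seq_along(years)) {
      d <- scenario$dbh_curve(ages[ti])
      b_aa[i, ti] <- stems_per_ha * scenario$a * d^scenario$b * f[i] / 1000
      rows[[k]] <- data.frame(
        stratum = strata$stratum_id[i], species = scenario$species,
        age_class = ages[ti], year = years[ti],
        pool = c("tree_AA", "tree_BB"),
        biomass = c(b_aa[i, ti], b_aa[i, ti] * root_shoot),
        cf = cf, area = area_i[i], stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  entries <- do.call(rbind, rows)
  # age_class is part of the ledger key and must match across years for the
  # same growing stand, so label the cohort by its initial age
  entries$age_class <- initial_age
  ledger <- carbon_ledger(entries)
  # closed-form truth: 44/12 * (1 + root_shoot) * cf * sum_i area_i dB_i
  truth <- data.frame(
    year = years[-1],
    C_P = vapply(seq_along(years)[-1], function(ti) {
      (44 / 12) * (1 + root_shoot) * cf *
        sum(area_i * (b_aa[, ti] - b_aa[, ti - 1]))
    }, numeric(1)))
  list(ledger = ledger,
       account = project_account(ledger, ghg = NULL, leakage = 0,
                                 baseline = NULL),
       truth = truth)
}
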