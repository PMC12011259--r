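# Per-pool carbon stock-change accounting to the project net sink.
#
# The project's net sink in year t is
#
#   C_P,t = dC_P,t - GHG_E,t - LK_t - dC_BSL,t        [t CO2e]
#
# where dC_P,t sums, over strata i, species j and age classes k, the CO2e
# stock changes of the aboveground (AA) and belowground (BB) biomass pools
# of trees and shrubs. A pool's carbon stock is C = B * CF * A (biomass
# t d.m./hm2 x carbon fraction x area hm2, giving t C) and stock changes
# convert to CO2e through the single molecular-weight operator 44/12.

CO2_PER_C <- 44 / 12
POOL_LEVELS <- c("tree_AA", "tree_BB", "shrub_AA", "shrub_BB")

#' Carbon stock of one pool
#'
#' `C = B * CF * A`: per-hectare biomass times carbon fraction times stand
#' area. Linear in each argument; zero iff any factor is zero.
#'
#' @param biomass Biomass density, t d.m./hm2, non-negative.
#' @param cf Carbon fraction CF_j, strictly inside (0, 1).
#' @param area Stand area, hm2, non-negative.
#' @return Carbon stock in t C.
#' @export
#' @examples
#' pool_carbon_stock(100, 0.5, 2)  # 100 t C
pool_carbon_stock <- function(biomass, cf, area) {
  assert_non_negative(biomass, "biomass")
  assert_non_negative(area, "area")
  if (!is.numeric(cf) || any(!is.finite(cf)) || any(cf <= 0) || any(cf >= 1))
    stopf("carbon fraction must lie strictly in (0, 1)")
  biomass * cf * area
}

#' Carbon stock change as CO2 equivalent
#'
#' `(44/12) * (c_t - c_prev)`: tonnes C to tonnes CO2 through the molecular
#' weight ratio. Sign is preserved — a falling stock yields a negative
#' value (carbon source).
#'
#' @param c_t,c_prev Carbon stocks (t C) in the current and previous year.
#' @return Stock change in t CO2e.
#' @export
#' @examples
#' stock_change_co2e(12, 0)  # 44
stock_change_co2e <- function(c_t, c_prev) {
  if (any(!is.finite(c_t)) || any(!is.finite(c_prev)))
    stopf("carbon stocks must be finite")
  CO2_PER_C * (c_t - c_prev)
}

#' Shrub pool change in CO2e from a biomass delta
#'
#' `(44/12) * dB * CF * A` — algebraically identical to converting the two
#' endpoint stocks and differencing, provided CF and A are constant.
#'
#' @param delta_biomass Biomass change, t d.m./hm2 (may be negative).
#' @param cf Carbon fraction in (0, 1).
#' @param area Area, hm2.
#' @return t CO2e.
#' @export
shrub_pool_change <- function(delta_biomass, cf, area) {
  if (any(!is.finite(delta_biomass))) stopf("delta_biomass must be finite")
  assert_non_negative(area, "area")
  if (!is.numeric(cf) || any(!is.finite(cf)) || any(cf <= 0) || any(cf >= 1))
    stopf("carbon fraction must lie strictly in (0, 1)")
  CO2_PER_C * delta_biomass * cf * area
}

#' Build a validated pool ledger
#'
#' One row per (stratum, species, age class, year, pool) holding the pool's
#' biomass density, carbon fraction and area. The derived `carbon_stock`
#' column is `B * CF * A` (t C). Duplicate keys are an error.
#'
#' @param entries Data.frame with columns `stratum`, `species`, `age_class`,
#'   `year`, `pool` (one of `tree_AA`, `tree_BB`, `shrub_AA`, `shrub_BB`),
#'   `biomass` (t/hm2), `cf`, `area` (hm2).
#' @return Data.frame of class `"carbon_ledger"` with `carbon_stock` added.
#' @export
carbon_ledger <- function(entries) {
  if (!is.data.frame(entries)) stopf("`entries` must be a data.frame")
  needed <- c("stratum", "species", "age_class", "year", "pool",
              "biomass", "cf", "area")
  missing <- setdiff(needed, names(entries))
  if (length(missing))
    stopf("ledger lacks column(s): %s", paste(missing, collapse = ", "))
  if (nrow(entries)) {
    bad_pool <- !entries$pool %in% POOL_LEVELS
    if (any(bad_pool))
      stopf("unknown pool(s): %s; expected %s",
            paste(unique(entries$pool[bad_pool]), collapse = ", "),
            paste(POOL_LEVELS, collapse = ", "))
    key <- paste(entries$stratum, entries$species, entries$age_class,
                 entries$year, entries$pool, sep = "\r")
    if (anyDuplicated(key))
      stopf("duplicated ledger key(s) (stratum, species, age_class, year, pool): %s",
            paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "))
  }
  entries$carbon_stock <- if (nrow(entries))
    pool_carbon_stock(entries$biomass, entries$cf, entries$area) else numeric(0)
  class(entries) <- c("carbon_ledger", "data.frame")
  entries
}

#' Read a pool ledger CSV
#'
#' @param path CSV with the [carbon_ledger()] columns.
#' @return A `"carbon_ledger"`.
#' @export
read_carbon_ledger <- function(path) {
  carbon_ledger(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Project carbon stock change for one year
#'
#' The triple sum over strata, species and age classes of the AA + BB pool
#' changes between `year - 1` and `year`, in t CO2e. A (stratum, species,
#' age class, pool) cell present in only one of the two years counts with a
#' zero stock in the other (with a warning).
#'
#' @param ledger A [carbon_ledger()] holding both years.
#' @param year The accounting year t.
#' @return Stock change dC_P,t in t CO2e.
#' @export
project_stock_change <- function(ledger, year) {
  ledger <- if (inherits(ledger, "carbon_ledger")) ledger
            else carbon_ledger(ledger)
  cur <- ledger[ledger$year == year, , drop = FALSE]
  prev <- ledger[ledger$year == year - 1, , drop = FALSE]
  if (nrow(cur) == 0L && nrow(prev) == 0L) return(0)
  keyof <- function(df) paste(df$stratum, df$species, df$age_class, df$pool,
                              sep = "\r")
  kc <- keyof(cur); kp <- keyof(prev)
  unmatched <- union(setdiff(kc, kp), setdiff(kp, kc))
  if (length(unmatched))
    warnf("%d pool cell(s) present in only one of years %d/%d; missing stocks taken as 0",
          length(unmatched), year - 1, year)
  all_keys <- union(kc, kp)
  c_t <- stats::setNames(rep(0, length(all_keys)), all_keys)
  c_p <- c_t
  c_t[kc] <- cur$carbon_stock
  c_p[kp] <- prev$carbon_stock
  sum(stock_change_co2e(c_t, c_p))
}

#' Project GHG emission increase for one year
#'
#' `GHG_E,t = E_fuel,t + E_fertilizer,t`, both already expressed in t CO2e
#' (fuel machinery combustion; fertilizer-induced emissions are supplied as
#' CO2e by the user).
#'
#' @param fuel,fertilizer Emissions in t CO2e, non-negative.
#' @return t CO2e.
#' @export
ghg_emissions <- function(fuel, fertilizer = 0) {
  assert_non_negative(fuel, "fuel")
  assert_non_negative(fertilizer, "fertilizer")
  fuel + fertilizer
}

#' Baseline carbon stock change for one year
#'
#' Sums the AA and BB baseline changes over baseline strata. For projects
#' on cleared land the baseline change is identically zero — pass
#' `baseline = NULL` (or use [baseline_cleared()]).
#'
#' @param baseline `NULL` (cleared site), or a data.frame with columns
#'   `stratum`, `year`, `delta_aa`, `delta_bb` in t CO2e.
#' @param year Accounting year.
#' @return dC_BSL,t in t CO2e.
#' @export
baseline_change <- function(baseline, year) {
  if (is.null(baseline)) return(0)
  if (!is.data.frame(baseline) ||
      !all(c("stratum", "year", "delta_aa", "delta_bb") %in% names(baseline)))
    stopf("baseline must be NULL or have columns stratum, year, delta_aa, delta_bb")
  rows <- baseline[baseline$year == year, , drop = FALSE]
  sum(rows$delta_aa + rows$delta_bb)
}

#' Baseline for a cleared project site
#'
#' @param years Accounting years.
#' @return A baseline data.frame with zero change in every year.
#' @export
baseline_cleared <- function(years) {
  data.frame(stratum = "baseline", year = years, delta_aa = 0, delta_bb = 0)
}

#' Assemble a project account
#'
#' @param ledger A [carbon_ledger()].
#' @param ghg `NULL`, or data.frame with columns `year`, `fuel`,
#'   `fertilizer` (t CO2e).
#' @param leakage Leakage LK_t: a single value recycled to every year
#'   (default 0, the simplification for afforestation projects), or a
#'   data.frame with `year`, `leakage`.
#' @param baseline See [baseline_change()]; default `NULL` (cleared site).
#' @return List of class `"project_account"`.
#' @export
project_account <- function(ledger, ghg = NULL, leakage = 0, baseline = NULL) {
  ledger <- if (inherits(ledger, "carbon_ledger")) ledger
            else carbon_ledger(ledger)
  if (!is.null(ghg)) {
    if (!is.data.frame(ghg) ||
        !all(c("year", "fuel", "fertilizer") %in% names(ghg)))
      stopf("ghg must be NULL or have columns year, fuel, fertilizer")
    assert_non_negative(ghg$fuel, "ghg$fuel")
    assert_non_negative(ghg$fertilizer, "ghg$fertilizer")
  }
  if (is.data.frame(leakage)) {
    if (!all(c("year", "leakage") %in% names(leakage)))
      stopf("leakage data.frame needs columns year, leakage")
  } else assert_number(leakage, "leakage")
  structure(list(ledger = ledger, ghg = ghg, leakage = leakage,
                 baseline = baseline),
            class = "project_account")
}

account_component <- function(account, year) {
  ghg_t <- if (is.null(account$ghg)) 0 else {
    rows <- account$ghg[account$ghg$year == year, , drop = FALSE]
    if (nrow(rows)) sum(ghg_emissions(rows$fuel, rows$fertilizer)) else 0
  }
  lk_t <- if (is.data.frame(account$leakage)) {
    rows <- account$leakage[account$leakage$year == year, , drop = FALSE]
    if (nrow(rows)) sum(rows$leakage) else 0
  } else account$leakage
  list(delta_c_p = project_stock_change(account$ledger, year),
       ghg = ghg_t, leakage = lk_t,
       delta_c_bsl = baseline_change(account$baseline, year))
}

#' Net carbon sink of the project in year t
#'
#' `C_P,t = dC_P,t - GHG_E,t - LK_t - dC_BSL,t`, all in t CO2e. Positive
#' values are a sink, negative a source.
#'
#' @param account A [project_account()].
#' @param year Accounting year t; the ledger must contain year t or t-1
#'   entries.
#' @return Net sink C_P,t in t CO2e.
#' @export
net_carbon_sink <- function(account, year) {
  stopifnot(inherits(account, "project_account"))
  yrs <- unique(account$ledger$year)
  if (!(year %in% yrs) && !((year - 1) %in% yrs))
    stopf("ledger has no entries for year %d or %d", year, year - 1)
  cmp <- account_component(account, year)
  cmp$delta_c_p - cmp$ghg - cmp$leakage - cmp$delta_c_bsl
}

#' Year-by-year net sink series
#'
#' Evaluates every accounting identity component for each year after the
#' first ledger year.
#'
#' @param account A [project_account()].
#' @return Data.frame with columns `year`, `delta_C_P`, `GHG`, `LK`,
#'   `delta_C_BSL`, `C_P` (all t CO2e except `year`).
#' @export
net_carbon_sink_series <- function(account) {
  stopifnot(inherits(account, "project_account"))
  yrs <- sort(unique(account$ledger$year))
  if (length(yrs) < 2L) stopf("ledger must span at least two years")
  rows <- lapply(yrs[-1], function(t) {
    cmp <- account_component(account, t)
    data.frame(year = t, delta_C_P = cmp$delta_c_p, GHG = cmp$ghg,
               LK = cmp$leakage, delta_C_BSL = cmp$delta_c_bsl,
               C_P = cmp$delta_c_p - cmp$ghg - cmp$leakage - cmp$delta_c_bsl)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
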