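# Stratified sampling design for carbon monitoring plots.
#
# A project area is divided into carbon strata (homogeneous sub-areas).
# The number of monitoring plots needed to estimate the mean carbon stock
# with absolute error E at reliability t_VAL follows the classical
# stratified-sampling sample-size formula with finite-population correction,
#
#   n = N t^2 sum_i(W_i S_i^2) / (N E^2 + t^2 sum_i(W_i S_i^2)),  N = A / A_p,
#
# and plots are spread over strata by Neyman optimal allocation,
# n_i = n W_i S_i / sum(W_i S_i).

#' Build a validated stratum table
#'
#' A stratum (carbon layer) is a homogeneous sub-area of the project with an
#' area weight \eqn{W_i} and a standard deviation \eqn{S_i} of its per-plot
#' biomass carbon stock estimates (t/hm2).
#'
#' @param stratum_id Character identifiers, unique.
#' @param area_weight Fractions \eqn{W_i} in \[0,1\]; must sum to 1
#'   (tolerance 1e-9).
#' @param stock_sd Standard deviations \eqn{S_i} in t/hm2, non-negative.
#' @return A `data.frame` of class `"stratum_table"`.
#' @export
#' @examples
#' stratum_table(c("broadleaf", "conifer"), c(0.6, 0.4), c(20, 30))
stratum_table <- function(stratum_id, area_weight, stock_sd) {
  stratum_id <- as.character(stratum_id)
  if (length(stratum_id) == 0L) stopf("at least one stratum is required")
  if (anyDuplicated(stratum_id)) stopf("stratum_id values must be unique")
  if (length(area_weight) != length(stratum_id) ||
      length(stock_sd) != length(stratum_id))
    stopf("stratum_id, area_weight and stock_sd must have equal length")
  if (any(!is.finite(area_weight)) || any(area_weight < 0) ||
      any(area_weight > 1))
    stopf("area weights must lie in [0, 1]")
  if (abs(sum(area_weight) - 1) > 1e-9)
    stopf("area weights must sum to 1 (got %.12g)", sum(area_weight))
  assert_non_negative(stock_sd, "stock_sd")
  out <- data.frame(stratum_id = stratum_id,
                    area_weight = as.numeric(area_weight),
                    stock_sd = as.numeric(stock_sd),
                    stringsAsFactors = FALSE)
  class(out) <- c("stratum_table", "data.frame")
  out
}

as_stratum_table <- function(x) {
  if (inherits(x, "stratum_table")) return(x)
  if (!is.data.frame(x) ||
      !all(c("stratum_id", "area_weight", "stock_sd") %in% names(x)))
    stopf("strata must be a stratum_table or a data.frame with columns stratum_id, area_weight, stock_sd")
  stratum_table(x$stratum_id, x$area_weight, x$stock_sd)
}

#' Sampling design configuration
#'
#' @param total_area Project area \eqn{A} in hm2.
#' @param plot_area Monitoring plot area \eqn{A_p} in hm2; must be smaller
#'   than `total_area`.
#' @param reliability_index \eqn{t_{VAL}}, the reliability index. Default
#'   1.645, the two-sided 90% normal quantile matching the 90%-reliability
#'   precision requirement.
#' @param error_bound \eqn{E}, the absolute error bound of the carbon stock
#'   estimate in t/hm2.
#' @return A list of class `"sampling_config"`.
#' @seealso [error_bound_from_relative()] to derive `error_bound` from a
#'   relative precision target.
#' @export
sampling_config <- function(total_area, plot_area, reliability_index = 1.645,
                            error_bound) {
  assert_number(total_area, "total_area", lower = 0, allow_zero_lower = FALSE)
  assert_number(plot_area, "plot_area", lower = 0, allow_zero_lower = FALSE)
  assert_number(reliability_index, "reliability_index", lower = 0,
                allow_zero_lower = FALSE)
  assert_number(error_bound, "error_bound", lower = 0, allow_zero_lower = FALSE)
  if (plot_area >= total_area)
    stopf("plot_area must be smaller than total_area (N = A/Ap must exceed 1)")
  structure(list(total_area = total_area, plot_area = plot_area,
                 reliability_index = reliability_index,
                 error_bound = error_bound,
                 N = total_area / plot_area),
            class = "sampling_config")
}

sum_w_s2 <- function(strata) sum(strata$area_weight * strata$stock_sd^2)

#' Required number of monitoring plots
#'
#' Computes the plot count under the finite-population stratified-sampling
#' formula
#' \deqn{n = \frac{N\, t^2 \sum_i W_i S_i^2}{N E^2 + t^2 \sum_i W_i S_i^2}}
#' with \eqn{N = A/A_p}, then rounds up (never under-sample). Monotone
#' non-decreasing in each \eqn{S_i} and in \eqn{t}, non-increasing in
#' \eqn{E}.
#'
#' @param strata A [stratum_table()].
#' @param config A [sampling_config()].
#' @param min_plots Returned (with a warning) when all stock SDs are zero and
#'   the formula gives 0. Default 1.
#' @return Integer plot count; the unrounded value is in attribute `"raw"`.
#' @export
#' @examples
#' st <- stratum_table(c("a", "b"), c(0.6, 0.4), c(20, 30))
#' cfg <- sampling_config(total_area = 100, plot_area = 0.08, error_bound = 5)
#' required_plot_count(st, cfg)
required_plot_count <- function(strata, config, min_plots = 1L) {
  strata <- as_stratum_table(strata)
  stopifnot(inherits(config, "sampling_config"))
  wss <- sum_w_s2(strata)
  if (wss == 0) {
    warnf("all stratum stock SDs are zero; returning min_plots = %d", min_plots)
    return(structure(as.integer(min_plots), raw = 0))
  }
  t2 <- config$reliability_index^2
  n_raw <- config$N * t2 * wss / (config$N * config$error_bound^2 + t2 * wss)
  structure(as.integer(ceiling(n_raw)), raw = n_raw)
}

#' Finite-population adjustment of a plot count
#'
#' Second-iteration adjustment \eqn{n_a = n / (1 + n/N)} applied when the
#' plot count is a non-trivial fraction of the sampling population
#' \eqn{N = A/A_p}. Always \eqn{n_a \le n}; as \eqn{N \to \infty},
#' \eqn{n_a \to n}.
#'
#' @param n Raw plot count (> 0).
#' @param N Sampling population, i.e. total area / plot area.
#' @return Integer adjusted count (ceiling); unrounded value in attribute
#'   `"raw"`.
#' @export
adjust_plot_count <- function(n, N) {
  assert_number(n, "n", lower = 0, allow_zero_lower = FALSE)
  assert_number(N, "N", lower = 0, allow_zero_lower = FALSE)
  raw <- n / (1 + n / N)
  structure(as.integer(ceiling(raw)), raw = raw)
}

#' Simplified plot count for small sampled fractions
#'
#' The large-\eqn{N} limit \eqn{n = (t_{VAL}/E)^2 \sum_i W_i S_i^2},
#' applicable when the sampled plot area is below about 5% of the project
#' area. Agrees with [required_plot_count()] as `plot_area / total_area`
#' approaches zero.
#'
#' @inheritParams required_plot_count
#' @param t_val Reliability index \eqn{t_{VAL}}.
#' @param error_bound Absolute error bound \eqn{E} in t/hm2 (> 0).
#' @return Integer plot count; unrounded value in attribute `"raw"`.
#' @export
#' @examples
#' simplified_plot_count(stratum_table("all", 1, 20), t_val = 1.645,
#'                       error_bound = 5)
simplified_plot_count <- function(strata, t_val = 1.645, error_bound) {
  strata <- as_stratum_table(strata)
  assert_number(t_val, "t_val", lower = 0, allow_zero_lower = FALSE)
  assert_number(error_bound, "error_bound", lower = 0,
                allow_zero_lower = FALSE)
  raw <- (t_val / error_bound)^2 * sum_w_s2(strata)
  structure(as.integer(ceiling(raw)), raw = raw)
}

#' Optimal (Neyman) allocation of plots to strata
#'
#' Allocates `n` plots proportionally to \eqn{W_i S_i}, with
#' largest-remainder rounding so the allocation sums to `n` exactly. Strata
#' with \eqn{S_i = 0} receive 0 plots.
#'
#' @param n Total number of plots to allocate.
#' @param strata A [stratum_table()].
#' @return Named integer vector of per-stratum plot counts summing to `n`.
#' @export
#' @examples
#' allocate_plots(8, stratum_table(c("a", "b"), c(0.5, 0.5), c(10, 30)))
allocate_plots <- function(n, strata) {
  strata <- as_stratum_table(strata)
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 0)
    stopf("`n` must be a single non-negative integer")
  n <- as.integer(n)
  ws <- strata$area_weight * strata$stock_sd
  if (sum(ws) == 0) stopf("all W_i * S_i are zero; allocation undefined")
  active <- sum(ws > 0)
  if (n < active)
    warnf("n = %d is below the number of strata with positive W_i*S_i (%d); some active strata receive 0 plots",
          n, active)
  quota <- n * ws / sum(ws)
  base <- floor(quota)
  short <- n - sum(base)
  if (short > 0) {
    # largest remainder; ties broken by stratum order for determinism
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), strata$stratum_id)
}

#' Derive an absolute error bound from a relative precision target
#'
#' Computes \eqn{E = p \sum_i W_i \bar{c}_i}, the relative precision `p`
#' applied to the stratum-weighted mean carbon stock.
#'
#' @param strata A [stratum_table()].
#' @param stock_mean Per-stratum mean carbon stocks, t/hm2 (same order as
#'   `strata`).
#' @param precision Relative precision, default 0.1 (the 90%-accuracy
#'   requirement).
#' @return Absolute error bound in t/hm2.
#' @export
error_bound_from_relative <- function(strata, stock_mean, precision = 0.1) {
  strata <- as_stratum_table(strata)
  assert_non_negative(stock_mean, "stock_mean")
  if (length(stock_mean) != nrow(strata))
    stopf("stock_mean must have one value per stratum")
  assert_number(precision, "precision", lower = 0, upper = 1,
                allow_zero_lower = FALSE)
  precision * sum(strata$area_weight * stock_mean)
}

#' Full sampling design: count, adjustment, allocation
#'
#' Runs [required_plot_count()], optionally applies the finite-population
#' adjustment of [adjust_plot_count()], and allocates the result with
#' [allocate_plots()].
#'
#' @inheritParams required_plot_count
#' @param fpc When to apply the finite-population adjustment: `"auto"`
#'   (default; applied when the sampled plot-area fraction `n * Ap / A` is
#'   below `fpc_threshold`), `"always"`, or `"never"`.
#' @param fpc_threshold Sampled-fraction threshold for `"auto"`, default
#'   0.05.
#' @return A list of class `"sampling_design"` with elements `n`,
#'   `n_adjusted`, `allocation`, `N`, and `sampled_fraction`.
#' @export
#' @examples
#' st <- stratum_table(c("a", "b"), c(0.6, 0.4), c(20, 30))
#' cfg <- sampling_config(100, 0.08, error_bound = 5)
#' design_sampling(st, cfg)
design_sampling <- function(strata, config, fpc = c("auto", "always", "never"),
                            fpc_threshold = 0.05) {
  strata <- as_stratum_table(strata)
  fpc <- match.arg(fpc)
  n <- required_plot_count(strata, config)
  frac <- as.integer(n) * config$plot_area / config$total_area
  apply_fpc <- switch(fpc, always = TRUE, never = FALSE,
                      auto = frac < fpc_threshold)
  n_adj <- if (apply_fpc && n > 0L) adjust_plot_count(as.integer(n), config$N)
           else n
  structure(list(n = as.integer(n), n_adjusted = as.integer(n_adj),
                 allocation = allocate_plots(as.integer(n_adj), strata),
                 N = config$N, sampled_fraction = frac,
                 fpc_applied = apply_fpc),
            class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat("Sampling design\n")
  cat(sprintf("  raw plot count n      : %d\n", x$n))
  cat(sprintf("  adjusted count n_a    : %d (finite-population adjustment %s)\n",
              x$n_adjusted, if (x$fpc_applied) "applied" else "not applied"))
  cat(sprintf("  sampling population N : %.1f\n", x$N))
  cat("  allocation:\n")
  for (s in names(x$allocation))
    cat(sprintf("    %-12s %d\n", s, x$allocation[[s]]))
  invisible(x)
}
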