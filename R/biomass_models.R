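# Per-tree biomass estimation.
#
# Baseline: the power-law allometry M = a * D^b (optionally a * D^b * H^c),
# fitted by least squares in log space, where D is DBH (cm), H height (m)
# and M dry biomass (kg). A small feed-forward network (R/mlp.R) offers a
# region-aware alternative. Both feed the carbon-pool ledger through
# predict_biomass().

#' Construct an allometric power-law model
#'
#' `M = a * D^b` (kg from DBH in cm), optionally `M = a * D^b * H^c` with
#' height in m.
#'
#' @param a Scale coefficient (> 0).
#' @param b DBH exponent.
#' @param c Optional height exponent; `NULL` for the DBH-only form.
#' @param sigma Residual SD in log space (used by the back-transform bias
#'   correction); default 0.
#' @param bias_correct Multiply predictions by `exp(sigma^2 / 2)`? Default
#'   `FALSE`.
#' @return Object of class `"allometric_model"`.
#' @export
allometric_model <- function(a, b, c = NULL, sigma = 0, bias_correct = FALSE) {
  assert_number(a, "a", lower = 0, allow_zero_lower = FALSE)
  assert_number(b, "b")
  if (!is.null(c)) assert_number(c, "c")
  assert_number(sigma, "sigma", lower = 0)
  structure(list(a = a, b = b, c = c, sigma = sigma,
                 bias_correct = isTRUE(bias_correct), n = NA_integer_),
            class = "allometric_model")
}

#' Fit an allometric biomass model
#'
#' Ordinary least squares on `log(M) ~ log(D)` (and `log(H)` when heights
#' are supplied), the standard fitting route for `M = a D^b`. Noiseless
#' power-law data are recovered exactly. The residual log-SD is stored so
#' the lognormal back-transform correction `exp(sigma^2/2)` can be enabled.
#'
#' @param dbh DBH values in cm, all positive, length >= 3.
#' @param mass Biomass values in kg, all positive.
#' @param height Optional heights in m; adds the `H^c` term.
#' @param bias_correct Enable the back-transform bias correction on
#'   predictions. Default `FALSE` (plain `a D^b`).
#' @return A fitted `"allometric_model"`.
#' @export
#' @examples
#' d <- c(8, 12, 16, 20)
#' fit_allometric(d, 0.1 * d^2.4)
fit_allometric <- function(dbh, mass, height = NULL, bias_correct = FALSE) {
  assert_positive(dbh, "dbh")
  assert_positive(mass, "mass")
  if (length(dbh) != length(mass)) stopf("dbh and mass lengths differ")
  if (length(dbh) < 3L) stopf("at least 3 (dbh, mass) pairs are required")
  if (!is.null(height)) {
    assert_positive(height, "height")
    if (length(height) != length(dbh)) stopf("height length differs from dbh")
    fit <- stats::lm(log(mass) ~ log(dbh) + log(height))
    cf <- stats::coef(fit)
    m <- allometric_model(exp(cf[[1]]), cf[[2]], cf[[3]],
                          sigma = sqrt(mean(stats::resid(fit)^2)),
                          bias_correct = bias_correct)
  } else {
    fit <- stats::lm(log(mass) ~ log(dbh))
    cf <- stats::coef(fit)
    m <- allometric_model(exp(cf[[1]]), cf[[2]],
                          sigma = sqrt(mean(stats::resid(fit)^2)),
                          bias_correct = bias_correct)
  }
  m$n <- length(dbh)
  m
}

#' @export
print.allometric_model <- function(x, ...) {
  form <- if (is.null(x$c)) sprintf("M = %.6g * D^%.6g", x$a, x$b)
          else sprintf("M = %.6g * D^%.6g * H^%.6g", x$a, x$b, x$c)
  cat("Allometric biomass model: ", form, " (kg; D cm, H m)\n", sep = "")
  if (!is.na(x$n)) cat(sprintf("  fitted on %d stems, log-residual SD %.4g\n",
                               x$n, x$sigma))
  if (x$bias_correct) cat("  lognormal back-transform correction enabled\n")
  invisible(x)
}

#' @param object A fitted `"allometric_model"`.
#' @param dbh DBH values (cm), non-negative; 0 maps to 0 kg.
#' @param height Heights (m), required iff the model has a height exponent.
#' @param ... Unused.
#' @rdname fit_allometric
#' @export
predict.allometric_model <- function(object, dbh, height = NULL, ...) {
  if (missing(dbh)) stopf("missing required feature: dbh")
  assert_non_negative(dbh, "dbh")
  out <- object$a * dbh^object$b
  if (!is.null(object$c)) {
    if (is.null(height)) stopf("missing required feature: height")
    assert_non_negative(height, "height")
    out <- out * height^object$c
  }
  if (object$bias_correct) out <- out * exp(object$sigma^2 / 2)
  out
}

#' Predict per-tree biomass from a fitted model
#'
#' Dispatches on the model class: allometric models use DBH (and height when
#' the model includes it); MLP estimators use DBH, height, age and the
#' one-hot region code. Errors name any missing feature.
#'
#' @param model An `"allometric_model"` or `"mlp_estimator"`.
#' @param trees Data.frame of tree records (columns `dbh`, and for the MLP
#'   also `height`, `age`, `region`).
#' @return Numeric vector of biomass predictions, kg, non-negative.
#' @export
predict_biomass <- function(model, trees) {
  if (!is.data.frame(trees)) stopf("`trees` must be a data.frame")
  if (inherits(model, "allometric_model")) {
    if (!"dbh" %in% names(trees)) stopf("missing required feature: dbh")
    h <- if (!is.null(model$c)) {
      if (!"height" %in% names(trees)) stopf("missing required feature: height")
      trees$height
    }
    predict(model, dbh = trees$dbh, height = h)
  } else if (inherits(model, "mlp_estimator")) {
    predict(model, trees)
  } else stopf("unsupported model class: %s", paste(class(model), collapse = "/"))
}

#' Belowground biomass from aboveground via a root-shoot ratio
#'
#' The ledger needs both pools but field campaigns rarely excavate roots;
#' the conventional shortcut multiplies the aboveground stock by a
#' species-level root-shoot ratio.
#'
#' @param b_aa Aboveground biomass (t/hm2 or kg), non-negative.
#' @param root_shoot_ratio Ratio in (0, 1]; default 0.25.
#' @return Belowground biomass in the same unit as `b_aa`.
#' @export
belowground_from_aboveground <- function(b_aa, root_shoot_ratio = 0.25) {
  assert_non_negative(b_aa, "b_aa")
  if (!is.numeric(root_shoot_ratio) || any(root_shoot_ratio <= 0) ||
      any(root_shoot_ratio > 1))
    stopf("root_shoot_ratio must lie in (0, 1]")
  b_aa * root_shoot_ratio
}

#' Regression evaluation metrics
#'
#' R^2 (`1 - SSE/SST`), MAE, RMSE and MSE of predictions against
#' observations. With zero-variance observations R^2 is undefined and
#' reported as `NA`.
#'
#' @param predicted,observed Equal-length numeric vectors (kg).
#' @return Object of class `"fit_metrics"`: list with `r2`, `mae`, `rmse`,
#'   `mse`, `n`.
#' @export
evaluate_model <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) == 0L)
    stopf("predicted and observed must be non-empty and of equal length")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stopf("non-finite values in predicted/observed")
  err <- predicted - observed
  mse <- mean(err^2)
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst == 0) {
    warnf("observations have zero variance; R^2 undefined")
    NA_real_
  } else 1 - sum(err^2) / sst
  structure(list(r2 = r2, mae = mean(abs(err)), rmse = sqrt(mse), mse = mse,
                 n = length(observed)),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("Fit metrics (n = %d): R2 = %s, MAE = %.4f, RMSE = %.4f, MSE = %.4f\n",
              x$n, if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2),
              x$mae, x$rmse, x$mse))
  invisible(x)
}

#' Read a species parameter file
#'
#' CSV with columns `species, a, b, c, carbon_fraction, root_shoot_ratio`
#' (`c` may be empty). Used to look up allometric coefficients, carbon
#' fractions CF_j and root-shoot ratios per species.
#'
#' @param path CSV path; default the packaged example.
#' @return Data.frame keyed by species.
#' @export
read_species_params <- function(path = fc_extdata("species_params.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species", "a", "b", "carbon_fraction", "root_shoot_ratio")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stopf("species parameter file lacks column(s): %s",
          paste(missing, collapse = ", "))
  df
}
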