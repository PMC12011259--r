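# Prediction-error validation of carbon stock estimates.
#
# Given per-age predicted and observed carbon stocks (t/hm2), recompute the
# absolute and relative error of every row from the raw values — never from
# pre-printed error columns — and summarize them (mean relative error,
# absolute-error range).

#' Absolute prediction error
#'
#' `|predicted - observed|`, symmetric in its arguments.
#'
#' @param predicted,observed Carbon stocks, t/hm2.
#' @return Absolute error, t/hm2.
#' @export
absolute_error <- function(predicted, observed) {
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stopf("predicted/observed must be finite")
  abs(predicted - observed)
}

#' Relative prediction error
#'
#' `100 * |predicted - observed| / observed` — the denominator is the
#' observation (stated explicitly; verified against every row of the
#' packaged reference table).
#'
#' @param predicted,observed Carbon stocks, t/hm2; `observed` must be
#'   positive.
#' @return Relative error in percent.
#' @export
relative_error <- function(predicted, observed) {
  if (any(!is.finite(predicted))) stopf("predicted must be finite")
  if (any(!is.finite(observed)) || any(observed <= 0))
    stopf("observed values must be finite and > 0")
  100 * abs(predicted - observed) / observed
}

#' Summarize prediction errors over a validation table
#'
#' Recomputes per-row absolute and relative errors from the `predicted` and
#' `observed` columns and aggregates: arithmetic mean of relative errors,
#' minimum and maximum absolute error.
#'
#' @param rows Data.frame with columns `predicted` and `observed` (t/hm2);
#'   any further columns (age, mean DBH, ...) are carried through.
#' @return List of class `"error_summary"` with `per_row` (the input plus
#'   `absolute` and `relative` columns), `mean_relative` (%),
#'   `min_absolute` and `max_absolute` (t/hm2), and `n`.
#' @export
#' @examples
#' tab <- read_prediction_table()
#' error_summary(tab)
error_summary <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stopf("`rows` must be a non-empty data.frame")
  if (!all(c("predicted", "observed") %in% names(rows)))
    stopf("`rows` needs columns predicted and observed")
  if (any(rows$observed <= 0)) stopf("observed values must be > 0")
  per <- rows
  per$absolute <- absolute_error(rows$predicted, rows$observed)
  per$relative <- relative_error(rows$predicted, rows$observed)
  structure(list(per_row = per,
                 mean_relative = mean(per$relative),
                 min_absolute = min(per$absolute),
                 max_absolute = max(per$absolute),
                 n = nrow(per)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("Prediction error summary over %d rows\n", x$n))
  cat(sprintf("  mean relative error : %.2f %%\n", x$mean_relative))
  cat(sprintf("  absolute error range: %.3f - %.3f t/hm2\n",
              x$min_absolute, x$max_absolute))
  invisible(x)
}

#' Read a carbon stock prediction table
#'
#' CSV with columns `age`, `mean_dbh`, `mean_height`, `predicted`,
#' `observed` (and optionally the printed `abs_error` / `rel_error`
#' columns, which are ignored by [error_summary()] and kept only for
#' regression checks). Default: the packaged Chinese-fir reference table.
#'
#' @param path CSV path.
#' @return Data.frame of prediction rows.
#' @export
read_prediction_table <- function(path = fc_extdata("table2_carbon_predictions.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("predicted", "observed") %in% names(df)))
    stopf("prediction table needs columns predicted and observed")
  if (any(df$predicted <= 0) || any(df$observed <= 0))
    stopf("predicted and observed stocks must be positive")
  df
}
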