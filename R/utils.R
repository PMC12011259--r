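# internal validation and RNG helpers

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  lo_ok <- if (allow_zero_lower) x >= lower else x > lower
  if (!lo_ok || x > upper)
    stopf("`%s` = %g is outside the allowed range %s%g, %g]",
          name, x, if (allow_zero_lower) "[" else "(", lower, upper)
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("`%s` must be finite and strictly positive", name)
  invisible(x)
}

assert_non_negative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stopf("`%s` must be finite and non-negative", name)
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  All public generators route through this
# so simulations never perturb user RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("`seed` must be a single integer")
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Path to a packaged example data file
#'
#' Convenience wrapper around [system.file()] for the plain-text fixtures
#' shipped under `extdata/` (carbon-stock prediction table, plot volume
#' tables, species parameter file, example strata).
#'
#' @param file File name within `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @export
#' @examples
#' fc_extdata()
#' fc_extdata("table2_carbon_predictions.csv")
fc_extdata <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "forestcarbon")))
  path <- system.file("extdata", file, package = "forestcarbon")
  if (path == "") stopf("no packaged file named '%s'", file)
  path
}
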