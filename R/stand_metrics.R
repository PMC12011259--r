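# Stand-level volume statistics: per-species subtotals, survival ratios
# and volume densities for plot summaries.

#' Per-species volume and count subtotals
#'
#' @param groups Data.frame with columns `species`, `volume` (m3) and
#'   `count` (stems); typically one row per sample group.
#' @return Data.frame with one row per species: `species`, `volume`,
#'   `count`.
#' @export
#' @examples
#' g <- data.frame(species = c("a", "a", "b"), volume = c(1, 2, 5),
#'                 count = c(10, 20, 7))
#' species_subtotals(g)
species_subtotals <- function(groups) {
  if (!is.data.frame(groups) || nrow(groups) == 0L)
    stopf("`groups` must be a non-empty data.frame")
  if (!all(c("species", "volume", "count") %in% names(groups)))
    stopf("`groups` needs columns species, volume, count")
  assert_non_negative(groups$volume, "volume")
  assert_non_negative(groups$count, "count")
  if (any(groups$count != round(groups$count)))
    stopf("tree counts must be integers")
  vol <- tapply(groups$volume, groups$species, sum)
  cnt <- tapply(groups$count, groups$species, sum)
  out <- data.frame(species = names(vol), volume = as.numeric(vol),
                    count = as.integer(cnt), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Survival ratio of standing volume
#'
#' Percentage of the total stand volume contributed by surviving stems.
#' Full precision is returned; the paper-style 2-decimal display is left to
#' `print()`/`round()`.
#'
#' @param total Total stand volume, m3 (> 0).
#' @param surviving Surviving-stem volume, m3, non-negative.
#' @return Percentage in \[0, 100\] (when `surviving <= total`).
#' @export
#' @examples
#' survival_ratio(24.41, 23.74)  # 97.26 (2 dp)
survival_ratio <- function(total, surviving) {
  if (!is.numeric(total) || any(total <= 0)) stopf("total volume must be > 0")
  assert_non_negative(surviving, "surviving")
  100 * surviving / total
}

#' Stand volume density
#'
#' @param volume Volume, m3, non-negative.
#' @param area Plot area, hm2 (> 0).
#' @return Density in m3/hm2.
#' @export
volume_density <- function(volume, area) {
  assert_non_negative(volume, "volume")
  if (!is.numeric(area) || any(area <= 0)) stopf("area must be > 0")
  volume / area
}

#' Plot volume summary
#'
#' Bundles the stand volume statistics of one monitoring plot: total and
#' surviving volume, both densities, and the survival ratio.
#'
#' @param total_volume Total standing volume, m3.
#' @param surviving_volume Surviving-stem volume, m3 (must not exceed
#'   `total_volume` beyond rounding slack 1e-9).
#' @param area Plot area, hm2.
#' @return List of class `"plot_volume_summary"`.
#' @export
#' @examples
#' plot_volume_summary(36.00, 30.30, area = 0.8)
plot_volume_summary <- function(total_volume, surviving_volume, area) {
  assert_number(total_volume, "total_volume", lower = 0,
                allow_zero_lower = FALSE)
  assert_number(surviving_volume, "surviving_volume", lower = 0)
  assert_number(area, "area", lower = 0, allow_zero_lower = FALSE)
  if (surviving_volume > total_volume + 1e-9)
    stopf("surviving volume (%g) exceeds total volume (%g)",
          surviving_volume, total_volume)
  structure(list(total_volume = total_volume,
                 surviving_volume = surviving_volume,
                 area = area,
                 volume_density = volume_density(total_volume, area),
                 surviving_density = volume_density(surviving_volume, area),
                 survival_ratio = survival_ratio(total_volume,
                                                 surviving_volume)),
            class = "plot_volume_summary")
}

#' @export
print.plot_volume_summary <- function(x, ...) {
  cat("Plot volume summary\n")
  cat(sprintf("  total volume      : %.2f m3\n", x$total_volume))
  cat(sprintf("  surviving volume  : %.2f m3\n", x$surviving_volume))
  cat(sprintf("  volume density    : %.2f m3/hm2\n", x$volume_density))
  cat(sprintf("  surviving density : %.2f m3/hm2\n", x$surviving_density))
  cat(sprintf("  survival ratio    : %.2f %%\n", x$survival_ratio))
  invisible(x)
}

#' Read a packaged species-volume table
#'
#' Long-format CSV with columns `sample_group`, `species`, `volume`,
#' `count` (the shape of the packaged standing/surviving volume fixtures).
#'
#' @param path CSV path, e.g.
#'   `fc_extdata("plot2_surviving_volume.csv")`.
#' @return Data.frame suitable for [species_subtotals()].
#' @export
read_volume_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_group", "species", "volume", "count") %in% names(df)))
    stopf("volume table needs columns sample_group, species, volume, count")
  df
}
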