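# Reading, splicing and cleaning forest inventory tables.
#
# Tree tallies arrive as heterogeneous per-region CSV exports; this module
# unifies species names against a synonym table, outer-joins tables on
# shared fields, and applies the cleaning rules: drop stems with no biomass
# at all, impute a single missing organ from the total, and discard stems
# whose recorded biomass deviates from a reference allometric prediction by
# more than a stated relative tolerance.

ORGAN_COLS <- c("biomass_stem", "biomass_branch", "biomass_leaf",
                "biomass_root")

#' Default species synonym table
#'
#' Maps lowercase, whitespace-trimmed regional aliases to canonical
#' scientific names. Chinese fir (Cunninghamia lanceolata) carries many
#' regional names; the defaults cover the common ones.
#'
#' @return Named character vector: `alias -> canonical name`.
#' @export
default_species_synonyms <- function() {
  c("sand wood"  = "Cunninghamia lanceolata",
    "sand tree"  = "Cunninghamia lanceolata",
    "thorn fir"  = "Cunninghamia lanceolata",
    "cedar"      = "Cunninghamia lanceolata",
    "chinese fir" = "Cunninghamia lanceolata",
    "black locust" = "Robinia pseudoacacia",
    "chinese pine" = "Pinus tabulaeformis")
}

#' Normalize species names against a synonym table
#'
#' Lowercases and trims each raw name, then looks it up in the synonym
#' table. Names already equal to a canonical name are returned unchanged.
#' Unknown names are kept as-is (auditable, never silently dropped) with a
#' warning and are flagged in the `"unknown"` attribute.
#'
#' @param name_raw Character vector of raw species names.
#' @param synonyms Named character vector mapping lowercase trimmed aliases
#'   to canonical names; default [default_species_synonyms()].
#' @return Character vector of canonical names, with a logical attribute
#'   `"unknown"` marking names not found in the table.
#' @export
#' @examples
#' normalize_species(c("sand wood", "  CEDAR "))
normalize_species <- function(name_raw, synonyms = default_species_synonyms()) {
  if (!is.character(name_raw)) stopf("species names must be character")
  key <- tolower(trimws(name_raw))
  if (any(key == "" | is.na(key))) stopf("empty species name")
  canonical <- unique(unname(synonyms))
  out <- name_raw
  unknown <- logical(length(key))
  for (i in seq_along(key)) {
    if (key[i] %in% names(synonyms)) {
      out[i] <- unname(synonyms[[key[i]]])
    } else if (trimws(name_raw[i]) %in% canonical) {
      out[i] <- trimws(name_raw[i])
    } else {
      unknown[i] <- TRUE
    }
  }
  if (any(unknown))
    warnf("%d species name(s) not in the synonym table, kept unchanged: %s",
          sum(unknown), paste(unique(name_raw[unknown]), collapse = ", "))
  structure(out, unknown = unknown)
}

#' Splice several tree-record tables into one
#'
#' Outer-union of columns: the merged table carries every field that occurs
#' in any input; rows from tables lacking a field get `NA` there. Row count
#' is conserved. A `.source` column records the table each row came from.
#'
#' @param tables List of data.frames (each with a header, shared fields in
#'   identical units).
#' @param source_names Optional character names for the `.source` column;
#'   defaults to list names or `table1`, `table2`, ...
#' @return One merged data.frame.
#' @export
splice_tables <- function(tables, source_names = NULL) {
  if (!is.list(tables)) stopf("`tables` must be a list of data.frames")
  if (length(tables) == 0L)
    return(data.frame(.source = character(0), stringsAsFactors = FALSE))
  if (is.null(source_names))
    source_names <- if (!is.null(names(tables)) && all(nzchar(names(tables))))
      names(tables) else paste0("table", seq_along(tables))
  all_cols <- unique(unlist(lapply(tables, names)))
  # shared fields must agree in type (numeric vs character)
  for (col in all_cols) {
    kinds <- unique(vapply(tables, function(tb) {
      if (!col %in% names(tb)) return(NA_character_)
      if (is.numeric(tb[[col]])) "numeric" else "character"
    }, character(1)))
    kinds <- kinds[!is.na(kinds)]
    if (length(kinds) > 1L)
      stopf("field '%s' has conflicting types across tables (%s)",
            col, paste(kinds, collapse = " vs "))
  }
  pieces <- lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    for (col in setdiff(all_cols, names(tb))) tb[[col]] <- NA
    tb <- tb[, all_cols, drop = FALSE]
    tb$.source <- source_names[[i]]
    tb
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Clean tree records against a reference allometric model
#'
#' Applies the inventory cleaning rules in order:
#' \enumerate{
#'   \item stems with neither total biomass nor any organ biomass are
#'     dropped (a stem with organ masses but no total gets the total
#'     recomputed as the organ sum);
#'   \item stems with total present and exactly one organ missing have that
#'     organ imputed as `total - sum(other organs)`;
#'   \item stems whose biomass deviates from the reference prediction
#'     `a * D^b` by more than `tolerance` (relative to the prediction) are
#'     dropped as recording outliers.
#' }
#' Row conservation holds: `n_input = n_output + dropped(missing) +
#' dropped(outlier)`.
#'
#' @param trees Data.frame of tree records with at least `dbh` and
#'   `biomass`; organ columns `biomass_stem`, `biomass_branch`,
#'   `biomass_leaf`, `biomass_root` are used when present.
#' @param reference_model An [allometric_model()] predicting biomass (kg)
#'   from DBH (cm).
#' @param tolerance Relative deviation in (0, 1] beyond which a record is an
#'   outlier; default 0.5.
#' @return List with `records` (cleaned data.frame) and `report`
#'   (a `cleaning_report`).
#' @export
clean_records <- function(trees, reference_model, tolerance = 0.5) {
  if (!is.data.frame(trees)) stopf("`trees` must be a data.frame")
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
      tolerance <= 0 || tolerance > 1)
    stopf("`tolerance` must be in (0, 1]")
  if (!inherits(reference_model, "allometric_model"))
    stopf("`reference_model` must be an allometric_model")
  n_input <- nrow(trees)
  msgs <- character(0)
  organs <- intersect(ORGAN_COLS, names(trees))
  if (!"biomass" %in% names(trees)) trees$biomass <- NA_real_

  organ_sum <- function(df, which = organs) {
    if (length(which) == 0L) return(rep(NA_real_, nrow(df)))
    m <- as.matrix(df[, which, drop = FALSE])
    rowSums(m)
  }

  # 1. drop stems with no biomass information at all
  no_total <- is.na(trees$biomass)
  all_organs_missing <- if (length(organs))
    rowSums(!is.na(trees[, organs, drop = FALSE])) == 0L
  else rep(TRUE, n_input)
  drop_missing <- no_total & all_organs_missing
  n_drop_missing <- sum(drop_missing)
  if (n_drop_missing)
    msgs <- c(msgs, sprintf("dropped %d record(s) with no biomass data",
                            n_drop_missing))
  kept <- trees[!drop_missing, , drop = FALSE]

  # recompute total from complete organs when total absent
  if (length(organs)) {
    complete <- rowSums(is.na(kept[, organs, drop = FALSE])) == 0L
    fill <- is.na(kept$biomass) & complete
    if (any(fill)) {
      kept$biomass[fill] <- organ_sum(kept)[fill]
      msgs <- c(msgs, sprintf("recomputed total biomass for %d record(s) from organ sums",
                              sum(fill)))
    }
  }

  # 2. impute a single missing organ from the total
  n_imputed <- 0L
  if (length(organs) > 1L) {
    miss <- is.na(kept[, organs, drop = FALSE])
    one_missing <- rowSums(miss) == 1L & !is.na(kept$biomass)
    for (r in which(one_missing)) {
      col <- organs[which(miss[r, ])]
      others <- sum(unlist(kept[r, setdiff(organs, col)]))
      val <- kept$biomass[r] - others
      if (val >= 0) {
        kept[[col]][r] <- val
        n_imputed <- n_imputed + 1L
      } else {
        msgs <- c(msgs, sprintf("row %s: organ imputation skipped (total below organ sum)",
                                rownames(kept)[r]))
      }
    }
    if (n_imputed)
      msgs <- c(msgs, sprintf("imputed %d missing organ value(s) from totals",
                              n_imputed))
  }

  # 3. outlier screen against the reference allometric prediction
  pred <- predict(reference_model, dbh = kept$dbh)
  rel_dev <- abs(kept$biomass - pred) / pred
  outlier <- !is.na(rel_dev) & rel_dev > tolerance
  n_outlier <- sum(outlier)
  if (n_outlier)
    msgs <- c(msgs, sprintf("dropped %d outlier(s) deviating > %.0f%% from the reference allometry",
                            n_outlier, 100 * tolerance))
  out <- kept[!outlier, , drop = FALSE]
  rownames(out) <- NULL

  report <- structure(list(n_input = n_input,
                           n_output = nrow(out),
                           n_dropped_missing_biomass = n_drop_missing,
                           n_dropped_outlier = n_outlier,
                           n_imputed_organ = n_imputed,
                           messages = msgs),
                      class = "cleaning_report")
  stopifnot(report$n_input == report$n_output +
              report$n_dropped_missing_biomass + report$n_dropped_outlier)
  list(records = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Inventory cleaning report\n")
  cat(sprintf("  input records           : %d\n", x$n_input))
  cat(sprintf("  retained                 : %d\n", x$n_output))
  cat(sprintf("  dropped (missing biomass): %d\n", x$n_dropped_missing_biomass))
  cat(sprintf("  dropped (outlier)        : %d\n", x$n_dropped_outlier))
  cat(sprintf("  organs imputed           : %d\n", x$n_imputed_organ))
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

#' Write a cleaning report as JSON
#'
#' @param report A `cleaning_report` from [clean_records()].
#' @param path Output file path.
#' @export
write_cleaning_report <- function(report, path) {
  stopifnot(inherits(report, "cleaning_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tree tally CSV
#'
#' Expects (after optional renaming via `column_map`) the canonical columns
#' `tree_id, species, dbh, height, age, region, biomass`, with DBH in cm,
#' height in m, age in years, biomass in kg and region an integer code 0-5.
#' Organ columns (`biomass_stem`, `biomass_branch`, `biomass_leaf`,
#' `biomass_root`) and `alive` are optional.
#'
#' @param path CSV file path (UTF-8, comma-separated, header row).
#' @param column_map Optional named character vector `canonical = file_name`
#'   renaming file columns to the canonical schema.
#' @param synonyms Species synonym table for [normalize_species()]; `NULL`
#'   skips normalization.
#' @return Data.frame of tree records with a `species_raw` column preserving
#'   the file's spelling.
#' @export
read_tree_tally <- function(path, column_map = NULL,
                            synonyms = default_species_synonyms()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stopf("column '%s' not found in %s", src, path)
      names(df)[names(df) == src] <- canon
    }
  }
  needed <- c("tree_id", "species", "dbh")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stopf("tree tally %s lacks required column(s): %s", path,
          paste(missing, collapse = ", "))
  validate_tree_records(df)
  df$species_raw <- df$species
  if (!is.null(synonyms))
    df$species <- as.character(normalize_species(df$species, synonyms))
  df
}

validate_tree_records <- function(df) {
  for (col in c("dbh", "height")) {
    if (col %in% names(df)) {
      v <- df[[col]]
      bad <- !is.na(v) & (!is.finite(v) | v <= 0)
      if (any(bad))
        stopf("%d record(s) have non-positive or non-finite %s", sum(bad), col)
    }
  }
  if ("age" %in% names(df) && any(!is.na(df$age) & df$age < 0))
    stopf("negative ages present")
  if ("region" %in% names(df)) {
    bad <- !is.na(df$region) & !df$region %in% 0:5
    if (any(bad)) stopf("region codes must be integers 0-5")
  }
  if ("biomass" %in% names(df) &&
      any(!is.na(df$biomass) & df$biomass < 0))
    stopf("negative biomass present")
  # when all organs are present the total must match their sum
  if (all(ORGAN_COLS %in% names(df)) && "biomass" %in% names(df)) {
    s <- rowSums(df[, ORGAN_COLS])
    chk <- !is.na(s) & !is.na(df$biomass)
    off <- chk & abs(df$biomass - s) > 1e-6 * pmax(abs(s), 1)
    if (any(off))
      stopf("%d record(s): biomass total disagrees with organ sum", sum(off))
  }
  invisible(df)
}

#' Build a plot inventory
#'
#' Bundles a monitoring plot's metadata with its tree records. All trees are
#' expected to share the plot's region code; a mixture triggers a warning,
#' not an error (auditable, like all cleaning decisions).
#'
#' @param plot_id Plot identifier.
#' @param area Plot area in hm2 (> 0).
#' @param stratum_id Carbon stratum the plot belongs to.
#' @param year Calendar year of measurement.
#' @param trees Data.frame of tree records.
#' @return A list of class `"plot_inventory"`.
#' @export
plot_inventory <- function(plot_id, area, stratum_id, year, trees) {
  assert_number(area, "area", lower = 0, allow_zero_lower = FALSE)
  if (!is.data.frame(trees)) stopf("`trees` must be a data.frame")
  if ("region" %in% names(trees)) {
    reg <- unique(trees$region[!is.na(trees$region)])
    if (length(reg) > 1L)
      warnf("plot %s mixes region codes: %s", plot_id,
            paste(reg, collapse = ", "))
  }
  validate_tree_records(trees)
  structure(list(plot_id = as.character(plot_id), area = area,
                 stratum_id = as.character(stratum_id),
                 year = as.integer(year), trees = trees),
            class = "plot_inventory")
}

#' @export
print.plot_inventory <- function(x, ...) {
  cat(sprintf("Plot %s (stratum %s, %d): %.3g hm2, %d trees\n",
              x$plot_id, x$stratum_id, x$year, x$area, nrow(x$trees)))
  invisible(x)
}

#' Compare two entries of the same table (dual-track check)
#'
#' Field data are entered twice by different operators; this reports every
#' cell where the two entries disagree so the original sheets can be
#' re-checked.
#'
#' @param a,b Data.frames with identical dimensions and column names.
#' @param tol Numeric tolerance for numeric columns, default 0 (exact).
#' @return Data.frame with columns `row`, `column`, `value_a`, `value_b`;
#'   zero rows when the entries agree.
#' @export
diff_entries <- function(a, b, tol = 0) {
  if (!identical(dim(a), dim(b)) || !identical(names(a), names(b)))
    stopf("the two entries must have identical dimensions and column names")
  out <- list()
  for (col in names(a)) {
    va <- a[[col]]; vb <- b[[col]]
    differ <- if (is.numeric(va) && is.numeric(vb))
      !(is.na(va) & is.na(vb)) & (xor(is.na(va), is.na(vb)) |
                                    abs(va - vb) > tol)
    else !(is.na(va) & is.na(vb)) & (xor(is.na(va), is.na(vb)) | va != vb)
    differ[is.na(differ)] <- FALSE
    if (any(differ))
      out[[col]] <- data.frame(row = which(differ), column = col,
                               value_a = as.character(va[differ]),
                               value_b = as.character(vb[differ]),
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(row = integer(0), column = character(0),
                      value_a = character(0), value_b = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$row, res$column), , drop = FALSE]
}
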