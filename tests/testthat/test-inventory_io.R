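test_that("normalize_species folds case/whitespace and flags unknowns", {
  expect_equal(as.character(normalize_species("sand wood")),
               "Cunninghamia lanceolata")
  expect_equal(as.character(normalize_species("  CEDAR ")),
               "Cunninghamia lanceolata")
  # canonical names pass through untouched
  out <- normalize_species("Cunninghamia lanceolata")
  expect_equal(as.character(out), "Cunninghamia lanceolata")
  expect_false(any(attr(out, "unknown")))
  expect_warning(unk <- normalize_species("mystery oak"), "not in the synonym")
  expect_equal(as.character(unk), "mystery oak")
  expect_true(attr(unk, "unknown"))
  expect_error(normalize_species(""), "empty")
})

test_that("splice_tables outer-unions columns and conserves rows", {
  t1 <- data.frame(id = 1:3, dbh = c(10, 12, 14))
  t2 <- data.frame(id = 4:7, dbh = c(9, 11, 13, 15), height = c(6, 7, 8, 9))
  merged <- splice_tables(list(t1, t2))
  expect_identical(nrow(merged), 7L)
  expect_setequal(names(merged), c("id", "dbh", "height", ".source"))
  expect_true(all(is.na(merged$height[merged$.source == "table1"])))
  expect_false(anyNA(merged$height[merged$.source == "table2"]))
  # empty input
  expect_identical(nrow(splice_tables(list())), 0L)
  # conflicting types name the offending field
  t3 <- data.frame(id = 1, dbh = "twelve", stringsAsFactors = FALSE)
  expect_error(splice_tables(list(t1, t3)), "dbh")
})

test_that("clean_records applies drop/impute/outlier rules with row conservation", {
  ref <- allometric_model(a = 0.1, b = 2.4)
  trees <- data.frame(
    tree_id = paste0("t", 1:6),
    dbh = c(10, 10, 10, 10, 10, 10),
    biomass = c(0.1 * 10^2.4,      # exactly on the reference: retained
                NA,                # no biomass anywhere: dropped
                3 * 0.1 * 10^2.4,  # 200% above prediction: outlier
                NA,                # organs present: total recomputed
                25, 25),           # near the ~25.1 kg prediction: retained
    biomass_stem = c(NA, NA, NA, 15, 10, NA),
    biomass_branch = c(NA, NA, NA, 5, 5, 8),
    biomass_leaf = c(NA, NA, NA, 3, 5, 3),
    biomass_root = c(NA, NA, NA, 2, 5, 4))
  res <- clean_records(trees, ref, tolerance = 0.5)
  rep <- res$report
  expect_identical(rep$n_input, 6L)
  expect_identical(rep$n_dropped_missing_biomass, 1L)
  expect_identical(rep$n_dropped_outlier, 1L)
  expect_identical(rep$n_input,
                   rep$n_output + rep$n_dropped_missing_biomass +
                     rep$n_dropped_outlier)
  # t4: total recomputed from complete organs (15+5+3+2 = 25 kg)
  expect_equal(res$records$biomass[res$records$tree_id == "t4"], 25)
  # t6: missing stem imputed as total - other organs = 25 - 15 = 10
  expect_equal(res$records$biomass_stem[res$records$tree_id == "t6"], 10)
  expect_identical(rep$n_imputed_organ, 1L)
  expect_error(clean_records(trees, ref, tolerance = 0), "tolerance")
})

test_that("tolerance is relative to the reference prediction", {
  ref <- allometric_model(a = 1, b = 0)  # predicts 1 kg for any D; scale up
  ref$a <- 100; ref$b <- 0               # predicts 100 kg flat
  trees <- data.frame(tree_id = c("x", "y"), dbh = c(10, 10),
                      biomass = c(200, 149))
  res <- clean_records(trees, ref, tolerance = 0.5)
  # 200 kg vs 100 kg predicted: relative deviation 1.0 > 0.5 -> dropped
  expect_identical(res$report$n_dropped_outlier, 1L)
  expect_identical(res$records$tree_id, "y")
})

test_that("cleaning is idempotent on already-clean tables", {
  ref <- allometric_model(0.1, 2.4)
  trees <- make_power_law_trees(40, sigma = 0.05, seed = 9)
  first <- clean_records(trees, ref, tolerance = 0.5)
  second <- clean_records(first$records, ref, tolerance = 0.5)
  expect_identical(second$report$n_output, second$report$n_input)
  expect_identical(second$report$n_dropped_outlier, 0L)
  expect_identical(second$report$n_dropped_missing_biomass, 0L)
})

test_that("tree tally CSV round-trips with unit-checked columns", {
  trees <- make_power_law_trees(12, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(trees, path, row.names = FALSE)
  back <- read_tree_tally(path)
  expect_equal(back$dbh, trees$dbh, tolerance = 1e-12)
  expect_equal(back$height, trees$height, tolerance = 1e-12)
  expect_equal(back$biomass, trees$biomass, tolerance = 1e-12)
  # column mapping renames on ingestion
  alt <- trees
  names(alt)[names(alt) == "dbh"] <- "dbh_cm"
  write.csv(alt, path, row.names = FALSE)
  back2 <- read_tree_tally(path, column_map = c(dbh = "dbh_cm"))
  expect_equal(back2$dbh, trees$dbh, tolerance = 1e-12)
  # invalid data rejected
  bad <- trees; bad$dbh[1] <- -3
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_tree_tally(path), "dbh")
})

test_that("plot_inventory validates area and mixed regions warn", {
  trees <- make_power_law_trees(5, seed = 2)
  trees$region <- c(0, 0, 0, 1, 0)
  expect_warning(plot_inventory("P1", 0.08, "S1", 2020, trees), "region")
  trees$region <- 0
  inv <- plot_inventory("P1", 0.08, "S1", 2020, trees)
  expect_s3_class(inv, "plot_inventory")
  expect_error(plot_inventory("P1", 0, "S1", 2020, trees), "area")
})

test_that("diff_entries reports cell-level mismatches of dual entries", {
  a <- data.frame(id = 1:3, dbh = c(10.0, 12.5, 14.1))
  b <- a
  expect_identical(nrow(diff_entries(a, b)), 0L)
  b$dbh[2] <- 12.6
  d <- diff_entries(a, b)
  expect_identical(d$row, 2L)
  expect_identical(d$column, "dbh")
  expect_identical(nrow(diff_entries(a, b, tol = 0.2)), 0L)
})
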