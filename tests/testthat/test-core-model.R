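test_that("a consistent toy dataset loads and documentation flags count", {
  ds <- make_toy_dataset()
  expect_s3_class(ds, "ni_dataset")
  expect_equal(nrow(ds$records), 3)
  flags <- documentation_flags(ds)
  expect_equal(sum(flags$delta), 3)
  # lattice spans all (indicator x ecosystem) pairs with membership, crossed
  # with units where the ecosystem is present: 4 pairs x 2 units x 1 date
  expect_equal(nrow(flags), 8)
})

test_that("invariant violations are rejected with the offending cell named", {
  ds <- make_toy_dataset()
  rec <- ds$records
  bad <- rec
  bad$q25[2] <- 5; bad$q75[2] <- 3
  err <- expect_error(ni_dataset(bad, ds$references, ds$meta, ds$units),
                      "q25 > q75")
  expect_match(conditionMessage(err), "ptarmigan")
  expect_match(conditionMessage(err), "u1")
  expect_match(conditionMessage(err), "2010")

  bad <- rec; bad$mean_value[1] <- -2
  expect_error(ni_dataset(bad, ds$references, ds$meta, ds$units),
               "negative or non-finite")

  bad <- rec; bad$indicator_id[1] <- "unknown_ind"
  # also add metadata so the reference check is the one that fires
  meta2 <- rbind(ds$meta, data.frame(indicator_id = "unknown_ind",
                                     ecosystem_id = "forest",
                                     membership = 1, group_id = "g",
                                     extra_representative = FALSE))
  err <- expect_error(ni_dataset(bad, ds$references, meta2, ds$units),
                      "missing reference state")
  expect_match(conditionMessage(err), "unknown_ind")

  bad <- rbind(rec, rec[1, ])
  expect_error(ni_dataset(bad, ds$references, ds$meta, ds$units),
               "duplicate observation")

  refs2 <- ds$references; refs2$ref_value[1] <- 0
  expect_error(ni_dataset(rec, refs2, ds$meta, ds$units), "positive")

  meta3 <- ds$meta; meta3$membership[2] <- 0.5
  expect_error(ni_dataset(rec, ds$references, meta3, ds$units),
               "sum to 1")
})

test_that("duplication groups must be identical copies of one elicitation", {
  ds <- make_toy_dataset()
  rec <- ds$records
  rec2 <- rec[2, ]; rec2$unit_id <- "u2"
  rec$duplication_group <- c(NA, "d1", NA)
  rec2$duplication_group <- "d1"
  ok <- ni_dataset(rbind(rec, rec2), ds$references, ds$meta, ds$units)
  expect_equal(sum(!is.na(ok$records$duplication_group)), 2)

  rec2$mean_value <- 99
  expect_error(ni_dataset(rbind(rec, rec2), ds$references, ds$meta,
                          ds$units), "duplication_group")
})

test_that("delta is a pure function of record presence", {
  ds <- make_toy_dataset()
  # empty records: all delta zero, lattice shape intact
  empty <- ds$records[0, ]
  ds0 <- ni_dataset(empty, ds$references, ds$meta, ds$units, dates = 2010L)
  f0 <- documentation_flags(ds0)
  expect_equal(sum(f0$delta), 0)
  expect_equal(nrow(f0), 8)
  # adding one record flips exactly one delta
  ds1 <- ni_dataset(ds$records[1, ], ds$references, ds$meta, ds$units,
                    dates = 2010L)
  f1 <- documentation_flags(ds1)
  expect_equal(sum(f1$delta), 1)
  expect_equal(sum(f0$delta != f1$delta), 1)
  key0 <- paste(f0$indicator_id, f0$ecosystem_id, f0$unit_id, f0$date)
  key1 <- paste(f1$indicator_id, f1$ecosystem_id, f1$unit_id, f1$date)
  expect_identical(key0, key1)
})

test_that("a fully documented lattice has all delta = 1", {
  ds <- make_toy_dataset()
  flags <- documentation_flags(ds)
  full <- flags[, c("indicator_id", "ecosystem_id", "unit_id", "date")]
  full$mean_value <- 10; full$q25 <- 9; full$q75 <- 11
  full$source <- "expert"; full$variable_kind <- "continuous"
  refs <- unique(full[, c("indicator_id", "ecosystem_id", "unit_id")])
  refs$ref_value <- 50; refs$definition_tag <- "pristine"
  refs$scaling_model <- "minimal"
  ds_full <- ni_dataset(full, refs, ds$meta, ds$units)
  expect_true(all(documentation_flags(ds_full)$delta == 1))
})

test_that("CSV and JSON round trips reproduce every field bit-identically", {
  g <- generate_dataset(ni_generator_config(n_units = 3, n_indicators = 4,
                                            seed = 7))
  ds <- g$dataset
  for (fmt in c("csv", "json")) {
    path <- file.path(tempfile("ni"),
                      if (fmt == "json") "ds.json" else "tables")
    dir.create(dirname(path), recursive = TRUE)
    write_ni(ds, path, format = fmt)
    back <- read_ni(path)
    for (tab in c("records", "references", "meta", "units")) {
      a <- ds[[tab]]; b <- back[[tab]][names(ds[[tab]])]
      rownames(a) <- rownames(b) <- NULL
      expect_identical(a, b, label = sprintf("%s (%s)", tab, fmt))
    }
  }
})

test_that("the packaged synthetic example study loads and validates", {
  path <- system.file("extdata", "synthetic_example",
                      package = "natureindex")
  ds <- read_ni(path)
  expect_s3_class(ds, "ni_dataset")
  expect_equal(length(unique(ds$meta$ecosystem_id)), 3)
  expect_equal(length(unique(ds$units$unit_id)), 6)
  expect_equal(ds$dates, c(1950L, 1990L, 2000L, 2010L))
  # the fixture is bit-identical to regenerating it from its seed
  g <- generate_dataset(ni_generator_config(n_indicators = 4, seed = 2025))
  expect_equal(ds$records, g$dataset$records)
})

test_that("reader applies a schema column mapping and flags missing files", {
  ds <- make_toy_dataset()
  dir <- tempfile("nicsv")
  write_ni(ds, dir, format = "csv")
  rec <- utils::read.csv(file.path(dir, "records.csv"))
  names(rec)[names(rec) == "mean_value"] <- "mean"
  utils::write.csv(rec, file.path(dir, "records.csv"), row.names = FALSE,
                   na = "")
  expect_error(read_ni(dir), "mean_value")
  back <- read_ni(dir, schema = list(records = c(mean_value = "mean")))
  expect_equal(back$records$mean_value, ds$records$mean_value)
  expect_error(read_ni(tempfile("nope")), "no such file")
})
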