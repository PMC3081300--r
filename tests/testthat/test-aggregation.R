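test_that("the index of constant cells is their exact weighted mean", {
  # two ordinary indicators in different groups, weights 0.5 each,
  # constant scaled values 0.2 and 0.6 -> index 0.4 with zero-width CI
  ds <- make_constant_dataset(c(0.2, 0.6))
  scaled <- scale_dataset(draw_replicates(fit_dataset(ds), 999, 1), ds)
  res <- compute_index(scaled, ds, ni_scope(), 2010L)
  expect_equal(res$median, 0.4)
  expect_equal(res$ci_low, 0.4)
  expect_equal(res$ci_high, 0.4)
  expect_equal(res$n_documented, 2L)
  expect_true(all(res$sims == 0.4))
})

test_that("a single documented cell passes through unchanged", {
  ds <- make_constant_dataset(0.7)
  scaled <- scale_dataset(draw_replicates(fit_dataset(ds), 99, 1), ds)
  res <- compute_index(scaled, ds, ni_scope(), 2010L)
  expect_equal(res$sims, unname(scaled$values[1, ]))
})

test_that("index draws stay in [0, 1] and CIs bracket the median", {
  g <- generate_dataset(ni_generator_config(n_units = 4, n_indicators = 5,
                                            noise = 0.3, seed = 21))
  tr <- nature_index(g$dataset, n_sim = 299, seed = 2)
  for (r in tr) {
    expect_true(all(r$sims >= 0 & r$sims <= 1))
    expect_lte(r$ci_low, r$median)
    expect_gte(r$ci_high, r$median)
    expect_equal(sum(r$source_counts), r$n_documented)
  }
})

test_that("country index equals the area-weighted mean of unit indexes", {
  cfg <- ni_generator_config(n_units = 5, n_ecosystems = 2,
                             n_indicators = 4, dates = 2010L,
                             missingness_prob = 0, seed = 31)
  ds <- generate_dataset(cfg)$dataset
  scaled <- scale_dataset(draw_replicates(fit_dataset(ds), 199, 1), ds)
  country <- compute_index(scaled, ds, ni_scope(), 2010L)
  units <- unique(ds$units$unit_id)
  aw <- area_weights(ds$units, units)
  acc <- 0
  for (k in units) {
    uk <- compute_index(scaled, ds, ni_scope(units = k), 2010L)
    acc <- acc + aw$area_factor[aw$unit_id == k] * uk$sims
  }
  expect_equal(country$sims, acc, tolerance = 1e-12)
})

test_that("tie convention and extreme separations in date comparisons", {
  ds <- make_constant_dataset(c(0.3, 0.5), dates = c(2000L, 2010L))
  scaled <- scale_dataset(draw_replicates(fit_dataset(ds), 999, 1), ds)
  r1 <- compute_index(scaled, ds, ni_scope(), 2000L)
  r2 <- compute_index(scaled, ds, ni_scope(), 2010L)
  tie <- compare_dates(r1, r2)   # identical constants at both dates
  expect_equal(tie$p_one_sided, 0.5)
  expect_equal(tie$p_two_sided, 1)

  hi <- r1; hi$sims <- rep(0.9, 999); hi$median <- 0.9
  lo <- r2; lo$sims <- rep(0.4, 999); lo$median <- 0.4
  sep <- compare_dates(hi, lo)
  expect_equal(sep$p_one_sided, 1)
  expect_equal(sep$p_two_sided, 0)
  expect_equal(sep$median_difference, 0.5)

  r2$scope <- ni_scope(units = "elsewhere")
  expect_error(compare_dates(r1, r2), "different scopes")
})

test_that("trend series preserves length and flags undocumented dates", {
  ds <- make_constant_dataset(0.5, dates = 2000L)
  ds2 <- ni_dataset(ds$records, ds$references, ds$meta, ds$units,
                    dates = c(2000L, 2010L))
  scaled <- scale_dataset(draw_replicates(fit_dataset(ds2), 49, 1), ds2)
  tr <- trend_series(scaled, ds2)
  expect_length(tr, 2)
  df <- as.data.frame(tr)
  expect_false(df$gap[1])
  expect_true(df$gap[2])
  expect_equal(df$median[1], 0.5)
  expect_true(is.na(df$median[2]))
  one <- trend_series(scaled, ds2, dates = 2000L)
  expect_length(one, 1)
})

test_that("unit selection by ecosystem share follows the area threshold", {
  units <- data.frame(unit_id = c("a", "b", "c"),
                      ecosystem_id = "mountain",
                      total_area = c(100, 100, 100),
                      ecosystem_area = c(19.9, 20, 100))
  expect_equal(mountain_filter(units, "mountain", 0.2), c("b", "c"))
  expect_equal(mountain_filter(units, "mountain", 0), c("a", "b", "c"))
  expect_equal(mountain_filter(units, "mountain", 1), "c")
  expect_error(mountain_filter(units, "mountain", 1.2))
})

test_that("gap statistics match a hand count", {
  ds <- make_toy_dataset()
  # mountain ecosystem: 1 expert record in u1, 1 in u2, both units present
  gaps <- gap_statistics(ds)
  md <- gaps$mean_documented
  get <- function(eco, src) md$mean_count[md$ecosystem_id == eco &
                                            md$source == src]
  expect_equal(get("mountain", "expert"), 1)     # (1 + 1) / 2 units
  expect_equal(get("forest", "monitoring"), 0.5) # (1 + 0) / 2 units
  expect_equal(get("forest", "expert"), 0)
  es <- gaps$expert_share
  expect_equal(es$expert_pct[es$ecosystem_id == "mountain"], 100)
  expect_equal(es$expert_pct[es$ecosystem_id == "forest"], 0)

  # two units with 3 and 5 documented expert indicators -> mean 4
  ids <- sprintf("x%d", 1:5)
  units <- data.frame(unit_id = c("u1", "u2"), ecosystem_id = "eco",
                      total_area = 10, ecosystem_area = 10)
  meta <- data.frame(indicator_id = ids, ecosystem_id = "eco",
                     membership = 1, group_id = "g",
                     extra_representative = FALSE)
  refs <- expand.grid(indicator_id = ids, ecosystem_id = "eco",
                      unit_id = c("u1", "u2"), stringsAsFactors = FALSE)
  refs$ref_value <- 1; refs$definition_tag <- "pristine"
  refs$scaling_model <- "minimal"
  rec <- data.frame(indicator_id = c(ids[1:3], ids),
                    ecosystem_id = "eco",
                    unit_id = rep(c("u1", "u2"), c(3, 5)), date = 2010L,
                    mean_value = 1, q25 = 1, q75 = 1, source = "expert",
                    variable_kind = "continuous")
  g2 <- gap_statistics(ni_dataset(rec, refs, meta, units))
  expect_equal(g2$mean_documented$mean_count[
    g2$mean_documented$source == "expert"], 4)
  expect_equal(g2$expert_share$expert_pct, 100)

  # no records at all -> all means zero
  empty <- ni_dataset(rec[0, ], refs, meta, units, dates = 2010L)
  expect_true(all(gap_statistics(empty)$mean_documented$mean_count == 0))
})

test_that("an empty scope fails with an explicit no-documentation signal", {
  ds <- make_toy_dataset()
  scaled <- scale_dataset(draw_replicates(fit_dataset(ds), 9, 1), ds)
  expect_error(compute_index(scaled, ds, ni_scope(units = "u9"), 2010L),
               "no documented indicators")
})
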