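test_that("criterion combines squared deviations symmetrically", {
  expect_equal(criterion_c(0, 0, 0), 0)
  expect_equal(criterion_c(1, 2, 2), 9)
  expect_equal(criterion_c(-1, 0, 0), 1)
  expect_equal(criterion_c(-1, 2, -2), criterion_c(1, -2, 2))
})

test_that("the (2, 1, 3) discrete triple recovers Poisson(2) exactly", {
  # independent check by exact CDF enumeration: type-1 quartiles of
  # Poisson(2) are the smallest k with cumulative mass >= p
  cdf <- cumsum(dpois(0:50, 2))
  expect_equal(which(cdf >= 0.25)[1] - 1, 1)
  expect_equal(which(cdf >= 0.75)[1] - 1, 3)
  fit <- fit_distribution(2, 1, 3, "discrete")
  expect_equal(fit$family, "poisson")
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$C_value, 0)
})

test_that("degenerate elicitations collapse to a point mass", {
  fit <- fit_distribution(7, 7, 7, "continuous")
  expect_equal(fit$family, "point_mass")
  expect_equal(fit$a, 7)
  expect_equal(fit$C_value, 0)
  expect_equal(fit_distribution(3, 3, 3, "discrete")$family, "point_mass")
  expect_equal(fit_distribution(0, 0, 0, "continuous")$a, 0)
  # q25 = q75 != mean is a genuine (if odd) elicitation: fit proceeds
  fit2 <- fit_distribution(10, 8, 8, "continuous")
  expect_false(fit2$family == "point_mass")
  expect_gt(fit2$C_value, 0)
})

test_that("a tight symmetric continuous triple is matched within 1%", {
  fit <- fit_distribution(100, 93.3, 106.7, "continuous")
  expect_equal(100 - fit$m, 100, tolerance = 0.01)         # expectation
  expect_equal(93.3 - fit$q_l, 93.3, tolerance = 0.01)     # fitted q25
  expect_equal(106.7 - fit$q_u, 106.7, tolerance = 0.01)   # fitted q75
  expect_equal(fit$C_value,
               criterion_c(fit$m, fit$q_l, fit$q_u), tolerance = 1e-12)
})

test_that("invalid elicitations are rejected", {
  expect_error(fit_distribution(2, 5, 3, "continuous"), "q25")
  expect_error(fit_distribution(Inf, 1, 2, "continuous"), "finite")
  expect_error(fit_distribution(-1, 0, 1, "continuous"), "non-negative")
})

test_that("continuous fits are scale-equivariant", {
  for (sc in c(0.01, 1, 250)) {
    f1 <- fit_distribution(10, 8.5, 12, "continuous")
    f2 <- fit_distribution(10 * sc, 8.5 * sc, 12 * sc, "continuous")
    expect_equal(f2$family, f1$family)
    expect_equal(f2$C_value, f1$C_value * sc^2, tolerance = 1e-9)
  }
})

test_that("fit_dataset reproduces per-triple fits across a dataset", {
  g <- generate_dataset(ni_generator_config(n_units = 3, n_indicators = 3,
                                            dates = c(2000L, 2010L),
                                            seed = 11))
  fits <- fit_dataset(g$dataset)
  expect_equal(nrow(fits), nrow(g$dataset$records))
  i <- which(is.na(fits$duplication_group))[1]
  rec <- g$dataset$records[i, ]
  direct <- fit_distribution(rec$mean_value, rec$q25, rec$q75,
                             rec$variable_kind)
  expect_equal(fits$family[i], direct$family)
  expect_equal(fits$C_value[i], direct$C_value, tolerance = 1e-9)
  expect_equal(fits$a[i], direct$a, tolerance = 1e-9)
})

test_that("replicate draws honor length, point masses and moments", {
  ds <- make_constant_dataset(c(0.5, 1))
  fits <- fit_dataset(ds)
  sims <- draw_replicates(fits, n_sim = 999, seed = 5)
  expect_equal(ncol(sims$values), 999)
  expect_true(all(sims$values[1, ] == 25))  # point mass at 0.5 * 50

  # Poisson(2) sample mean obeys the Monte-Carlo standard-error bound
  pois_fits <- fit_dataset(ni_dataset(
    data.frame(indicator_id = "i1", ecosystem_id = "eco", unit_id = "u1",
               date = 2010L, mean_value = 2, q25 = 1, q75 = 3,
               source = "expert", variable_kind = "discrete"),
    data.frame(indicator_id = "i1", ecosystem_id = "eco", unit_id = "u1",
               ref_value = 5, definition_tag = "pristine",
               scaling_model = "minimal"),
    data.frame(indicator_id = "i1", ecosystem_id = "eco", membership = 1,
               group_id = "g", extra_representative = FALSE),
    data.frame(unit_id = "u1", ecosystem_id = "eco", total_area = 1,
               ecosystem_area = 1)))
  draws <- draw_replicates(pois_fits, n_sim = 5000, seed = 3)$values[1, ]
  expect_lt(abs(mean(draws) - 2), 3 * sqrt(2 / 5000))
  expect_true(all(draws == floor(draws)))
})

test_that("identical seeds give bit-identical draws; seeds isolate cells", {
  # non-degenerate elicitations so draws actually depend on the RNG
  ds0 <- make_toy_dataset()
  rec <- ds0$records
  rec$q25 <- 0.8 * rec$mean_value
  rec$q75 <- 1.25 * rec$mean_value
  ds <- ni_dataset(rec, ds0$references, ds0$meta, ds0$units)
  fits <- fit_dataset(ds)
  s1 <- draw_replicates(fits, n_sim = 200, seed = 42)
  s2 <- draw_replicates(fits, n_sim = 200, seed = 42)
  expect_identical(s1$values, s2$values)
  s3 <- draw_replicates(fits, n_sim = 200, seed = 43)
  expect_false(identical(s1$values, s3$values))
  # adding a cell does not perturb the other cells' substreams
  sub <- ds$records[1:2, ]
  ds_sub <- ni_dataset(sub, ds$references, ds$meta, ds$units)
  s4 <- draw_replicates(fit_dataset(ds_sub), n_sim = 200, seed = 42)
  expect_identical(s4$values, s1$values[rownames(s4$values), ])
})

test_that("cells in a duplication group share one simulated vector", {
  cfg <- ni_generator_config(n_units = 4, n_ecosystems = 1,
                             n_indicators = 3, duplication_prob = 1,
                             missingness_prob = 0, seed = 9)
  ds <- generate_dataset(cfg)$dataset
  expect_true(all(!is.na(ds$records$duplication_group)))
  sims <- draw_replicates(fit_dataset(ds), n_sim = 99, seed = 1)
  for (gkey in unique(sims$cells$duplication_group)) {
    rows <- which(sims$cells$duplication_group == gkey)
    expect_true(all(apply(sims$values[rows, , drop = FALSE], 2,
                          function(col) all(col == col[1]))))
  }
})

test_that("draws from every family are non-negative", {
  triples <- list(c(10, 8, 12), c(3, 1, 4), c(50, 20, 60), c(1, 0.2, 1.5))
  for (tp in triples) {
    for (kind in c("continuous", "discrete")) {
      f <- fit_distribution(tp[1], floor(tp[2] * 10) / 10,
                            ceiling(tp[3]), kind)
      fits <- structure(
        data.frame(indicator_id = "i", ecosystem_id = "e", unit_id = "u",
                   date = 2000L, family = f$family, a = f$a, b = f$b,
                   C_value = f$C_value, m = f$m, q_l = f$q_l, q_u = f$q_u,
                   duplication_group = NA_character_),
        class = c("ni_fits", "data.frame"))
      v <- draw_replicates(fits, n_sim = 500, seed = 8)$values
      expect_true(all(v >= 0))
    }
  }
})
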