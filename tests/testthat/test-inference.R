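test_that("cumulative odds reproduce the clinical worked examples", {
  expect_equal(cumulative_odds(0.75, 4)$phrased_fold, 3.2)
  expect_equal(cumulative_odds(1.21, 4)$phrased_fold, 2.1)
  # 1.31^4 = 2.9453 rounds to 2.9; the published 3.0 requires the
  # pre-rounding coefficient (any OR in [1.311, 1.315] yields 3.0)
  expect_equal(cumulative_odds(1.31, 4)$phrased_fold, 2.9)
  expect_equal(cumulative_odds(1.3125, 4)$phrased_fold, 3.0)
  expect_equal(cumulative_odds(2, 0)$fold_change, 1)
  expect_error(cumulative_odds(0.75, -1), "k_points")
  expect_error(cumulative_odds(-1, 2), "positive")
})

test_that("cumulative odds are multiplicative in the point difference", {
  for (or in c(0.6, 0.75, 1.21, 2.3)) {
    for (ab in list(c(1, 3), c(2, 2), c(0, 4))) {
      expect_equal(
        cumulative_odds(or, sum(ab))$fold_change,
        cumulative_odds(or, ab[1])$fold_change * cumulative_odds(or, ab[2])$fold_change,
        tolerance = 1e-12
      )
    }
  }
})

test_that("percent odds change matches the reporting convention", {
  expect_equal(percent_odds_change(0.75), -25)
  expect_equal(percent_odds_change(1.31), 31)
  expect_equal(percent_odds_change(1.21), 21)
  expect_equal(percent_odds_change(1.0), 0)
})

test_that("odds ratios come from the outcome regression; absent edges give OR 1", {
  adj <- matrix(0, 4, 4,
                dimnames = list(c("a", "b", "c", "remission"),
                                c("a", "b", "c", "remission")))
  adj[1, 4] <- adj[4, 1] <- -0.2
  raw <- c(a = -0.2877, b = 0.05, c = 0)  # b retained by neither rule => edge 0
  net <- fake_network(adj, raw_outcome = raw)
  tab <- odds_ratio_table(net)
  expect_equal(tab$per_point_or[tab$item == "a"], 0.75, tolerance = 0.005)
  expect_equal(tab$direction[tab$item == "a"], "negative")
  expect_equal(tab$per_point_or[tab$item == "b"], 1)
  expect_true(is.na(tab$direction[tab$item == "b"]))
  expect_true(all(tab$per_point_or > 0))
})

test_that("a single bootstrap resample gives 0/1 inclusions and degenerate intervals", {
  bs <- suppressWarnings(bootstrap_network(
    cohort5, estimation_config(cv_seed = 3),
    bootstrap_config(n_boot = 1, seed = 5)
  ))
  expect_true(all(bs$inclusion_proportion %in% c(0, 1)))
  expect_equal(bs$weight_low, bs$weight_high)
  expect_equal(bs$n_effective, 1L)
})

test_that("bootstrap summaries are deterministic for a fixed seed", {
  cfg <- estimation_config(cv_seed = 3)
  b1 <- suppressWarnings(bootstrap_network(cohort5, cfg, bootstrap_config(10, seed = 7)))
  b2 <- suppressWarnings(bootstrap_network(cohort5, cfg, bootstrap_config(10, seed = 7)))
  expect_identical(b1$inclusion_proportion, b2$inclusion_proportion)
  expect_identical(b1$weight_low, b2$weight_low)
  expect_identical(b1$or_table, b2$or_table)
  b3 <- suppressWarnings(bootstrap_network(cohort5, cfg, bootstrap_config(10, seed = 8)))
  expect_false(identical(b1$inclusion_proportion, b3$inclusion_proportion))
})

test_that("bootstrap intervals are reported as bCI with the regularization-bias caveat", {
  bs <- suppressWarnings(bootstrap_network(
    cohort5, estimation_config(cv_seed = 3), bootstrap_config(2, seed = 1)
  ))
  expect_output(print(bs), "bCI")
  expect_output(print(bs), "not coverage-valid")
})

test_that("unstable edges have weight intervals containing zero and OR intervals containing one", {
  bs <- suppressWarnings(bootstrap_network(
    cohort5, estimation_config(cv_seed = 3), bootstrap_config(40, seed = 9)
  ))
  span <- (bs$boot_config$percentile_high - bs$boot_config$percentile_low) / 100
  unstable <- bs$inclusion_proportion < span
  expect_true(all(bs$weight_low[unstable] <= 0))
  expect_true(all(bs$weight_high[unstable] >= 0))
  u <- bs$or_table$inclusion_proportion < span
  expect_true(all(bs$or_table$or_low[u] <= 1))
  expect_true(all(bs$or_table$or_high[u] >= 1))
  expect_true(all(bs$or_table$or_low > 0))
  expect_true(all(bs$or_table$or_low <= bs$or_table$or_high))
})
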