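test_that("lambda forced to lambda_max zeroes every coefficient", {
  cfg <- estimation_config(cv_seed = 3)
  # lambda_max for node 1 from a cv fit's grid top
  f_cv <- fit_nodewise(cohort5, 1, cfg)
  lmax <- max(f_cv$cv_error_curve$lambda)
  f <- fit_nodewise(cohort5, 1, cfg, lambda = lmax)
  expect_true(all(f$coefficients == 0))
  expect_equal(f$selected_lambda, lmax)
})

test_that("unregularized nodewise fits match textbook least-squares and logistic fits", {
  cfg <- estimation_config(cv_seed = 3)
  D <- cbind(cohort5$scores, remission = cohort5$outcome)

  f_g <- fit_nodewise(cohort5, 2, cfg, lambda = 0)
  ls <- lm(D[, 2] ~ D[, -2])
  expect_lt(max(abs(f_g$coefficients - coef(ls)[-1])), 1e-4)

  f_b <- fit_nodewise(cohort5, 6, cfg, lambda = 0)
  ml <- glm(D[, 6] ~ D[, -6], family = binomial())
  expect_lt(max(abs(f_b$coefficients - coef(ml)[-1])), 1e-3)
})

test_that("the edge rules combine nodewise coefficients as documented", {
  # 3 nodes; each fit carries std coefficients for the other two, in order
  fits <- list(
    fake_fit("a", c(b = 0.30, c = 0.00)),
    fake_fit("b", c(a = 0.20, c = 0.30)),
    fake_fit("c", c(a = 0.00, b = 0.00))
  )
  and <- combine_edges(fits, "AND")
  expect_equal(and$adjacency["a", "b"], 0.25)   # mean of |0.30| and |0.20|
  expect_equal(and$adjacency["b", "c"], 0)      # c's fit did not retain b
  or <- combine_edges(fits, "OR")
  expect_equal(or$adjacency["b", "c"], 0.15)    # mean over both positions
  expect_equal(or$adjacency["a", "b"], 0.25)

  # conflicting signs: retained at mean magnitude, flagged
  fits2 <- list(
    fake_fit("a", c(b = 0.30)),
    fake_fit("b", c(a = -0.10))
  )
  and2 <- combine_edges(fits2, "AND")
  expect_equal(and2$adjacency["a", "b"], 0.20)
  expect_true(and2$sign_undefined["a", "b"])

  # structural invariants
  net <- suppressWarnings(estimate_network(cohort5, estimation_config(cv_seed = 5)))
  expect_equal(net$adjacency, t(net$adjacency))
  expect_true(all(diag(net$adjacency) == 0))
})

test_that("constant predictors are excluded with a warning; degenerate outcomes error", {
  sc <- scale5
  scores <- cohort5$scores
  scores[, "insight"] <- 1L
  co <- cohort_table(scores, cohort5$outcome, scale = sc)
  expect_warning(fit_nodewise(co, 1, estimation_config(cv_seed = 2)),
                 "constant predictor.*insight")
  co2 <- cohort_table(cohort5$scores, rep(1L, n_patients(cohort5)), scale = sc)
  expect_error(fit_nodewise(co2, 6, estimation_config(cv_seed = 2)),
               "single class")
  expect_error(estimate_network(co2), "outcome classes")
})

test_that("fold assignment and selected penalties are reproducible for a fixed cv seed", {
  cfg <- estimation_config(cv_seed = 17)
  f1 <- fit_nodewise(cohort5, 1, cfg)
  f2 <- fit_nodewise(cohort5, 1, cfg)
  expect_identical(f1$selected_lambda, f2$selected_lambda)
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("retained coefficient count is non-increasing in lambda along the grid", {
  for (node in c(1, 6)) {
    f <- fit_nodewise(cohort5, node, estimation_config(cv_seed = 23))
    curve <- f$cv_error_curve[order(-f$cv_error_curve$lambda), ]
    expect_true(all(diff(curve$n_nonzero) >= 0))
  }
})

test_that("permuting item columns permutes the adjacency identically", {
  perm <- c(3, 1, 5, 2, 4)
  sc_perm <- symptom_scale(scale5$items$label[perm],
                           scale5$items$max_score[perm])
  co_perm <- cohort_table(cohort5$scores[, perm], cohort5$outcome, scale = sc_perm)
  cfg <- estimation_config(cv_seed = 29)
  net <- suppressWarnings(estimate_network(cohort5, cfg))
  net_perm <- suppressWarnings(estimate_network(co_perm, cfg))
  lab <- net$node_labels
  # identical support; weights agree up to the solver's convergence tolerance
  expect_identical(net_perm$adjacency[lab, lab] != 0, net$adjacency != 0)
  expect_equal(net_perm$adjacency[lab, lab], net$adjacency, tolerance = 1e-4)
})

test_that("smallest retained weight is the minimum nonzero edge magnitude", {
  net <- suppressWarnings(estimate_network(cohort5, estimation_config(cv_seed = 5)))
  nz <- abs(net$adjacency[upper.tri(net$adjacency)])
  nz <- nz[nz > 0]
  if (length(nz)) {
    expect_gt(net$smallest_retained_weight, 0)
    expect_equal(net$smallest_retained_weight, min(nz))
  } else {
    expect_true(is.na(net$smallest_retained_weight))
  }
})

test_that("predictability is zero for an empty network and bounded in [0, 1]", {
  cfg <- estimation_config(cv_seed = 31)
  # force an empty model: every nodewise fit at a huge penalty
  fits <- lapply(seq_len(6), function(i) fit_nodewise(cohort5, i, cfg, lambda = 100))
  net <- suppressWarnings(estimate_network(cohort5, cfg))
  empty <- net
  empty$nodewise_fits <- fits
  pred0 <- compute_predictability(empty, cohort5)
  expect_true(all(pred0 == 0))

  pred <- compute_predictability(net, cohort5)
  expect_true(all(pred >= 0 & pred <= 1))
})

test_that("a hub node whose neighbors nearly determine it has predictability above 0.95", {
  # star network close to the stability boundary: marginal R^2 of the hub is
  # 16 w^2 = 0.97
  p <- 17
  w <- sqrt(0.97 / 16)
  W <- matrix(0, p, p)
  W[1, 2:p] <- W[2:p, 1] <- w
  m <- generating_model(W)
  co <- sample_cohort(m, scale17,
                      sim_config(1500, seed = 101, burn_in = 500, thinning = 8,
                                 discretize = FALSE))
  net <- suppressWarnings(estimate_network(co, estimation_config(cv_seed = 7)))
  expect_gt(net$predictability[1], 0.95)
})
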