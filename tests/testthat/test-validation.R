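test_that("split plans are reproducible and correctly sized", {
  p1 <- make_split_plan(94, 100, 0.2, seed = 9)
  expect_equal(p1$test_size, 19)                     # round(0.2 * 94)
  expect_identical(p1, make_split_plan(94, 100, 0.2, seed = 9))
  p2 <- make_split_plan(94, 100, 0.2, seed = 10)
  expect_false(identical(p1$test, p2$test))
  expect_true(all(vapply(p1$test, length, integer(1)) == 19))
  expect_true(all(unlist(p1$test) %in% 1:94))
  # each compound is held out about n_cycles * 19 / 94 ~ 20 times
  appearances <- tabulate(unlist(p1$test), 94)
  expect_equal(sum(appearances), 100 * 19)
  expect_equal(mean(appearances), 100 * 19 / 94)
  expect_error(make_split_plan(4, 10, 0.2, seed = 1), ">= 5")
  expect_error(make_split_plan(10, 10, 0.01, seed = 1), "rounds to zero")
  expect_error(make_split_plan(10, 10, 0.2), "seed")
})

test_that("both R^2 conventions behave as documented", {
  expect_equal(compute_r2(1:5, 1:5), 1)
  # perfectly anti-correlated: fit-line R^2 is 1, explained-SS is negative
  expect_equal(compute_r2(c(1, 2, 3), c(3, 2, 1), "pearson_sq"), 1)
  expect_lt(compute_r2(c(1, 2, 3), c(3, 2, 1), "one_minus_ss"), 0)
  expect_error(compute_r2(1:3, c(2, 2, 2)), "observed values are constant")
  expect_error(compute_r2(c(2, 2, 2), 1:3, "pearson_sq"),
               "predicted values are constant")
  expect_error(compute_r2(1:2, 1:2), ">= 3")
  # classical inequality for least-squares in-sample predictions
  set.seed(701)
  for (rep in 1:10) {
    x <- matrix(rnorm(40), 20, 2)
    y <- x %*% c(1, -1) + rnorm(20)
    pred <- lm.fit(cbind(1, x), y)$fitted.values
    expect_lte(compute_r2(pred, y, "one_minus_ss"),
               compute_r2(pred, y, "pearson_sq") + 1e-12)
  }
})

test_that("composite runs are deterministic and conserve hold-out counts", {
  ds <- small_synth(n = 30, noise_sd = 0.3, seed = 402)
  occ <- occupancy_of(ds)
  plan <- make_split_plan(30, 40, 0.2, seed = 5)
  a <- run_composite(occ, ds$activities, plan, pls_engine(4))
  b <- run_composite(occ, ds$activities, plan, pls_engine(4))
  expect_identical(a[setdiff(names(a), "models")],
                   b[setdiff(names(b), "models")])
  expect_identical(a$models, b$models)
  expect_equal(sum(a$times_predicted), 40 * plan$test_size)
  expect_equal(nrow(a$cycles), 40)
  # KNN on the same plan: no training/scrambling columns
  k <- run_composite(occ, ds$activities, plan, knn_engine(3))
  expect_false(any(c("r2_train", "r2_scrambling") %in% names(k$cycles)))
  expect_equal(sum(k$times_predicted), 40 * plan$test_size)
  expect_error(run_composite(occ, ds$activities,
                             make_split_plan(29, 10, 0.2, seed = 1),
                             pls_engine(2)),
               "plan was made for")
})

test_that("scrambling destroys planted signal but tracks pure noise", {
  ds <- small_synth(n = 50, noise_sd = 0, seed = 403)
  occ <- occupancy_of(ds)
  plan <- make_split_plan(50, 40, 0.2, seed = 6)
  cp <- run_composite(occ, ds$activities, plan, pls_engine(7),
                      keep_models = FALSE)
  expect_gt(cp$summary$r2_test_mean, cp$summary$r2_scrambling_mean)
  # pure-noise activities: test and scrambling R^2 are indistinguishable
  noise_y <- with(list(), {set.seed(77); rnorm(50, 6)})
  names(noise_y) <- names(ds$activities)
  cn <- suppressMessages(run_composite(occ, noise_y, plan, pls_engine(7),
                                       keep_models = FALSE))
  expect_lt(abs(cn$summary$r2_test_mean - cn$summary$r2_scrambling_mean),
            0.05)
})

test_that("convergence curves are running means at checkpoints", {
  expect_equal(unname(convergence_curve(rep(0.5, 10), c(1, 5, 10))),
               rep(0.5, 3))
  expect_equal(unname(convergence_curve(c(0.4, 0.6), c(1, 2))), c(0.4, 0.5))
  expect_error(convergence_curve(numeric(0), 1), "empty")
  expect_error(convergence_curve(c(0.4, 0.6), 3), "in 1\\..2")
})

test_that("matched-pair analysis quantifies engine orthogonality", {
  plan <- make_split_plan(20, 1000, 0.2, seed = 8)
  set.seed(801)
  ra <- 0.6 + 0.1 * rnorm(1000)
  rb <- 0.6 + 0.1 * rnorm(1000)          # independent sequences
  mp <- matched_pair_analysis(fake_composite(ra, plan),
                              fake_composite(rb, plan))
  # normal theory: ~31.7% of cycles deviate by >= 1 SD from the mean
  expect_gt(mp$n_beyond_1sd / 1000, 0.25)
  expect_lt(mp$n_beyond_1sd / 1000, 0.40)
  expect_lt(abs(mp$cor_matched), 0.1)
  expect_equal(mp$n_beyond_1sd_a_wins + mp$n_beyond_1sd_b_wins,
               mp$n_beyond_1sd)
  # identical members: zero differences, perfect correlation
  self <- matched_pair_analysis(fake_composite(ra, plan),
                                fake_composite(ra, plan))
  expect_equal(self$pairs$delta, rep(0, 1000))
  expect_equal(self$cor_matched, 1)
  # anti-correlated construction
  anti <- matched_pair_analysis(fake_composite(ra, plan),
                                fake_composite(1.2 - ra, plan))
  expect_lt(anti$cor_matched, 0)
  # mismatched plans are rejected
  other <- make_split_plan(20, 1000, 0.2, seed = 9)
  expect_error(matched_pair_analysis(fake_composite(ra, plan),
                                     fake_composite(rb, other)),
               "same split plan")
})

test_that("hyperparameter scans report the best setting per grid", {
  ds <- small_synth(n = 30, noise_sd = 0.2, seed = 405)
  fp <- build_fingerprints(ds$compounds)
  plan <- make_split_plan(30, 15, 0.2, seed = 11)
  one <- scan_hyperparameters(fp, ds$activities, list(grid_spec(10, 2.5)),
                              plan, lv_range = 3, k_range = 4)
  expect_equal(nrow(one), 1)
  expect_equal(one$optimal_lv, 3)
  expect_equal(one$optimal_k, 4)
  expect_error(scan_hyperparameters(fp, ds$activities, list(), plan),
               "empty grid list")
  # signal planted at a coarse grid: that grid outranks a much finer one
  grids <- list(grid_spec(2, 0.5), grid_spec(10, 2.5))
  sc <- scan_hyperparameters(fp, ds$activities, grids, plan,
                             lv_range = c(3, 7), k_range = c(3, 6))
  expect_equal(nrow(sc), 2)
  expect_gt(sc$avg_r2_test_pls[sc$bin_size == "10 ppm x 10 ppm x 2.5 A"],
            sc$avg_r2_test_pls[sc$bin_size == "2 ppm x 2 ppm x 0.5 A"])
  best <- attr(sc, "best")
  expect_equal(best$PLS$bin_size, "10 ppm x 10 ppm x 2.5 A")
  expect_equal(nrow(attr(sc, "pls_scan")), 4)   # 2 grids x 2 LV settings
})
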