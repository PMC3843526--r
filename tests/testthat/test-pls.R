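test_that("standardization z-scores on the fitting rows and replays", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  s <- standardize(x)
  expect_equal(unname(s$x[, "a"]), c(-1, 0, 1))       # sample SD = 1
  expect_equal(unname(s$x[, "b"]), c(0, 0, 0))        # zero-variance rule
  expect_true(s$params$zero_var[["b"]])
  # applying stored params reproduces the fit-time output
  expect_equal(standardize(x, s$params)$x, s$x)
  expect_error(standardize(x[1, , drop = FALSE]), "at least 2 rows")
})

test_that("SIMPLS at full rank reproduces least squares", {
  set.seed(505)
  for (rep in 1:25) {
    m <- sample(8:15, 1); n <- sample(3:6, 1)
    x <- matrix(rnorm(m * n), m, n,
                dimnames = list(NULL, paste0("b", 1:n)))
    y <- rnorm(m)
    fit <- simpls_fit(x, y, n_lv = n)
    # independent oracle: ordinary least squares with intercept
    ols <- lm.fit(cbind(1, x), y)
    expect_lt(max(abs(pls_predict(fit, x) - ols$fitted.values)), 1e-8)
  }
})

test_that("single-column SIMPLS equals the simple-regression slope", {
  set.seed(506)
  x <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "b1"))
  y <- 2 + 3 * x[, 1] + rnorm(20, sd = 0.1)
  fit <- simpls_fit(x, y, 1, scale = FALSE)
  slope <- cov(x[, 1], y) / var(x[, 1])   # analytic simple regression
  expect_equal(unname(fit$coefficients), slope, tolerance = 1e-10)
  expect_equal(pls_predict(fit, x),
               mean(y) + slope * (x[, 1] - mean(x[, 1])),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("constant response yields the null model", {
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("b", 1:3)))
  fit <- simpls_fit(x, rep(4.2, 10), 2)
  expect_equal(unname(fit$coefficients), rep(0, 3))
  expect_equal(pls_predict(fit, x), rep(4.2, 10))
})

test_that("training fit is non-decreasing in the number of LVs", {
  set.seed(507)
  x <- matrix(rpois(15 * 12, 3), 15, 12,
              dimnames = list(NULL, paste0("b", 1:12)))
  y <- rnorm(15)
  r2 <- vapply(1:6, function(a) {
    fit <- simpls_fit(x, y, a)
    compute_r2(pls_predict(fit, x), y, "one_minus_ss")
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("per-LV weights are unit norm and start at the cross-covariance", {
  set.seed(508)
  x <- matrix(rpois(60, 4), 12, 5, dimnames = list(NULL, paste0("b", 1:5)))
  y <- rnorm(12)
  fit <- simpls_fit(x, y, 3)
  expect_equal(unname(colSums(fit$weights^2)), rep(1, fit$n_lv))
  w1 <- extract_lv_weights(fit, 1)
  # first weight vector is proportional to X'y on the standardized scale
  z <- standardize(x)$x
  s <- crossprod(z, y - mean(y))
  expect_equal(unname(w1), unname(s[, 1] / sqrt(sum(s^2))), tolerance = 1e-10)
  expect_named(w1, paste0("b", 1:5))
  expect_error(extract_lv_weights(fit, fit$n_lv + 1), "must be in 1\\..")
  # determinism: identical refit
  expect_identical(fit$weights, simpls_fit(x, y, 3)$weights)
})

test_that("excess LVs truncate with a warning", {
  set.seed(509)
  x <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, paste0("b", 1:3)))
  y <- rnorm(4)
  expect_warning(fit <- simpls_fit(x, y, 8), "truncated")
  expect_lte(fit$n_lv, 3)
})

test_that("prediction aligns columns by bin label", {
  set.seed(510)
  x <- matrix(rpois(48, 3), 12, 4,
              dimnames = list(NULL, c("1_1_1", "1_2_1", "2_2_3", "4_4_1")))
  y <- rnorm(12)
  fit <- simpls_fit(x, y, 2)
  base <- pls_predict(fit, x)
  # permuting columns changes nothing: labels travel with columns
  perm <- x[, c(3, 1, 4, 2)]
  expect_equal(pls_predict(fit, perm), base)
  # unseen bins are dropped, missing training bins imputed as 0
  extra <- cbind(x[, c(1, 3)], `9_9_9` = 5L)
  manual <- x; manual[, c(2, 4)] <- 0L
  expect_equal(pls_predict(fit, extra), pls_predict(fit, manual))
  # no overlapping bins at all is an error
  none <- matrix(1L, 2, 2, dimnames = list(NULL, c("7_7_7", "8_8_8")))
  expect_error(pls_predict(fit, none), "no overlap")
})

test_that("model serialization is self-describing JSON", {
  set.seed(511)
  x <- matrix(rpois(40, 2), 10, 4, dimnames = list(NULL, paste0("b", 1:4)))
  y <- rnorm(10)
  fit <- simpls_fit(x, y, 2)
  f <- tempfile(fileext = ".json")
  write_pls_model(fit, f)
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(doc$type, "sdar_pls")
  expect_equal(doc$bin_labels, fit$bin_labels)
  expect_equal(doc$coefficients, unname(fit$coefficients), tolerance = 1e-12)
  expect_equal(doc$y_mean, fit$y_mean, tolerance = 1e-12)
})
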