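test_that("OLS fit matches the normal-equations oracle", {
  tab <- random_fixture(n = 30, p = 3, seed = 7)
  m <- fit_ols(tab, c("x1", "x2", "x3"))
  o <- oracle_ols(as.matrix(tab[c("x1", "x2", "x3")]), tab$error_abs)
  expect_equal(unname(m$coefficients), o$beta, tolerance = 1e-8)
  expect_equal(m$rss, o$rss, tolerance = 1e-8)
  expect_equal(m$loglik, o$loglik, tolerance = 1e-8)
  expect_equal(bic(m), oracle_bic(o$loglik, 30, 3), tolerance = 1e-8)
})

test_that("intercept-only fit returns the mean with zero adjusted R2", {
  tab <- random_fixture(n = 25, seed = 3)
  m <- fit_ols(tab, character(0))
  expect_equal(unname(m$coefficients), mean(tab$error_abs))
  expect_equal(m$adj_r2, 0)
  expect_equal(m$d, 0L)
})

test_that("perfect fits keep intervals but refuse a log-likelihood", {
  tab <- tibble::tibble(x1 = 1:10, error_abs = 2 + 0.5 * (1:10))
  m <- fit_ols(tab, "x1")
  expect_true(m$degenerate_rss)
  expect_error(bic(m), "RSS = 0")
  pi <- predict_interval(m, tibble::tibble(x1 = 30))
  expect_equal(pi$upper, pi$point, tolerance = 1e-8)   # s^2 = 0: zero width
  expect_equal(pi$point, 17)
  mf <- fit_ols(tab, "x1", rss_floor = TRUE)
  expect_true(is.finite(bic(mf)))
})

test_that("aliased columns are dropped and flagged at prediction time", {
  tab <- random_fixture(n = 30, p = 2, seed = 11)
  tab$x3 <- 0                      # constant zero column, e.g. an absent level
  expect_warning(m <- fit_ols(tab, c("x1", "x2", "x3")), "aliased")
  expect_equal(m$dropped, "x3")
  pi <- predict_interval(m, tibble::tibble(x1 = 0, x2 = 0, x3 = c(0, 1)))
  expect_equal(pi$flag_unmodeled, c(FALSE, TRUE))
})

test_that("prediction intervals match the closed-form oracle and its geometry", {
  tab <- random_fixture(n = 5, p = 1, seed = 13)
  m <- fit_ols(tab, "x1")
  o <- oracle_ols(as.matrix(tab["x1"]), tab$error_abs)
  for (x0 in c(-1, 0, 2.5)) {
    for (side in c("upper", "two_sided")) {
      got <- predict_interval(m, tibble::tibble(x1 = x0), side = side)
      want <- oracle_pi(o, x0, side = side)
      expect_equal(got$point, unname(want["point"]), tolerance = 1e-8)
      expect_equal(got$lower, unname(want["lower"]), tolerance = 1e-8)
      expect_equal(got$upper, unname(want["upper"]), tolerance = 1e-8)
    }
  }
  # nesting in the level
  pi90 <- predict_interval(m, tibble::tibble(x1 = 1), level = 0.90)
  pi99 <- predict_interval(m, tibble::tibble(x1 = 1), level = 0.99)
  expect_lt(pi99$lower, pi90$lower)
  expect_gt(pi99$upper, pi90$upper)
  # monotone widening with leverage
  centroid <- mean(tab$x1)
  w <- function(x0) {
    p <- predict_interval(m, tibble::tibble(x1 = x0))
    p$upper - p$lower
  }
  expect_lt(w(centroid), w(centroid + 2))
  expect_lt(w(centroid + 2), w(centroid + 4))
  expect_error(predict_interval(m, tibble::tibble(x1 = 1), level = 1.2), "level")
  expect_error(predict_interval(m, tibble::tibble(z = 1)), "lacks predictor")
})

test_that("BIC penalty and convention behave as documented", {
  # equal log-likelihood, d = 3 vs d = 5, n = 100: difference is 2 ln(100)
  expect_equal(oracle_bic(-50, 100, 5) - oracle_bic(-50, 100, 3), 2 * log(100))
  tab <- random_fixture(n = 40, p = 4, seed = 17)
  m_small <- fit_ols(tab, c("x1", "x2"))
  m_big <- fit_ols(tab, c("x1", "x2", "x3", "x4"))
  # convention shift is constant at fixed n: rankings are invariant
  expect_equal(bic(m_small, "plus_intercept") - bic(m_small), log(40))
  expect_equal(sign(bic(m_big) - bic(m_small)),
               sign(bic(m_big, "plus_intercept") - bic(m_small, "plus_intercept")))
})

test_that("interval-width effects follow the decile-contrast definition", {
  tab <- random_fixture(n = 60, p = 3, seed = 19)
  m <- fit_ols(tab, c("x1", "x2", "x3"))
  # independent application of the contrast definition
  v <- tab$x1
  hi <- mean(v[v >= quantile(v, 0.9)])
  lo <- mean(v[v <= quantile(v, 0.1)])
  base <- vapply(tab[c("x1", "x2", "x3")], mean, numeric(1))
  row_at <- function(x1) tibble::tibble(x1 = x1, x2 = base["x2"], x3 = base["x3"])
  want <- predict_interval(m, row_at(hi))$upper - predict_interval(m, row_at(lo))$upper
  expect_equal(effect_on_interval_width(m, tab, "x1"), want, tolerance = 1e-10)

  # binary predictors contrast 1 vs 0
  tab$flag <- rep(c(0, 1), 30)
  m2 <- fit_ols(tab, c("x1", "flag"))
  b_hi <- predict_interval(m2, tibble::tibble(x1 = mean(tab$x1), flag = 1))$upper
  b_lo <- predict_interval(m2, tibble::tibble(x1 = mean(tab$x1), flag = 0))$upper
  expect_equal(effect_on_interval_width(m2, tab, "flag"), b_hi - b_lo)

  tab$const <- 1
  expect_warning(m3 <- fit_ols(tab, c("x1", "const")), "aliased")
  expect_error(effect_on_interval_width(m, tab, "x9"), "not in model")
})

test_that("tidy and glance expose the coefficient table and fit summaries", {
  tab <- random_fixture(n = 30, p = 2, seed = 23)
  m <- fit_ols(tab, c("x1", "x2"))
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "x1", "x2"))
  expect_true(all(c("estimate", "p.value") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n, 30)
  expect_equal(gl$BIC, bic(m))
})
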