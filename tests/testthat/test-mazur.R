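# Hyperbolic discounting fits, exclusion rule and transforms.

delays5 <- c(1, 7, 30, 60, 180)

test_that("hyperbolic value function evaluates and validates", {
  expect_equal(mazur_value(50, 0, 100), 50)
  expect_equal(mazur_value(50, 0.01, 100), 25)
  expect_equal(mazur_value(1, 1, 1), 0.5)
  expect_error(mazur_value(50, -0.1, 10), "k")
  expect_error(mazur_value(50, 0.1, -1), "delayDays")
})

test_that("exact hyperbolic data are recovered to optimizer precision", {
  cv <- indifference_curve(delays5, mazur_value(50, 0.1, delays5), 50)
  fit <- fit_hyperbolic(cv)
  expect_lt(abs(fit$k - 0.1), 1e-6)
  expect_equal(fit$rSquared, 1, tolerance = 1e-9)
  expect_true(fit$included)
  expect_equal(unname(coef(fit)), fit$k)
  expect_equal(predict(fit, 100), 50 / (1 + fit$k * 100), tolerance = 1e-6)
  expect_equal(sum(abs(residuals(fit))), 0, tolerance = 1e-6)
})

test_that("a constant curve at the anchor is the k = 0 hyperbola", {
  cv <- indifference_curve(delays5, rep(50, 5), 50)
  fit <- fit_hyperbolic(cv)
  expect_equal(fit$k, 0)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$rSquared))
  expect_true(fit$included)
  # constant curve below the anchor cannot be an exact hyperbola
  low <- fit_hyperbolic(indifference_curve(delays5, rep(20, 5), 50))
  expect_true(low$degenerate)
  expect_false(low$included)
})

test_that("fits require at least three points", {
  expect_error(fit_hyperbolic(indifference_curve(c(1, 7), c(40, 30), 50)),
               "at least 3")
})

test_that("the fitted k is invariant to the commodity's unit scale", {
  set.seed(42)
  ips <- pmax(pmin(mazur_value(50, 0.07, delays5) * (1 + rnorm(5, 0, 0.1)),
                   50), 0)
  k1 <- fit_hyperbolic(indifference_curve(delays5, ips, 50))$k
  k3 <- fit_hyperbolic(indifference_curve(delays5, ips * 3, 150))$k
  expect_equal(k1, k3, tolerance = 1e-9)
})

test_that("the multi-start fitter matches a dense grid-search oracle", {
  set.seed(11)
  for (i in 1:20) {
    kt <- exp(runif(1, log(0.003), log(0.6)))
    ips <- pmax(pmin(mazur_value(50, kt, delays5) * (1 + rnorm(5, 0, 0.15)),
                     50), 0)
    fit <- fit_hyperbolic(indifference_curve(delays5, ips, 50))
    oracle <- grid_oracle(function(k) sum((ips / 50 - 1 / (1 + k * delays5))^2))
    expect_lt(abs(fit$k - oracle), 1e-3)
  }
})

test_that("larger generating k lowers fitted subjective value at any delay", {
  vals <- vapply(c(0.01, 0.05, 0.2, 0.5), function(kt) {
    cv <- indifference_curve(delays5, mazur_value(50, kt, delays5), 50)
    predict(fit_hyperbolic(cv), 30)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("poor fits are excluded strictly below the threshold", {
  mk <- function(r2) {
    f <- fit_hyperbolic(indifference_curve(delays5,
                                           mazur_value(50, 0.1, delays5), 50))
    f$rSquared <- r2
    f$included <- r2 >= 0.7
    f
  }
  part <- apply_exclusion(list(mk(0.69), mk(0.70), mk(0.95)))
  expect_equal(nrow(part$retained), 2)
  expect_equal(nrow(part$removed), 1)
  expect_equal(part$removed$rSquared, 0.69)
  empty <- apply_exclusion(list())
  expect_equal(nrow(empty$retained), 0)
  expect_equal(nrow(empty$removed), 0)
})

test_that("pre-statistics transforms are log and square with validation", {
  expect_equal(transform_for_stats(1, "logK"), 0)
  expect_equal(transform_for_stats(c(1, exp(2)), "logK"), c(0, 2))
  expect_equal(transform_for_stats(10, "rpeSquare"), 100)
  expect_error(transform_for_stats(c(1, 0, 2), "logK"), "position 2")
})
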