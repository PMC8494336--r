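# Shared-k effort valuation and the exact sign test.

# small synthetic condition: heterogeneous costs and rewards
effort_obs <- function(k = 0.204, deltaM = 0, n = 48) {
  cost <- seq(7, 15, length.out = n)
  reward <- seq(0.8, 1.3, length.out = n)
  data.frame(vp = (reward + deltaM) / (1 + k * cost),
             cost = cost, reward = reward)
}

test_that("Feeling Scale ratings normalise by the scale maximum", {
  expect_equal(normalize_fs(4.27), 0.854)
  expect_equal(normalize_fs(5), 1)
  expect_equal(normalize_fs(0), 0)
  expect_equal(normalize_fs(-5), -1)
  expect_error(normalize_fs(5.5), "\\[-5, 5\\]")
})

test_that("the fitness-to-reward mapping is the documented ratio", {
  expect_equal(map_reward(20, 20, 0), 1)
  expect_equal(map_reward(20, 22, 0), 1.1)
  expect_equal(map_reward(20, 20, 0.2), 1.2)
  expect_error(map_reward(-1, 20), "positive")
  expect_error(map_reward(20, 20, mapping = "affine"), "unknown")
})

test_that("noise-free data generated at k = 0.204 are recovered exactly", {
  fit <- fit_shared_k(effort_obs(0.204))
  expect_lt(abs(fit$k - 0.204), 1e-4)
  # prediction identity holds to machine precision
  expect_lt(max(abs(fit$vpModel -
                      fit$data$reward / (1 + fit$k * fit$data$cost))), 1e-12)
})

test_that("k = 0 data give back the reward as the prediction", {
  fit <- fit_shared_k(effort_obs(0))
  expect_lt(fit$k, 1e-8)
  expect_equal(fit$vpModel, fit$data$reward, tolerance = 1e-8)
})

test_that("an unmodeled reward surplus drags the fitted k down monotonically", {
  ks <- vapply(seq(0, 0.5, by = 0.1), function(dm) {
    fit_shared_k(effort_obs(0.204, deltaM = dm))$k
  }, numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_lt(ks[length(ks)], ks[1])
})

test_that("the shared-k fitter matches a dense grid-search oracle on noisy data", {
  set.seed(23)
  for (i in 1:20) {
    obs <- effort_obs(exp(runif(1, log(0.02), log(0.8))), n = 30)
    obs$vp <- obs$vp * (1 + rnorm(30, 0, 0.1))
    fit <- fit_shared_k(obs)
    oracle <- grid_oracle(
      function(k) sum((obs$vp - obs$reward / (1 + k * obs$cost))^2),
      grid = seq(0, 2, by = 1e-4))
    expect_lt(abs(fit$k - oracle), 1e-3)
  }
})

test_that("degenerate inputs are flagged, not hidden", {
  obs <- data.frame(vp = c(0.5, 0.6), cost = c(10, 10), reward = c(1, 1))
  fit <- fit_shared_k(obs)
  expect_true(fit$flatObjective)
  expect_error(fit_shared_k(obs[1, ]), "at least 2")
  expect_error(fit_shared_k(data.frame(vp = 1, cost = 1)), "columns")
})

test_that("the exact sign test matches hand values and handles zeros", {
  expect_equal(sign_test(rep(0, 5))$pValue, 1)
  expect_equal(sign_test(rep(0, 5))$nonZeroPairs, 0)
  st <- sign_test(c(1, 2, 0.5, 3, 1, 2))
  expect_equal(st$pValue, 0.03125)
  expect_equal(st$statistic, 6)
  mixed <- sign_test(c(1, -1, 2, 0, 3))
  expect_equal(mixed$zerosDropped, 1)
  expect_equal(mixed$nonZeroPairs, 4)
  expect_error(sign_test(numeric(0)), "non-empty")
})

test_that("the sign test equals full enumeration for n <= 10", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(1:10, 1)
    diffs <- round(rnorm(n), 2)
    expect_equal(sign_test(diffs)$pValue, enumerate_sign_p(diffs),
                 tolerance = 1e-12)
  }
})

test_that("effort observations map trials onto model quantities", {
  co <- make_cohort(20, seed = 2)
  tr <- simulate_trials(co, seed = 3)
  obs <- effort_observations(tr, co)
  expect_equal(nrow(obs), nrow(tr))
  expect_true(all(obs$vp >= -1 & obs$vp <= 1))
  expect_true(all(obs$cost >= 6 & obs$cost <= 20))
  expect_true(all(obs$reward > 0))
  expect_equal(obs$vp, tr$fs / 5)
  expect_false(is.null(attr(obs, "refHrPerSpeed")))
})
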