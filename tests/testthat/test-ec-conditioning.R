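# Evaluative-conditioning controller, schedule and session simulation.

test_that("age-predicted maximal heart rate is 220 - age with range warning", {
  expect_equal(hr_max(20), 200)
  expect_equal(hr_max(24), 196)
  expect_equal(hr_max(50), 170)
  expect_warning(hr_max(55), "220 - age")
  expect_error(hr_max("twenty"), "numeric")
})

test_that("sweet rate follows the quadratic admixture law with clamping", {
  # endpoints: neutral at baseline, fully sweet at 85% of HRmax
  expect_equal(sweet_rate(120, 120, 200, 2), 0)
  expect_equal(sweet_rate(170, 120, 200, 2), 2)
  # hand evaluation between the endpoints: (25/50)^2 * 2
  expect_equal(sweet_rate(145, 120, 200, 2), 0.5)
  # clamped outside the operating band
  expect_equal(sweet_rate(80, 120, 200, 2), 0)
  expect_equal(sweet_rate(210, 120, 200, 2), 2)
  # exactly quadratic inside: doubling the elevation quadruples the rate
  h <- 7
  expect_equal(sweet_rate(120 + 2 * h, 120, 200, 2) /
                 sweet_rate(120 + h, 120, 200, 2), 4)
  # non-decreasing over the whole band
  hr <- seq(100, 180, by = 0.5)
  expect_true(all(diff(sweet_rate(hr, 120, 200, 2)) >= 0))
  # degenerate configuration rejected
  expect_error(sweet_rate(150, 175, 200, 2), "degenerate")
})

test_that("session schedule has six ramped cycles from 60 to 85% HRmax", {
  sch <- build_session_schedule()
  expect_s3_class(sch, "session_schedule")
  expect_equal(nrow(sch$cycles), 6)
  expect_equal(sch$cycles$targetPctHRmax, c(60, 65, 70, 75, 80, 85))
  expect_true(all(sch$cycles$holdSec == 120))
  expect_true(all(sch$cycles$baselineSec == 90))
  expect_true(all(sch$cycles$rampUpSec == 10))
})

test_that("simulated sessions conserve flow and log one pairing per cycle", {
  prof <- test_profile()
  ses <- simulate_session(prof, controllerOn = TRUE, seed = 4)
  expect_equal(max(abs(ses$commands$neutralRate + ses$commands$sweetRate - 2)),
               0)
  expect_true(all(ses$commands$sweetRate >= 0 & ses$commands$neutralRate >= 0))
  expect_equal(nrow(ses$pairings), 6)
  expect_true(all(ses$pairings$peakSweetFraction >= 0 &
                    ses$pairings$peakSweetFraction <= 1))
  # sweetness saturates in the 85% cycle (noise-free trace holds target)
  ses0 <- simulate_session(prof, controllerOn = TRUE, seed = 1, noise = FALSE)
  expect_equal(nrow(ses0$pairings), 6)
  expect_gt(ses0$pairings$peakSweetFraction[6], 0.9)
  expect_true(all(diff(ses0$pairings$peakSweetFraction) > 0))
})

test_that("controller off delivers only neutral solution", {
  ses <- simulate_session(test_profile(), controllerOn = FALSE, seed = 2)
  expect_true(all(ses$commands$sweetRate == 0))
  expect_true(all(ses$commands$neutralRate == 2))
  expect_equal(nrow(ses$pairings), 0)
})

test_that("session simulation is a pure function of its seed", {
  prof <- test_profile()
  a <- simulate_session(prof, seed = 11)
  b <- simulate_session(prof, seed = 11)
  c <- simulate_session(prof, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$trace$hr, c$trace$hr))
})

test_that("the standard three-week plan accumulates 54 pairings", {
  expect_equal(count_pairings(3, 3, 6), 54)
  expect_equal(count_pairings(3, 1, 6), 18)
  expect_equal(count_pairings(0, 3, 6), 0)
  expect_error(count_pairings(1.5, 3, 6), "integer")
  plan <- simulate_training_plan(test_profile(), sessions = 9, seed = 8)
  expect_equal(nrow(plan), 54)
  expect_equal(sort(unique(plan$sessionIndex)), 1:9)
})
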