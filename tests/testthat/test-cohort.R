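# Synthetic cohort generator: profiles, trial records, choices.

test_that("cohorts honour size, arm split and seeded determinism", {
  co <- make_cohort(58, c(NTR = 10, TR = 24, COTR = 24) / 58, seed = 1)
  expect_equal(nrow(co), 58)
  expect_equal(as.vector(table(co$group)[c("NTR", "TR", "COTR")]),
               c(10, 24, 24))
  expect_identical(make_cohort(48, seed = 7), make_cohort(48, seed = 7))
  expect_false(identical(make_cohort(48, seed = 7),
                         make_cohort(48, seed = 8)))
  expect_error(make_cohort(0), "outside")
  expect_error(make_cohort(10, c(NTR = 0.5, TR = 0.2, COTR = 0.2)),
               "summing to 1")
  expect_error(make_cohort(10, c(0.2, 0.4, 0.4)), "named")
})

test_that("latent profiles satisfy their invariants", {
  co <- make_cohort(120, seed = 3)
  expect_equal(co$hrMax, 220 - co$age)
  expect_true(all(co$kMoney > 0 & co$kFood > 0 & co$kExercise > 0 &
                    co$kEffort > 0))
  expect_true(all(co$conditioningDeltaM[co$group != "COTR"] == 0))
  expect_true(all(co$conditioningDeltaM[co$group == "COTR"] > 0))
  expect_true(all(co$trainingGain[co$group == "NTR"] == 0))
  expect_true(all(co$baselineHR < 0.85 * co$hrMax))
  # trained fitness is strictly better (fewer beats per km/h) at T1
  tr <- co[co$trainingGain > 0, ]
  expect_true(all(hr_per_speed(tr, "T1") < tr$hrPerSpeed0))
})

test_that("training raises the noise-free selected speed; detraining undoes it", {
  prof <- test_profile(trainingGain = 0.1)
  s0 <- simulate_trial_record(prof, "T0", noise = FALSE)$speed
  s1 <- simulate_trial_record(prof, "T1", noise = FALSE)$speed
  expect_gt(s1, s0)
  full <- test_profile(trainingGain = 0.1, detrainFraction = 1)
  expect_equal(simulate_trial_record(full, "T2", noise = FALSE)$speed,
               simulate_trial_record(full, "T0", noise = FALSE)$speed)
  expect_error(simulate_trial_record(prof, "T9"), "timePoint")
})

test_that("noise-free speed is monotone in fitness gain and conditioned reward", {
  s_gain <- vapply(seq(0, 0.2, by = 0.04), function(g) {
    simulate_trial_record(test_profile(trainingGain = g), "T1",
                          noise = FALSE)$speed
  }, numeric(1))
  expect_true(all(diff(s_gain) >= 0))
  s_dm <- vapply(seq(0, 0.5, by = 0.1), function(dm) {
    simulate_trial_record(test_profile(group = "COTR",
                                       conditioningDeltaM = dm),
                          "T2", noise = FALSE)$speed
  }, numeric(1))
  expect_true(all(diff(s_dm) >= 0))
  expect_gt(s_dm[length(s_dm)], s_dm[1])
})

test_that("trial records stay on their rating scales", {
  co <- make_cohort(30, seed = 9)
  tr <- simulate_trials(co, seed = 10)
  expect_true(all(tr$rpe >= 6 & tr$rpe <= 20))
  expect_true(all(tr$fs >= -5 & tr$fs <= 5))
  expect_true(all(tr$speed > 0))
  expect_true(all(tr$avgHR > 40 &
                    tr$avgHR <= co$hrMax[match(tr$participantId, co$id)]))
  # no-training arm is not assessed at follow-up
  ntr <- tr[tr$participantId %in% co$id[co$group == "NTR"], ]
  expect_false("T2" %in% ntr$timePoint)
})

test_that("baseline selected speed matches the calibrated study conditions", {
  # the generator is calibrated to a baseline preferred-speed mean of
  # ~5.25 km/h (SD ~1.27); check the simulated mean against a 2-SE band
  cfg <- default_config()
  co <- make_cohort(200, c(NTR = 0, TR = 1, COTR = 0), cfg, seed = 21)
  sp <- vapply(seq_len(200), function(i) {
    simulate_trial_record(co[i, ], "T0", cfg, seed = 500 + i)$speed
  }, numeric(1))
  expect_lt(abs(mean(sp) - 5.25), 2 * 1.27 / sqrt(200) + 0.1)
  expect_lt(abs(sd(sp) - 1.27), 0.5)
})

test_that("deterministic choices follow the hyperbolic argmax", {
  prof <- test_profile(kMoney = 0)
  trial <- list(commodity = "money", immediateAmount = 20,
                delayedAmount = 50, delayDays = 180)
  expect_equal(simulate_choice(prof, trial, seed = 1), "delayed")
  # 50 / (1 + 0.01 * 180) = 17.86 < 20
  prof$kMoney <- 0.01
  expect_equal(simulate_choice(prof, trial, seed = 1), "immediate")
  # exact tie: seeded fair coin, both outcomes reachable
  tie <- list(commodity = "money", immediateAmount = 25,
              delayedAmount = 50, delayDays = 100)
  ch <- vapply(1:40, function(s) simulate_choice(prof, tie, seed = s),
               character(1))
  expect_setequal(unique(ch), c("immediate", "delayed"))
  expect_error(simulate_choice(prof, list(commodity = "money",
                                          immediateAmount = 60,
                                          delayedAmount = 50,
                                          delayDays = 1)),
               "delayedAmount")
})

test_that("noisy choice rates match the closed-form logistic probability", {
  prof <- test_profile(kMoney = 0.02, choiceNoise = 0.5)
  trial <- list(commodity = "money", immediateAmount = 12,
                delayedAmount = 50, delayDays = 180)
  vDel <- 50 / (1 + 0.02 * 180)
  p <- plogis((12 - vDel) / 0.5)
  hits <- vapply(1:10000, function(s) {
    simulate_choice(prof, trial, seed = s) == "immediate"
  }, logical(1))
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(hits) - p), 2 * se + 0.005)
})
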