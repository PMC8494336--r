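# Synthetic cohort generator: latent participant traits and observable
# self-paced exercise trials, with the statistical structure the downstream
# fits assume, so every stage has ground truth for recovery testing.

#' Generate a synthetic participant cohort
#'
#' Draws \code{n} latent participant profiles split across the three study
#' arms (NTR no-training, TR training, COTR conditioning plus training).
#' Discount constants are log-normal (right-skewed, as observed for delay
#' discounting); fitness (heart rate per km/h of treadmill speed) and
#' demographic traits are Gaussian with clamping to physiological ranges.
#' The conditioned-reward increment \code{conditioningDeltaM} is non-zero
#' only in the COTR arm, and training gain is zero in the NTR arm.
#'
#' @param n Number of participants (>= 1).
#' @param groupSplit Named proportions over \code{NTR, TR, COTR} summing
#'   to 1. Counts use largest-remainder rounding so they always total n.
#' @param config Parameter record, see \code{default_config()}.
#' @param seed Integer seed; identical (arguments, seed) give identical
#'   cohorts.
#' @return A data frame with one row per participant: \code{id, group,
#'   age, baselineHR, hrMax, hrPerSpeed0, trainingGain, detrainFraction,
#'   kMoney, kFood, kExercise, kEffort, conditioningDeltaM, choiceNoise,
#'   ratingNoiseSD}.
#' @examples
#' cohort <- make_cohort(12, seed = 1)
#' table(cohort$group)
#' @export
make_cohort <- function(n, groupSplit = default_config()$groupSplit,
                        config = default_config(), seed = NULL) {
  check_number(n, "n", lower = 1)
  if (n != round(n)) stop("`n` must be an integer", call. = FALSE)
  n <- as.integer(n)
  if (is.null(names(groupSplit)) ||
      !setequal(names(groupSplit), study_groups())) {
    stop("`groupSplit` must be named with NTR, TR, COTR", call. = FALSE)
  }
  groupSplit <- groupSplit[study_groups()]
  if (any(groupSplit < 0) || abs(sum(groupSplit) - 1) > 1e-8) {
    stop("`groupSplit` must be non-negative proportions summing to 1",
         call. = FALSE)
  }
  counts <- floor(n * groupSplit)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * groupSplit - counts
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  group <- rep(study_groups(), times = counts)

  with_seed(seed, {
    age <- round(clamp(stats::rnorm(n, config$ageMean, config$ageSD),
                       config$ageMin, config$ageMax))
    hrMax <- hr_max(age)
    hrPerSpeed0 <- clamp(stats::rnorm(n, config$hrPerSpeedMean,
                                      config$hrPerSpeedSD), 12, 35)
    trainingGain <- ifelse(
      group == "NTR", 0,
      clamp(stats::rnorm(n, config$trainingGainMean, config$trainingGainSD),
            0, 0.3))
    detrainFraction <- clamp(stats::rnorm(n, config$detrainFractionMean,
                                          config$detrainFractionSD), 0, 1)
    cohort <- data.frame(
      id = sprintf("P%03d", seq_len(n)),
      group = group,
      age = age,
      baselineHR = NA_real_,
      hrMax = hrMax,
      hrPerSpeed0 = hrPerSpeed0,
      trainingGain = trainingGain,
      detrainFraction = detrainFraction,
      kMoney = stats::rlnorm(n, config$kMoneyMeanlog, config$kMoneySdlog),
      kFood = stats::rlnorm(n, config$kFoodMeanlog, config$kFoodSdlog),
      kExercise = stats::rlnorm(n, config$kExerciseMeanlog,
                                config$kExerciseSdlog),
      kEffort = stats::rlnorm(n, config$kEffortMeanlog, config$kEffortSdlog),
      conditioningDeltaM = ifelse(group == "COTR",
                                  config$conditioningDeltaM, 0),
      choiceNoise = config$choiceNoise,
      ratingNoiseSD = config$ratingNoiseSD,
      stringsAsFactors = FALSE
    )
    # baseline HR is by definition the HR at the self-selected baseline
    # speed, so it is derived from each profile's own noise-free T0
    # optimum (the conditioned-reward term is inactive at T0, so this is
    # not circular); capped below the controller's saturation threshold
    for (i in seq_len(n)) {
      grid <- pleasantness_profile(cohort[i, ], "T0", config)
      cohort$baselineHR[i] <- clamp(grid$hr[which.max(grid$vp)],
                                    60, 0.8 * cohort$hrMax[i])
    }
    cohort
  })
}

#' Heart rate per km/h at a study time point
#'
#' Training improves cardiovascular efficiency, reducing the heart-rate
#' cost of speed by the profile's \code{trainingGain} at post-training
#' (T1); by follow-up (T2) a share \code{detrainFraction} of that gain is
#' lost again.
#'
#' @param profile Participant profile row(s) from \code{make_cohort}
#'   (vectorised over rows).
#' @param timePoint One of \code{"T0"}, \code{"T1"}, \code{"T2"}.
#' @return Heart rate per speed in bpm per km/h.
#' @export
hr_per_speed <- function(profile, timePoint) {
  check_time_point(timePoint)
  g <- profile$trainingGain
  switch(timePoint,
         T0 = profile$hrPerSpeed0,
         T1 = profile$hrPerSpeed0 * (1 - g),
         T2 = profile$hrPerSpeed0 * (1 - g * (1 - profile$detrainFraction)))
}

# expected Borg RPE (6-20) as an affine function of the heart-rate fraction
# between rest and maximum
expected_rpe <- function(hr, hrMax, restHR = 60) {
  6 + 14 * clamp((hr - restHR) / (hrMax - restHR), 0, 1)
}

# latent effort cost on the RPE scale: affine in the heart-rate fraction,
# clamped below at rest but NOT above, so supra-maximal intensities keep
# getting costlier (an upper clamp would make arbitrarily fast speeds the
# most pleasant option); the observed RPE is clipped to 6-20 at recording
latent_cost <- function(hr, hrMax, restHR = 60) {
  6 + 14 * pmax((hr - restHR) / (hrMax - restHR), 0)
}

# model pleasantness over a candidate speed grid: hyperbolically
# effort-discounted value of an intensity-dependent reward. The conditioned
# reward component follows the same clamped quadratic HR profile as the
# conditioning controller (the learned reward tracks US delivery).
pleasantness_profile <- function(profile, timePoint, config) {
  s <- seq(config$speedMin, config$speedMax, by = config$speedStep)
  hps <- hr_per_speed(profile, timePoint)
  hr <- hps * s
  cost <- latent_cost(hr, profile$hrMax, config$restHR)
  deltaM <- if (timePoint == "T2" && profile$group == "COTR")
    profile$conditioningDeltaM else 0
  mFit <- config$rewardScale * map_reward(hps, profile$hrPerSpeed0, 0)
  thr <- config$thresholdFrac * profile$hrMax
  q <- if (deltaM != 0) {
    clamp((hr - profile$baselineHR) / (thr - profile$baselineHR), 0, 1)^2
  } else 0
  vp <- (mFit * (s / config$speedRef)^config$rewardExponent + deltaM * q) /
    (1 + profile$kEffort * cost)
  data.frame(speed = s, hr = hr, rpe = expected_rpe(hr, profile$hrMax,
                                                    config$restHR),
             vp = vp)
}

#' Simulate one self-paced exercise assessment
#'
#' The participant's selected treadmill speed is the argmax of model
#' pleasantness over a 0.1 km/h grid, where pleasantness is the hyperbolic
#' effort-discounted value of an intensity-dependent reward (see the
#' methods vignette). Observables are then the speed, the heart rate it
#' implies (plus measurement noise), the Borg 6--20 perceived exertion and
#' the -5..+5 Feeling Scale pleasantness rating (both rounded and clipped
#' to their scales).
#'
#' @param profile One-row participant profile.
#' @param timePoint One of \code{"T0"} (baseline), \code{"T1"}
#'   (post-training), \code{"T2"} (4-week follow-up).
#' @param config Parameter record.
#' @param seed Integer seed for the observation noise.
#' @param noise Logical; \code{FALSE} gives the noise-free record.
#' @return One-row data frame: \code{participantId, timePoint, speed,
#'   avgHR, rpe, fs}.
#' @export
simulate_trial_record <- function(profile, timePoint,
                                  config = default_config(), seed = NULL,
                                  noise = TRUE) {
  profile <- as_profile(profile)
  check_time_point(timePoint)
  grid <- pleasantness_profile(profile, timePoint, config)
  best <- grid[which.max(grid$vp), ]
  with_seed(seed, {
    hrSD <- if (noise) config$hrNoiseSD else 0
    rateSD <- if (noise) profile$ratingNoiseSD else 0
    avgHR <- best$hr + stats::rnorm(1, 0, hrSD)
    rpe <- clamp(round(best$rpe + stats::rnorm(1, 0, rateSD)), 6, 20)
    fs <- clamp(round(5 * best$vp + stats::rnorm(1, 0, rateSD)), -5, 5)
    data.frame(participantId = profile$id, timePoint = timePoint,
               speed = best$speed, avgHR = clamp(avgHR, 41, profile$hrMax),
               rpe = rpe, fs = fs, stringsAsFactors = FALSE)
  })
}

#' Simulate trial records for a whole cohort
#'
#' The no-training arm is not assessed at follow-up (T2), matching the
#' study design; training arms are assessed at all three time points.
#'
#' @param cohort Data frame from \code{make_cohort}.
#' @param config Parameter record.
#' @param seed Integer seed.
#' @param noise Logical; passed through to \code{simulate_trial_record}.
#' @return Data frame of trial records.
#' @export
simulate_trials <- function(cohort, config = default_config(), seed = NULL,
                            noise = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    prof <- cohort[i, ]
    tps <- if (prof$group == "NTR") c("T0", "T1") else time_points()
    for (tp in tps) {
      sub <- if (is.null(seed)) NULL else
        (seed + 131L * i + 17L * match(tp, time_points())) %%
          .Machine$integer.max
      rows[[length(rows) + 1L]] <-
        simulate_trial_record(prof, tp, config, seed = sub, noise = noise)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a single intertemporal choice
#'
#' Both options are valued hyperbolically with the profile's discount
#' constant for the trial's commodity: the immediate amount at face value
#' and the delayed amount as \code{A / (1 + k D)}. With zero choice noise
#' the larger value is chosen (exact ties are broken by a seeded fair
#' coin); otherwise the immediate option is chosen with logistic
#' probability \code{plogis((V_imm - V_del) / choiceNoise)}.
#'
#' @param profile One-row participant profile.
#' @param trial List or one-row data frame with \code{commodity,
#'   immediateAmount, delayedAmount, delayDays}.
#' @param seed Integer seed, or \code{NULL} to use the ambient RNG stream.
#' @return \code{"immediate"} or \code{"delayed"}.
#' @export
simulate_choice <- function(profile, trial, seed = NULL) {
  profile <- as_profile(profile)
  trial <- as.list(trial)
  if (!trial$commodity %in% commodities()) {
    stop("unknown commodity: ", trial$commodity, call. = FALSE)
  }
  check_number(trial$delayDays, "delayDays", lower = 0)
  check_number(trial$immediateAmount, "immediateAmount", lower = 0)
  check_number(trial$delayedAmount, "delayedAmount",
               lower = trial$immediateAmount)
  k <- switch(trial$commodity, money = profile$kMoney,
              food = profile$kFood, exercise = profile$kExercise)
  vImm <- trial$immediateAmount
  vDel <- mazur_value(trial$delayedAmount, k, trial$delayDays)
  with_seed(seed, {
    noise <- profile$choiceNoise
    if (noise <= 0) {
      if (vImm == vDel) {
        if (stats::runif(1) < 0.5) "immediate" else "delayed"
      } else if (vImm > vDel) "immediate" else "delayed"
    } else {
      p <- stats::plogis((vImm - vDel) / noise)
      if (stats::runif(1) < p) "immediate" else "delayed"
    }
  })
}

#' Build a responder closure for the adjusting-amount task
#'
#' @param profile One-row participant profile.
#' @param commodity One of money, food, exercise.
#' @return A function \code{(immediateAmount, delayedAmount, delayDays)}
#'   returning \code{"immediate"} or \code{"delayed"}, drawing any
#'   stochastic choice from the ambient RNG stream (the task engine seeds
#'   it).
#' @export
make_responder <- function(profile, commodity) {
  profile <- as_profile(profile)
  force(commodity)
  function(immediateAmount, delayedAmount, delayDays) {
    simulate_choice(profile,
                    list(commodity = commodity,
                         immediateAmount = immediateAmount,
                         delayedAmount = delayedAmount,
                         delayDays = delayDays))
  }
}
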