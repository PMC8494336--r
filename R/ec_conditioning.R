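# Evaluative-conditioning reward controller and interval-training schedule.
#
# During interval training, the conditioned stimulus is elevated heart rate
# and the unconditioned stimulus is a sweet solution delivered through a
# dual syringe-pump system at a fixed combined flow. The sweet fraction
# rises quadratically from 0 at the participant's baseline (self-selected
# speed) heart rate to 100% at 85% of age-predicted maximal heart rate.

#' Age-predicted maximal heart rate
#'
#' @param age Age in years. A warning is issued outside 18--50, the range
#'   in which the 220 - age prediction is considered adequate.
#' @return Predicted maximal heart rate in bpm, \code{220 - age}.
#' @examples
#' hr_max(20) # 200
#' @export
hr_max <- function(age) {
  if (!is.numeric(age) || anyNA(age)) {
    stop("`age` must be numeric", call. = FALSE)
  }
  if (any(age < 18 | age > 50)) {
    warning("age outside 18-50: the 220 - age prediction may be inaccurate")
  }
  220 - age
}

#' Sweet-solution pump rate as a function of current heart rate
#'
#' The controller delivers a sweet/neutral admixture at a constant combined
#' flow. The sweet rate is quadratic in the heart-rate elevation above
#' baseline, reaching the full flow at \code{thresholdFrac * hrMax}
#' (default 85% of maximal heart rate):
#' \deqn{sweet = total \cdot \frac{(HR - HR_{base})^2}{(0.85\,HR_{max} - HR_{base})^2}}
#' clamped to 0 below baseline and to \code{totalRate} at or above the
#' threshold, so the command is always physically realisable.
#'
#' @param currentHR Current heart rate, bpm (vectorised).
#' @param baselineHR Heart rate at self-selected baseline speed, bpm.
#' @param hrMax Maximal heart rate, bpm.
#' @param totalRate Combined liquid flow, ml/min (default 2).
#' @param thresholdFrac Fraction of \code{hrMax} at which sweetness
#'   saturates (default 0.85).
#' @return Sweet-solution rate in ml/min, in \code{[0, totalRate]}.
#' @examples
#' sweet_rate(120, 120, 200) # 0: at baseline
#' sweet_rate(170, 120, 200) # 2: saturated at 85% of 200
#' sweet_rate(145, 120, 200) # 0.5: (25/50)^2 * 2
#' @export
sweet_rate <- function(currentHR, baselineHR, hrMax, totalRate = 2,
                       thresholdFrac = 0.85) {
  check_number(baselineHR, "baselineHR", lower = 30, upper = 230)
  check_number(hrMax, "hrMax", lower = 100, upper = 230)
  check_number(totalRate, "totalRate", lower = 1e-9)
  threshold <- thresholdFrac * hrMax
  if (baselineHR >= threshold) {
    stop(sprintf(
      "degenerate controller: baselineHR (%g) >= %g%% of hrMax (%g)",
      baselineHR, 100 * thresholdFrac, threshold), call. = FALSE)
  }
  frac <- (currentHR - baselineHR)^2 / (threshold - baselineHR)^2
  frac[currentHR <= baselineHR] <- 0
  frac[currentHR >= threshold] <- 1
  totalRate * frac
}

#' Ramped interval-training session schedule
#'
#' One conditioning session: six treadmill cycles at peak intensities of
#' 60, 65, 70, 75, 80 and 85% of maximal heart rate. Each cycle ramps from
#' baseline to target over ~10 s, holds the target for 2 minutes, ramps
#' back down over ~10 s and holds baseline speed for a further 1.5 minutes.
#'
#' @param warmupSec Warm-up duration, s (default 180).
#' @param cooldownSec Cool-down duration, s (default 120).
#' @return An object of class \code{session_schedule}: a list with a
#'   \code{cycles} data frame (\code{targetPctHRmax}, \code{rampUpSec},
#'   \code{holdSec}, \code{rampDownSec}, \code{baselineSec}) plus warm-up
#'   and cool-down durations.
#' @export
build_session_schedule <- function(warmupSec = 180, cooldownSec = 120) {
  cycles <- data.frame(
    targetPctHRmax = c(60, 65, 70, 75, 80, 85),
    rampUpSec = 10,
    holdSec = 120,
    rampDownSec = 10,
    baselineSec = 90
  )
  structure(list(cycles = cycles, warmupSec = warmupSec,
                 cooldownSec = cooldownSec),
            class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  cat("Interval-training session schedule\n")
  cat(sprintf("  warm-up %d s, cool-down %d s, %d cycles\n",
              x$warmupSec, x$cooldownSec, nrow(x$cycles)))
  print(x$cycles, row.names = FALSE)
  invisible(x)
}

# piecewise-constant/linear HR target over one session, sampled at 1 Hz
session_target_profile <- function(schedule, baselineHR, hrMax) {
  seg <- function(dur, from, to) {
    if (dur <= 0) return(numeric(0))
    if (from == to) rep(to, dur) else seq(from, to, length.out = dur)
  }
  targets <- schedule$cycles$targetPctHRmax / 100 * hrMax
  hr <- seg(schedule$warmupSec, baselineHR, baselineHR)
  cycle_id <- rep(0L, schedule$warmupSec)
  for (i in seq_len(nrow(schedule$cycles))) {
    cyc <- schedule$cycles[i, ]
    part <- c(seg(cyc$rampUpSec, baselineHR, targets[i]),
              rep(targets[i], cyc$holdSec),
              seg(cyc$rampDownSec, targets[i], baselineHR),
              rep(baselineHR, cyc$baselineSec))
    hr <- c(hr, part)
    cycle_id <- c(cycle_id, rep(i, length(part)))
  }
  hr <- c(hr, rep(baselineHR, schedule$cooldownSec))
  cycle_id <- c(cycle_id, rep(0L, schedule$cooldownSec))
  data.frame(timeSec = seq_along(hr) - 1L, target = hr, cycle = cycle_id)
}

#' Simulate one conditioning/training session
#'
#' Heart rate follows a first-order relaxation towards the schedule's
#' moment-to-moment target with time constant \code{hrTimeConstant}
#' (Euler steps at 1 Hz) plus seeded Gaussian noise. Pump commands are
#' emitted at 1 Hz and always conserve the combined flow; with the
#' controller off (training-only arm) the sweet rate is identically zero.
#' One pairing event is logged per cycle when the controller is on,
#' carrying the cycle's peak heart rate and peak sweet fraction.
#'
#' @param profile A one-row participant profile (see \code{make_cohort}).
#' @param schedule A \code{session_schedule}
#'   (default \code{build_session_schedule()}).
#' @param controllerOn Logical; deliver the HR-contingent sweet admixture?
#' @param config Config list (uses \code{totalRate}, \code{thresholdFrac},
#'   \code{hrTimeConstant}, \code{hrTraceNoiseSD}).
#' @param seed Integer seed; the simulation is a pure function of
#'   (arguments, seed).
#' @param noise Logical; set \code{FALSE} for a deterministic trace.
#' @param sessionIndex Session number recorded in pairing events.
#' @return A list with \code{trace} (timeSec, hr), \code{commands}
#'   (timeSec, neutralRate, sweetRate) and \code{pairings} (sessionIndex,
#'   cycleIndex, peakHR, peakSweetFraction).
#' @export
simulate_session <- function(profile, schedule = build_session_schedule(),
                             controllerOn = TRUE, config = default_config(),
                             seed = NULL, noise = TRUE, sessionIndex = 1L) {
  profile <- as_profile(profile)
  check_flag(controllerOn, "controllerOn")
  prof_target <- session_target_profile(schedule, profile$baselineHR,
                                        profile$hrMax)
  tau <- config$hrTimeConstant
  sdn <- if (noise) config$hrTraceNoiseSD else 0
  with_seed(seed, {
    n <- nrow(prof_target)
    hr <- numeric(n)
    hr[1] <- profile$baselineHR
    eps <- if (sdn > 0) stats::rnorm(n, 0, sdn) else numeric(n)
    for (t in 2:n) {
      hr[t] <- hr[t - 1] + (prof_target$target[t] - hr[t - 1]) / tau + eps[t]
    }
    hr <- clamp(hr, 31, 229)
    sweet <- if (controllerOn) {
      sweet_rate(hr, profile$baselineHR, profile$hrMax,
                 totalRate = config$totalRate,
                 thresholdFrac = config$thresholdFrac)
    } else {
      rep(0, n)
    }
    commands <- data.frame(timeSec = prof_target$timeSec,
                           neutralRate = config$totalRate - sweet,
                           sweetRate = sweet)
    pairings <- if (controllerOn) {
      cyc <- sort(unique(prof_target$cycle[prof_target$cycle > 0L]))
      peakHR <- vapply(cyc, function(i) max(hr[prof_target$cycle == i]),
                       numeric(1))
      data.frame(
        sessionIndex = sessionIndex, cycleIndex = cyc, peakHR = peakHR,
        peakSweetFraction = sweet_rate(peakHR, profile$baselineHR,
                                       profile$hrMax,
                                       totalRate = config$totalRate,
                                       thresholdFrac = config$thresholdFrac) /
          config$totalRate)
    } else {
      data.frame(sessionIndex = integer(0), cycleIndex = integer(0),
                 peakHR = numeric(0), peakSweetFraction = numeric(0))
    }
    list(trace = data.frame(timeSec = prof_target$timeSec, hr = hr),
         commands = commands, pairings = pairings)
  })
}

#' Simulate a full conditioning plan (several sessions)
#'
#' @param profile One-row participant profile.
#' @param sessions Number of sessions (default 9: three weekly sessions
#'   over three weeks).
#' @param ... Passed to \code{simulate_session}.
#' @param seed Integer seed; session s uses a sub-seed derived from it.
#' @return A data frame of pairing events across sessions.
#' @export
simulate_training_plan <- function(profile, sessions = 9L, seed = NULL, ...) {
  out <- vector("list", sessions)
  for (s in seq_len(sessions)) {
    sub <- if (is.null(seed)) NULL else (seed + 1009L * s) %% .Machine$integer.max
    out[[s]] <- simulate_session(profile, seed = sub, sessionIndex = s,
                                 ...)$pairings
  }
  do.call(rbind, out)
}

#' Total number of CS--US pairings in a training plan
#'
#' @param sessionsPerWeek,weeks,pairingsPerSession Non-negative integers.
#' @return \code{sessionsPerWeek * weeks * pairingsPerSession}; the
#'   standard plan (3, 3, 6) gives 54.
#' @examples
#' count_pairings(3, 3, 6) # 54
#' @export
count_pairings <- function(sessionsPerWeek, weeks, pairingsPerSession) {
  for (nm in c("sessionsPerWeek", "weeks", "pairingsPerSession")) {
    v <- get(nm)
    check_number(v, nm, lower = 0)
    if (v != round(v)) stop(sprintf("`%s` must be an integer", nm),
                            call. = FALSE)
  }
  sessionsPerWeek * weeks * pairingsPerSession
}
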