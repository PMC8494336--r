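#' Default simulation and analysis configuration
#'
#' Returns the full parameter record driving the synthetic cohort, the
#' conditioning controller, the delay-discounting task and the fitting
#' stages. Defaults encode the study conditions: a 58-participant cohort
#' split 10/24/24 into no-training (NTR), training (TR) and
#' conditioning-plus-training (COTR) arms; right-skewed (log-normal)
#' per-day discount constants centred on the observed commodity medians;
#' a 2 ml/min dual-pump controller saturating at 85% of age-predicted
#' maximal heart rate; and a 15% distractor rate in the choice task.
#'
#' @return A named list of parameters. Keys mirror the field names used in
#'   the CSV interfaces, so a config file can override any subset.
#' @examples
#' cfg <- default_config()
#' cfg$totalRate
#' @export
default_config <- function() {
  list(
    # cohort composition
    n = 58L,
    groupSplit = c(NTR = 10, TR = 24, COTR = 24) / 58,
    # latent participant traits
    ageMean = 25, ageSD = 5, ageMin = 18, ageMax = 50,
    hrPerSpeedMean = 22.1, hrPerSpeedSD = 2.6,    # bpm per km/h, baseline
    trainingGainMean = 0.09, trainingGainSD = 0.03,
    detrainFractionMean = 0.8, detrainFractionSD = 0.1,
    kMoneyMeanlog = log(0.02), kMoneySdlog = 1.1,
    kExerciseMeanlog = log(0.17), kExerciseSdlog = 1.0,
    kFoodMeanlog = log(0.25), kFoodSdlog = 0.9,
    kEffortMeanlog = log(0.204), kEffortSdlog = 0.17,
    conditioningDeltaM = 0.2,                     # COTR only, added reward
    choiceNoise = 0.05, ratingNoiseSD = 0.5, hrNoiseSD = 3,
    # self-paced trial simulation
    speedMin = 3, speedMax = 16, speedStep = 0.1, # km/h treadmill grid
    speedRef = 5,                                 # km/h reward reference
    restHR = 60,                                  # bpm, RPE anchor
    rewardExponent = 0.715,                        # gamma in M(s) ~ s^gamma
    rewardScale = 2.8,                            # overall reward magnitude
    # conditioning controller
    totalRate = 2,                                # ml/min combined flow
    thresholdFrac = 0.85,                         # sweetness saturates here
    hrTimeConstant = 30,                          # s, HR relaxation
    hrTraceNoiseSD = 1,                           # bpm at 1 Hz
    # adjusting-amount task
    distractorRate = 0.15, staircaseMaxTrials = 200L,
    # fitting
    exclusionThreshold = 0.7, rewardMapping = "ratio"
  )
}

#' Read a plain-text key = value configuration file
#'
#' Lines have the form \code{key = value}; blank lines and lines starting
#' with \code{#} are ignored. Values are parsed as numeric where possible
#' (comma-separated values become numeric vectors) and kept as strings
#' otherwise. Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Path to the config file.
#' @param base Config to override; defaults to \code{default_config()}.
#' @return A config list as from \code{default_config()}.
#' @export
read_config <- function(path, base = default_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (line in lines) {
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop("malformed config line (no '='): ", line, call. = FALSE)
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    if (!key %in% names(base)) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) num else val
    if (!is.null(names(base[[key]])) && length(parsed) == length(base[[key]]))
      names(parsed) <- names(base[[key]])
    base[[key]] <- parsed
  }
  validate_config(base)
}

#' Write a configuration to a plain-text key = value file
#'
#' @param config Config list.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) paste(format(v, digits = 15, trim = TRUE,
                                  scientific = FALSE), collapse = ", ")
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", fmt(config[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

validate_config <- function(config) {
  check_number(config$totalRate, "totalRate", lower = 1e-9)
  check_number(config$thresholdFrac, "thresholdFrac", lower = 0.5, upper = 1)
  check_number(config$distractorRate, "distractorRate", lower = 0, upper = 0.9)
  check_number(config$exclusionThreshold, "exclusionThreshold",
               lower = 0, upper = 1)
  check_number(config$speedMin, "speedMin", lower = 0.1)
  check_number(config$speedMax, "speedMax", lower = config$speedMin)
  check_number(config$rewardExponent, "rewardExponent",
               lower = 0.05, upper = 0.95)
  if (any(config$groupSplit < 0) ||
      abs(sum(config$groupSplit) - 1) > 1e-8) {
    stop("`groupSplit` must be non-negative proportions summing to 1",
         call. = FALSE)
  }
  config
}

# stable hash of a config (used to stamp output files)
config_hash <- function(config) {
  tf <- tempfile(fileext = ".cfg")
  on.exit(unlink(tf), add = TRUE)
  write_config(config, tf)
  unname(tools::md5sum(tf))
}
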