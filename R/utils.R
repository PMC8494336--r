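# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global random stream seeded to \code{seed} and
#' restores the caller's RNG state afterwards, so every seeded generator in
#' the package is a pure function of (inputs, seed).
#'
#' @param seed Integer seed, or \code{NULL} to use the ambient RNG stream.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# clamp a numeric vector to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# scalar validation with a readable error
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (is.finite(x) && (x < lower || x > upper)) {
    stop(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

# one-row access helper: accept a one-row data.frame or a list-like profile
as_profile <- function(profile) {
  if (is.data.frame(profile)) {
    if (nrow(profile) != 1L) {
      stop("`profile` must be a single participant (one row)", call. = FALSE)
    }
    profile <- as.list(profile)
  }
  required <- c("id", "group", "age", "baselineHR", "hrMax", "hrPerSpeed0",
                "trainingGain", "detrainFraction", "kMoney", "kFood",
                "kExercise", "kEffort", "conditioningDeltaM", "choiceNoise",
                "ratingNoiseSD")
  missing <- setdiff(required, names(profile))
  if (length(missing)) {
    stop("profile is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  profile
}

time_points <- function() c("T0", "T1", "T2")
study_groups <- function() c("NTR", "TR", "COTR")
commodities <- function() c("money", "food", "exercise")

check_time_point <- function(timePoint) {
  if (!is.character(timePoint) || length(timePoint) != 1L ||
      !(timePoint %in% time_points())) {
    stop("`timePoint` must be one of ", paste(time_points(), collapse = ", "),
         call. = FALSE)
  }
  timePoint
}
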