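# Shared-k hyperbolic effort valuation: Vp = M / (1 + kC), with Vp the
# normalised Feeling Scale pleasantness, C the Borg RPE cost and M a
# fitness-derived reward value, fitted by least squares with one k per
# condition and compared to the measured values by an exact sign test.

#' Normalise a Feeling Scale rating to a subjective value
#'
#' The -5..+5 pleasantness rating is divided by the scale maximum, giving
#' a subjective value Vp in [-1, 1]; negative pleasantness maps to
#' negative value.
#'
#' @param fs Feeling Scale rating(s) in [-5, 5].
#' @return \code{fs / 5}.
#' @examples
#' normalize_fs(4.27) # 0.854
#' @export
normalize_fs <- function(fs) {
  if (!is.numeric(fs) || any(fs < -5 | fs > 5)) {
    stop("`fs` must be numeric in [-5, 5]", call. = FALSE)
  }
  fs / 5
}

#' Map fitness to the reward value M
#'
#' Heart rate per unit speed (bpm per km/h) is an inverse fitness index:
#' the fitter the participant, the fewer beats a given speed costs. The
#' default ("ratio") mapping sets \code{M = refHrPerSpeed / hrPerSpeed +
#' deltaM}, so the cohort reference has M = 1, improved fitness raises M,
#' and a conditioned reward adds on top. The mapping is a named, swappable
#' strategy recorded in fit metadata.
#'
#' @param hrPerSpeed Observed heart rate per speed, bpm per km/h (> 0).
#' @param refHrPerSpeed Reference (e.g. cohort baseline mean), > 0.
#' @param deltaM Additive conditioned-reward increment (default 0).
#' @param mapping Mapping name; only \code{"ratio"} is built in.
#' @return Reward value M (unitless).
#' @examples
#' map_reward(20, 22) # 1.1
#' @export
map_reward <- function(hrPerSpeed, refHrPerSpeed, deltaM = 0,
                       mapping = "ratio") {
  if (any(hrPerSpeed <= 0) || any(refHrPerSpeed <= 0)) {
    stop("heart-rate-per-speed values must be positive", call. = FALSE)
  }
  if (mapping != "ratio") {
    stop("unknown reward mapping: ", mapping, call. = FALSE)
  }
  refHrPerSpeed / hrPerSpeed + deltaM
}

#' Build effort observations from trial records
#'
#' Maps each self-paced exercise record to the effort model's quantities:
#' Vp = FS / 5, C = raw RPE, and M from the heart-rate-per-speed ratio
#' against a reference (by default the cohort's baseline mean).
#'
#' @param trials Trial records (see \code{simulate_trials}).
#' @param cohort Cohort table supplying each participant's group.
#' @param refHrPerSpeed Reference fitness; default is the cohort mean of
#'   avgHR/speed at T0.
#' @param mapping Reward mapping name.
#' @return Data frame of observations: \code{participantId, timePoint,
#'   group, vp, cost, reward}, with the reference and mapping recorded as
#'   attributes.
#' @export
effort_observations <- function(trials, cohort, refHrPerSpeed = NULL,
                                mapping = "ratio") {
  hps <- trials$avgHR / trials$speed
  if (is.null(refHrPerSpeed)) {
    refHrPerSpeed <- mean(hps[trials$timePoint == "T0"])
  }
  out <- data.frame(
    participantId = trials$participantId,
    timePoint = trials$timePoint,
    group = cohort$group[match(trials$participantId, cohort$id)],
    vp = normalize_fs(trials$fs),
    cost = trials$rpe,
    reward = map_reward(hps, refHrPerSpeed, 0, mapping = mapping),
    stringsAsFactors = FALSE
  )
  attr(out, "refHrPerSpeed") <- refHrPerSpeed
  attr(out, "mapping") <- mapping
  out
}

#' Fit the shared-k hyperbolic effort-discounting model
#'
#' One discount constant k is fitted per condition by minimising
#' \eqn{\sum_i (Vp_i - M_i/(1 + k C_i))^2} over \eqn{k \ge 0}
#' (multi-start bounded scalar minimisation, as in the Mazur fitter). The
#' predicted values are compared with the measured ones by an exact sign
#' test on the paired differences; because the phrase "sign test" can
#' also mean the signed-rank test, the Wilcoxon signed-rank statistic is
#' reported alongside for small samples (n <= 25).
#'
#' @param observations Data frame with columns \code{vp}, \code{cost},
#'   \code{reward} (see \code{effort_observations}); at least 2 rows.
#' @param conditionLabel Label for the fitted condition (e.g. "T0",
#'   "T2-COTR").
#' @return An object of class \code{effort_fit}: \code{k},
#'   \code{vpModel}, \code{residualSS}, \code{comparison} (exact sign
#'   test: statistic, pValue, nonZeroPairs, zerosDropped),
#'   \code{signedRank} (or NULL), \code{flatObjective} flag, the data and
#'   metadata.
#' @examples
#' obs <- data.frame(vp = 1 / (1 + 0.204 * c(8, 10, 12)),
#'                   cost = c(8, 10, 12), reward = 1)
#' coef(fit_shared_k(obs))
#' @export
fit_shared_k <- function(observations, conditionLabel = "all") {
  need <- c("vp", "cost", "reward")
  if (!all(need %in% names(observations))) {
    stop("observations need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(observations) < 2L) {
    stop("need at least 2 observations", call. = FALSE)
  }
  if (any(observations$reward <= 0)) {
    stop("rewards must be positive", call. = FALSE)
  }
  vp <- observations$vp
  C <- observations$cost
  M <- observations$reward
  flat <- length(unique(C)) == 1L && length(unique(M)) == 1L
  ss <- function(k) sum((vp - M / (1 + k * C))^2)
  k <- minimise_k(ss)
  vpModel <- M / (1 + k * C)
  cmp <- sign_test(vp - vpModel)
  sr <- NULL
  if (length(vp) <= 25L) {
    w <- suppressWarnings(stats::wilcox.test(vp, vpModel, paired = TRUE,
                                             exact = FALSE))
    sr <- list(statistic = unname(w$statistic), pValue = w$p.value)
  }
  structure(list(
    conditionLabel = conditionLabel,
    k = k,
    vpModel = vpModel,
    residualSS = ss(k),
    comparison = cmp,
    signedRank = sr,
    flatObjective = flat,
    data = observations,
    mapping = attr(observations, "mapping"),
    refHrPerSpeed = attr(observations, "refHrPerSpeed"),
    call = match.call()
  ), class = "effort_fit")
}

#' @export
print.effort_fit <- function(x, digits = 4, ...) {
  cat("Shared-k hyperbolic effort-valuation fit\n")
  cat(sprintf("  condition %s: k = %s (n = %d), residual SS = %s\n",
              x$conditionLabel, format(x$k, digits = digits),
              nrow(x$data), format(x$residualSS, digits = digits)))
  cat(sprintf("  model vs measured Vp, exact sign test: S = %d, p = %s\n",
              x$comparison$statistic,
              format(x$comparison$pValue, digits = digits)))
  if (x$flatObjective) cat("  [flat objective: degenerate inputs]\n")
  invisible(x)
}

#' @export
summary.effort_fit <- function(object, ...) {
  d <- data.frame(measured = object$data$vp, model = object$vpModel)
  structure(list(fit = object, vpSummary = summary(d)),
            class = "summary.effort_fit")
}

#' @export
print.summary.effort_fit <- function(x, ...) {
  print(x$fit)
  print(x$vpSummary)
  invisible(x)
}

#' @export
coef.effort_fit <- function(object, ...) c(k = object$k)

#' @export
fitted.effort_fit <- function(object, ...) object$vpModel

#' @export
residuals.effort_fit <- function(object, ...) {
  object$data$vp - object$vpModel
}

#' Predict subjective value for new cost/reward pairs
#'
#' @param object An \code{effort_fit}.
#' @param newdata Data frame with \code{cost} and \code{reward} columns;
#'   defaults to the fitted data.
#' @param ... Unused.
#' @return Predicted Vp values \code{reward / (1 + k * cost)}.
#' @export
predict.effort_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$vpModel)
  newdata$reward / (1 + object$k * newdata$cost)
}

#' @export
plot.effort_fit <- function(x, ...) {
  graphics::plot(x$data$cost, x$data$vp, pch = 19,
                 xlab = "Perceived cost (RPE)", ylab = "Subjective value Vp",
                 main = sprintf("Effort fit %s: k = %.3g", x$conditionLabel,
                                x$k), ...)
  ord <- order(x$data$cost)
  graphics::lines(x$data$cost[ord], x$vpModel[ord], col = "firebrick")
  invisible(x)
}

#' Exact two-sided sign test on paired differences
#'
#' Zero differences are dropped (and reported); the two-sided p-value is
#' the exact binomial tail doubling under a fair-coin null, identical to
#' full enumeration of sign patterns.
#'
#' @param pairedDiffs Numeric vector of signed paired differences.
#' @return List: \code{statistic} (number of positive differences),
#'   \code{pValue}, \code{nonZeroPairs}, \code{zerosDropped}.
#' @examples
#' sign_test(c(1, 2, 0.5, 3, 1, 2))$pValue # 2 * (1/2)^6 = 0.03125
#' @export
sign_test <- function(pairedDiffs) {
  if (!is.numeric(pairedDiffs) || length(pairedDiffs) < 1L) {
    stop("`pairedDiffs` must be a non-empty numeric vector", call. = FALSE)
  }
  nz <- pairedDiffs[pairedDiffs != 0]
  nPos <- sum(nz > 0)
  n <- length(nz)
  p <- if (n == 0) 1 else min(1, 2 * min(stats::pbinom(nPos, n, 0.5),
                                         1 - stats::pbinom(nPos - 1, n, 0.5)))
  list(statistic = nPos, pValue = p, nonZeroPairs = n,
       zerosDropped = length(pairedDiffs) - n)
}
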