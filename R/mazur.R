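# Hyperbolic (Mazur) delay-discounting fits: V = A / (1 + kD), least
# squares on indifference points normalised by the largest delayed reward,
# with the goodness-of-fit exclusion rule used before group statistics.

#' Hyperbolic subjective value of a delayed reward
#'
#' @param amount Reward amount (commodity units).
#' @param k Discount constant, per day, >= 0.
#' @param delayDays Delay in days, >= 0. Vectorised over all arguments.
#' @return \code{amount / (1 + k * delayDays)}.
#' @examples
#' mazur_value(50, 0.01, 100) # 25
#' @export
mazur_value <- function(amount, k, delayDays) {
  if (any(k < 0)) stop("`k` must be >= 0", call. = FALSE)
  if (any(delayDays < 0)) stop("`delayDays` must be >= 0", call. = FALSE)
  amount / (1 + k * delayDays)
}

# least-squares objective on normalised indifference points
mazur_ss <- function(k, delays, ipNorm) {
  sum((ipNorm - 1 / (1 + k * delays))^2)
}

# multi-start bounded scalar minimisation: coarse log-spaced candidate
# grid (plus k = 0), then local refinement around the best candidate.
# The objective can be flat at the extremes, so a single local search is
# not trusted.
minimise_k <- function(ss, kGrid = c(0, 10^seq(-6, 1, length.out = 71))) {
  vals <- vapply(kGrid, ss, numeric(1))
  best <- kGrid[which.min(vals)]
  lo <- if (best <= 0) 0 else best / 10
  hi <- max(best * 10, 1e-5)
  opt <- stats::optimize(ss, interval = c(lo, hi), tol = 1e-10)
  cand <- c(best, opt$minimum, 0)
  cand[which.min(vapply(cand, ss, numeric(1)))]
}

#' Fit Mazur's hyperbolic discount function to an indifference curve
#'
#' Minimises \eqn{\sum_D (IP_D/A - 1/(1+kD))^2} over \eqn{k \ge 0}, where
#' A is the fixed delayed anchor (largest reward); normalising by A puts
#' the three commodities' units on one scale. The optimiser is a
#' multi-start bounded scalar minimisation over a log-spaced grid of
#' starting values, so flat tails of the objective cannot trap it.
#' \eqn{R^2} is computed on the normalised points about their mean; a
#' curve whose points are all equal has zero total sum of squares, and
#' then \eqn{R^2} is reported as \code{NA} with inclusion decided by
#' whether the k = 0 hyperbola fits exactly.
#'
#' @param curve An \code{indifference_curve} (from
#'   \code{run_adjusting_task} or \code{indifference_curve}) with at
#'   least 3 non-zero-delay points.
#' @param inclusionThreshold Minimum \eqn{R^2} for inclusion
#'   (default 0.7); curves below it are excluded from group statistics by
#'   \code{apply_exclusion}.
#' @return An object of class \code{mazur_fit}: \code{k}, \code{logK},
#'   \code{rSquared}, \code{included}, \code{degenerate},
#'   \code{participantId}, \code{commodity}, \code{largestReward} and the
#'   fitted data.
#' @examples
#' cv <- indifference_curve(c(1, 7, 30, 60, 180),
#'                          mazur_value(50, 0.1, c(1, 7, 30, 60, 180)), 50)
#' fit <- fit_hyperbolic(cv)
#' coef(fit)
#' @export
fit_hyperbolic <- function(curve, inclusionThreshold = 0.7) {
  if (!inherits(curve, "indifference_curve")) {
    stop("`curve` must be an indifference_curve", call. = FALSE)
  }
  delays <- curve$points$delayDays
  ips <- curve$points$ip
  if (length(delays) < 3L) {
    stop("need at least 3 non-zero-delay indifference points",
         call. = FALSE)
  }
  A <- curve$largestReward
  ipNorm <- ips / A
  k <- minimise_k(function(k) mazur_ss(k, delays, ipNorm))
  ssRes <- mazur_ss(k, delays, ipNorm)
  ssTot <- sum((ipNorm - mean(ipNorm))^2)
  degenerate <- ssTot < 1e-12
  if (degenerate) {
    rSquared <- NA_real_
    included <- mazur_ss(0, delays, ipNorm) < 1e-12
    if (included) k <- 0
  } else {
    rSquared <- 1 - ssRes / ssTot
    included <- rSquared >= inclusionThreshold
  }
  structure(list(
    participantId = curve$participantId,
    commodity = curve$commodity,
    k = k,
    logK = if (k > 0) log(k) else NA_real_,
    rSquared = rSquared,
    included = included,
    degenerate = degenerate,
    largestReward = A,
    data = data.frame(delayDays = delays, ip = ips, ipNorm = ipNorm),
    fittedNorm = 1 / (1 + k * delays),
    normalised = TRUE,
    call = match.call()
  ), class = "mazur_fit")
}

#' @export
print.mazur_fit <- function(x, digits = 4, ...) {
  cat("Hyperbolic (Mazur) discounting fit\n")
  cat(sprintf("  %s / %s: k = %s per day, R^2 = %s, %s\n",
              x$participantId, x$commodity,
              format(x$k, digits = digits),
              if (is.na(x$rSquared)) "NA (degenerate)"
              else format(x$rSquared, digits = digits),
              if (x$included) "included" else "excluded (poor fit)"))
  invisible(x)
}

#' @export
summary.mazur_fit <- function(object, ...) {
  res <- stats::residuals(object)
  structure(list(fit = object,
                 residSummary = summary(res),
                 sse = sum(res^2)), class = "summary.mazur_fit")
}

#' @export
print.summary.mazur_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  SSE (normalised scale): %g\n", x$sse))
  cat("  residuals (normalised IP - fitted):\n")
  print(x$residSummary)
  invisible(x)
}

#' @export
coef.mazur_fit <- function(object, ...) c(k = object$k)

#' Predicted subjective value at new delays
#'
#' @param object A \code{mazur_fit}.
#' @param newdata Optional data frame with a \code{delayDays} column (or a
#'   numeric vector of delays); defaults to the fitted delays.
#' @param normalised If \code{TRUE} return values on the 0--1 normalised
#'   scale, else in commodity units (times the largest reward).
#' @param ... Unused.
#' @return Numeric vector of predicted values.
#' @export
predict.mazur_fit <- function(object, newdata = NULL, normalised = FALSE,
                              ...) {
  delays <- if (is.null(newdata)) object$data$delayDays
            else if (is.numeric(newdata)) newdata
            else newdata$delayDays
  v <- 1 / (1 + object$k * delays)
  if (normalised) v else v * object$largestReward
}

#' @export
fitted.mazur_fit <- function(object, ...) object$fittedNorm

#' @export
residuals.mazur_fit <- function(object, ...) {
  object$data$ipNorm - object$fittedNorm
}

#' @export
plot.mazur_fit <- function(x, ...) {
  d <- x$data
  dd <- seq(0, max(d$delayDays), length.out = 200)
  graphics::plot(d$delayDays, d$ipNorm, xlab = "Delay (days)",
                 ylab = "Normalised indifference point", ylim = c(0, 1),
                 pch = 19,
                 main = sprintf("%s / %s: k = %.4g", x$participantId,
                                x$commodity, x$k), ...)
  graphics::lines(dd, 1 / (1 + x$k * dd), col = "steelblue")
  invisible(x)
}

#' Collect a list of Mazur fits into a tidy table
#'
#' @param fits List of \code{mazur_fit} objects.
#' @return Data frame with one row per fit: \code{participantId,
#'   commodity, k, rSquared, included, logK, degenerate}.
#' @export
dd_fit_table <- function(fits) {
  if (inherits(fits, "mazur_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(participantId = f$participantId, commodity = f$commodity,
               k = f$k, rSquared = f$rSquared, included = f$included,
               logK = f$logK, degenerate = f$degenerate,
               stringsAsFactors = FALSE)
  }))
}

#' Apply the goodness-of-fit exclusion rule
#'
#' Data sets are removed when the hyperbolic model fits poorly:
#' \eqn{R^2 < threshold} (strict; a fit exactly at the threshold is
#' retained). Degenerate fits with undefined \eqn{R^2} use their
#' \code{included} flag (exact k = 0 fit retained).
#'
#' @param fits List of \code{mazur_fit}s or a table from
#'   \code{dd_fit_table}.
#' @param threshold Exclusion threshold (default 0.7).
#' @return List with \code{retained} and \code{removed} tables.
#' @export
apply_exclusion <- function(fits, threshold = 0.7) {
  tab <- if (is.data.frame(fits)) fits else dd_fit_table(fits)
  if (is.null(tab) || nrow(tab) == 0L) {
    empty <- data.frame(participantId = character(0),
                        commodity = character(0), k = numeric(0),
                        rSquared = numeric(0), included = logical(0),
                        logK = numeric(0))
    return(list(retained = empty, removed = empty))
  }
  keep <- ifelse(is.na(tab$rSquared), tab$included,
                 tab$rSquared >= threshold)
  list(retained = tab[keep, , drop = FALSE],
       removed = tab[!keep, , drop = FALSE])
}

#' Variable transforms applied before parametric group statistics
#'
#' Skewed variables are transformed before ANOVA-type analyses: discount
#' constants (and speed, heart rate) by natural log, perceived exertion by
#' squaring.
#'
#' @param values Numeric vector.
#' @param kind \code{"logK"} (natural log; requires strictly positive
#'   values) or \code{"rpeSquare"}.
#' @return Transformed vector.
#' @examples
#' transform_for_stats(c(1, exp(1)), "logK")
#' transform_for_stats(10, "rpeSquare")
#' @export
transform_for_stats <- function(values, kind = c("logK", "rpeSquare")) {
  kind <- match.arg(kind)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (kind == "logK") {
    bad <- which(values <= 0)
    if (length(bad)) {
      stop("log transform undefined for non-positive value(s) at position ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    log(values)
  } else {
    values^2
  }
}
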