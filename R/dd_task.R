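# Adjusting-amount delay-discounting task: commodity menus and the
# bisection staircase that locates per-delay indifference points.

#' Commodity menu for the delay-discounting task
#'
#' The three menus used in the computerised task: hypothetical money
#' amounts in GBP, food in bites (30 bites to a plate... the menu lists 1
#' to 5 plates), and exercise in minutes (one 30-minute gym session to
#' five). All menus share the delay set 0 ("at the end of this session"),
#' 1, 7, 30, 60 and 180 days; delay 0 only frames the immediate option and
#' is never fitted.
#'
#' @param commodity One of \code{"money"}, \code{"food"},
#'   \code{"exercise"}.
#' @return A list of class \code{commodity_menu}: \code{commodity},
#'   \code{amounts}, \code{unit}, \code{delaysDays}.
#' @examples
#' build_menu("money")$amounts
#' @export
build_menu <- function(commodity) {
  menus <- list(
    money = list(amounts = c(2, 7, 12, 17, 22, 27, 32, 37, 42, 47, 50),
                 unit = "GBP"),
    food = list(amounts = c(5, 10, 15, 20, 30, 60, 90, 120, 150),
                unit = "bites"),
    exercise = list(amounts = c(5, 10, 15, 20, 30, 60, 90, 120, 150),
                    unit = "minutes")
  )
  if (!is.character(commodity) || length(commodity) != 1L ||
      !commodity %in% names(menus)) {
    stop("unknown commodity; use one of ",
         paste(names(menus), collapse = ", "), call. = FALSE)
  }
  m <- menus[[commodity]]
  structure(list(commodity = commodity, amounts = m$amounts, unit = m$unit,
                 delaysDays = c(0, 1, 7, 30, 60, 180)),
            class = "commodity_menu")
}

#' @export
print.commodity_menu <- function(x, ...) {
  cat(sprintf("Delay-discounting menu: %s (%s)\n", x$commodity, x$unit))
  cat("  amounts:", paste(x$amounts, collapse = ", "), "\n")
  cat("  delays (days):", paste(x$delaysDays, collapse = ", "), "\n")
  invisible(x)
}

# smallest spacing between menu amounts = staircase resolution
menu_step <- function(menu) min(diff(sort(menu$amounts)))

#' Run the adjusting-amount task and recover indifference points
#'
#' For each non-zero delay the delayed option is anchored at the largest
#' menu reward and a bisection staircase adjusts the immediate amount on
#' \code{[0, largestReward]}: choosing the immediate option lowers the
#' upper bracket, choosing the delayed option raises the lower bracket,
#' until the bracket is narrower than one menu step. The indifference
#' point is the midpoint of the final bracket. Staircases for the
#' different delays are interleaved in seeded random order, and distractor
#' trials (verbatim repeats of earlier offers, which never feed the
#' bracket) are interspersed at \code{distractorRate} to mask the
#' adjustment rule.
#'
#' @param responder Function \code{(immediateAmount, delayedAmount,
#'   delayDays)} returning \code{"immediate"} or \code{"delayed"}; see
#'   \code{make_responder}.
#' @param menu A \code{commodity_menu}.
#' @param seed Integer seed controlling trial order, distractor placement
#'   and any stochastic responder.
#' @param distractorRate Fraction of trials that are distractors
#'   (default 0.15).
#' @param maxTrials Trial budget; exceeding it flags the curve instead of
#'   failing silently.
#' @param participantId Identifier recorded on the curve.
#' @return An object of class \code{indifference_curve}: \code{points}
#'   (delayDays, ip), \code{largestReward}, \code{flagged},
#'   \code{diagnostics} (per-delay trial counts and final bracket widths)
#'   and the full \code{trials} log (with a \code{distractor} column).
#' @export
run_adjusting_task <- function(responder, menu, seed = NULL,
                               distractorRate = 0.15, maxTrials = 200L,
                               participantId = "P000") {
  stopifnot(is.function(responder))
  check_number(distractorRate, "distractorRate", lower = 0, upper = 0.9)
  A <- max(menu$amounts)
  step <- menu_step(menu)
  delays <- setdiff(menu$delaysDays, 0)

  with_seed(seed, {
    lo <- stats::setNames(rep(0, length(delays)), delays)
    hi <- stats::setNames(rep(A, length(delays)), delays)
    done <- stats::setNames(rep(FALSE, length(delays)), delays)
    nTrials <- 0L
    log <- list()
    record <- function(imm, delay, choice, distractor) {
      log[[length(log) + 1L]] <<- data.frame(
        immediateAmount = imm, delayedAmount = A, delayDays = delay,
        choice = choice, distractor = distractor)
    }
    flagged <- FALSE
    while (!all(done)) {
      if (nTrials >= maxTrials) {
        flagged <- TRUE
        break
      }
      open <- names(done)[!done]
      d <- if (length(open) == 1L) open else sample(open, 1L)
      # distractor: replay a random earlier real offer; never updates brackets
      if (length(log) > 0 && stats::runif(1) < distractorRate) {
        prev <- log[[sample(length(log), 1L)]]
        ch <- responder(prev$immediateAmount, A, prev$delayDays)
        record(prev$immediateAmount, prev$delayDays, ch, TRUE)
        nTrials <- nTrials + 1L
        next
      }
      offer <- (lo[d] + hi[d]) / 2
      ch <- responder(offer, A, as.numeric(d))
      if (!ch %in% c("immediate", "delayed")) {
        stop("responder must return 'immediate' or 'delayed'",
             call. = FALSE)
      }
      record(offer, as.numeric(d), ch, FALSE)
      nTrials <- nTrials + 1L
      if (ch == "immediate") hi[d] <- offer else lo[d] <- offer
      if (hi[d] - lo[d] <= step) done[d] <- TRUE
    }
    points <- data.frame(delayDays = as.numeric(names(lo)),
                         ip = unname((lo + hi) / 2))
    points <- points[order(points$delayDays), ]
    structure(list(
      participantId = participantId,
      commodity = menu$commodity,
      points = points,
      largestReward = A,
      flagged = flagged,
      diagnostics = data.frame(delayDays = as.numeric(names(lo)),
                               finalWidth = unname(hi - lo),
                               converged = unname(done)),
      trials = do.call(rbind, log)
    ), class = "indifference_curve")
  })
}

#' @export
print.indifference_curve <- function(x, ...) {
  cat(sprintf("Indifference curve: %s, %s (anchor %g)%s\n",
              x$participantId, x$commodity, x$largestReward,
              if (x$flagged) " [FLAGGED: did not converge]" else ""))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Assemble an indifference curve from raw per-delay points
#'
#' Convenience constructor used when indifference points come from
#' elsewhere (e.g. directly evaluated hyperbolas in tests, or recorded
#' data) rather than from \code{run_adjusting_task}.
#'
#' @param delays Non-zero delays in days.
#' @param ips Indifference points, same length, each in
#'   \code{[0, largestReward]}.
#' @param largestReward The fixed delayed anchor amount.
#' @param participantId,commodity Identifiers carried through to fits.
#' @return An \code{indifference_curve}.
#' @export
indifference_curve <- function(delays, ips, largestReward,
                               participantId = "P000",
                               commodity = "money") {
  if (length(delays) != length(ips)) {
    stop("`delays` and `ips` must have equal length", call. = FALSE)
  }
  if (any(delays <= 0)) stop("delays must be positive", call. = FALSE)
  if (any(ips < 0 | ips > largestReward)) {
    stop("indifference points must lie in [0, largestReward]",
         call. = FALSE)
  }
  ord <- order(delays)
  structure(list(participantId = participantId, commodity = commodity,
                 points = data.frame(delayDays = delays[ord],
                                     ip = ips[ord]),
                 largestReward = largestReward, flagged = FALSE,
                 diagnostics = NULL, trials = NULL),
            class = "indifference_curve")
}
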