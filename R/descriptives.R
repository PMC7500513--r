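#' Per-trial outcomes
#'
#' Collapses the click events of each recorded trial into one row: who
#' clicked, whether each click was correct (assigned to the partner's
#' avatar), the PAS responses, joint success (both clicked and both
#' correct), the inter-click interval (absent unless both clicked) and the
#' dichotomized delay indicator, which is 1 iff both players clicked within
#' strictly less than \code{delay_window} seconds of each other.
#'
#' @param ds a \code{pc_session}; every click must have a target.
#' @param delay_window dichotomization window in seconds (default 3).
#' @return data frame, one row per recorded trial: \code{team_id,
#'   trial_number, clicked1, clicked2, correct1, correct2, pas1, pas2,
#'   both_clicked, joint_success, interclick_interval, delay_indicator}.
#' @export
trial_outcomes <- function(ds, delay_window = 3) {
  stopifnot(inherits(ds, "pc_session"))
  ev <- ds$events
  if (nrow(ev) && anyNA(ev$target))
    stop("unassigned click targets: run classify_session() first")
  tr <- ds$trials[order(ds$trials$team_id, ds$trials$trial_number), ,
                  drop = FALSE]
  n <- nrow(tr)
  out <- data.frame(team_id = tr$team_id, trial_number = tr$trial_number,
                    clicked1 = FALSE, clicked2 = FALSE,
                    correct1 = NA, correct2 = NA,
                    pas1 = NA_integer_, pas2 = NA_integer_,
                    both_clicked = FALSE, joint_success = FALSE,
                    interclick_interval = NA_real_, delay_indicator = 0L)
  if (nrow(ev)) {
    evkey <- paste(ev$team_id, ev$trial_number)
    trkey <- paste(tr$team_id, tr$trial_number)
    t1 <- rep(NA_real_, n); t2 <- rep(NA_real_, n)
    for (i in seq_len(nrow(ev))) {
      r <- match(evkey[i], trkey)
      m <- ev$player[i]
      out[[paste0("clicked", m)]][r] <- TRUE
      out[[paste0("correct", m)]][r] <- ev$target[i] == "other_avatar"
      out[[paste0("pas", m)]][r] <- ev$pas[i]
      if (m == 1L) t1[r] <- ev$click_time_s[i] else t2[r] <- ev$click_time_s[i]
    }
    out$interclick_interval <- abs(t1 - t2)
  }
  out$both_clicked <- out$clicked1 & out$clicked2
  out$joint_success <- out$both_clicked &
    !is.na(out$correct1) & !is.na(out$correct2) & out$correct1 & out$correct2
  out$interclick_interval[!out$both_clicked] <- NA_real_
  out$delay_indicator <- as.integer(!is.na(out$interclick_interval) &
                                      out$interclick_interval < delay_window)
  attr(out, "delay_window") <- delay_window
  out
}

# long (one row per click) view of outcomes, used by crosstabs and the model
outcomes_long <- function(out) {
  do.call(rbind, lapply(1:2, function(m) {
    sel <- out[[paste0("clicked", m)]]
    data.frame(team_id = out$team_id[sel], trial_number = out$trial_number[sel],
               player = rep(m, sum(sel)),
               correct = out[[paste0("correct", m)]][sel],
               pas = out[[paste0("pas", m)]][sel],
               joint_success = out$joint_success[sel],
               delay_indicator = out$delay_indicator[sel])
  }))
}

#' Headline counts of a session
#'
#' Tabulates the counts reported for this design: recorded trials, click
#' opportunities (two per trial), produced clicks, correct clicks (target =
#' partner's avatar), jointly successful trials, trials where both clicked
#' without joint success, and PAS response counts. Percentages are derived
#' by the caller; nothing is stored rounded.
#'
#' @param outcomes output of \code{\link{trial_outcomes}}.
#' @return object of class \code{pc_counts} (a list of integers plus the
#'   overall and conditional PAS frequency tables).
#' @export
count_summary <- function(outcomes) {
  if (!nrow(outcomes)) stop("no outcomes to summarise")
  lg <- outcomes_long(outcomes)
  res <- list(
    n_trials = nrow(outcomes),
    n_possible_clicks = 2L * nrow(outcomes),
    n_clicks = nrow(lg),
    n_correct = sum(lg$correct),
    n_joint_trials = sum(outcomes$joint_success),
    n_bothclick_nonjoint_trials = sum(outcomes$both_clicked &
                                        !outcomes$joint_success),
    n_pas = sum(!is.na(lg$pas)),
    pas_overall = pas_crosstab(outcomes, "all"),
    pas_incorrect = pas_crosstab(outcomes, "incorrect"),
    pas_correct_nonjoint = pas_crosstab(outcomes, "correct_nonjoint"),
    pas_correct_joint = pas_crosstab(outcomes, "correct_joint"))
  structure(res, class = "pc_counts")
}

#' @export
print.pc_counts <- function(x, ...) {
  cat(sprintf("trials %d | clicks %d/%d (%.0f%%) | correct %d (%.0f%%) | joint %d (%.0f%%)\n",
              x$n_trials, x$n_clicks, x$n_possible_clicks,
              100 * x$n_clicks / x$n_possible_clicks,
              x$n_correct, 100 * x$n_correct / x$n_clicks,
              x$n_joint_trials, 100 * x$n_joint_trials / x$n_trials))
  cat("PAS 1..4 overall:", x$pas_overall, "\n")
  invisible(x)
}

#' PAS frequency table under a condition
#'
#' Counts the PAS responses 1..4 among clicks meeting the condition:
#' \code{"all"} clicks with a PAS response, \code{"incorrect"} clicks,
#' \code{"correct_nonjoint"} correct clicks in trials without joint success,
#' or \code{"correct_joint"} correct clicks in jointly successful trials.
#'
#' @param outcomes output of \code{\link{trial_outcomes}}.
#' @param condition one of the four labels above.
#' @return integer vector of length 4 (counts of PAS = 1,2,3,4).
#' @export
pas_crosstab <- function(outcomes,
                         condition = c("all", "incorrect", "correct_nonjoint",
                                       "correct_joint")) {
  condition <- match.arg(condition)
  lg <- outcomes_long(outcomes)
  keep <- switch(condition,
                 all = rep(TRUE, nrow(lg)),
                 incorrect = !lg$correct,
                 correct_nonjoint = lg$correct & !lg$joint_success,
                 correct_joint = lg$correct & lg$joint_success)
  tabulate(lg$pas[keep & !is.na(lg$pas)], nbins = 4L)
}

#' Null distribution of the inter-click interval
#'
#' Under the null that both players click independently and uniformly over
#' the trial, the delay D = |X - Y| of two independent Uniform(0, T) times
#' has CDF \eqn{P(D \le d) = 1 - ((T - d)/T)^2}.
#'
#' @param d delay in seconds, in \code{[0, T]}. Vectorised.
#' @param T trial duration in seconds.
#' @return probability \code{P(D <= d)}.
#' @export
null_interval_cdf <- function(d, T = 60) {
  if (any(d < 0 | d > T)) stop("d must lie in [0, T]")
  1 - ((T - d) / T)^2
}

#' Boundary-corrected density of inter-click intervals
#'
#' Kernel density estimate of observed intervals on the bounded support
#' \code{[0, T]}, using Gaussian kernels with reflection at both boundaries
#' so the estimate integrates to one on the support. Also reports the
#' estimated probability that an interval falls below a threshold, by
#' numerical integration of the density.
#'
#' @param intervals numeric vector of observed intervals, seconds; at least
#'   5 values.
#' @param T trial duration (upper support bound), seconds.
#' @param method \code{"reflect"} (boundary-corrected, default) or
#'   \code{"plain"} (uncorrected, renormalised on \code{[0, T]}).
#' @param bandwidth kernel bandwidth in seconds; default Silverman's rule.
#' @param threshold delay threshold for the reported tail probability.
#' @param n_grid grid resolution.
#' @return list with \code{x}, \code{density}, \code{bandwidth},
#'   \code{p_below} (estimate of P(interval < threshold)), and
#'   \code{threshold}.
#' @export
interval_density <- function(intervals, T = 60, method = c("reflect", "plain"),
                             bandwidth = NULL, threshold = 3, n_grid = 1024) {
  method <- match.arg(method)
  intervals <- intervals[!is.na(intervals)]
  if (length(intervals) < 5)
    stop("too few intervals (", length(intervals), ") for density estimation; need >= 5")
  if (any(intervals < 0 | intervals > T)) stop("intervals must lie in [0, T]")
  h <- if (is.null(bandwidth)) stats::bw.nrd0(intervals) else bandwidth
  if (h <= 0) h <- 0.1
  x <- seq(0, T, length.out = n_grid)
  f <- vapply(x, function(xx) {
    k <- stats::dnorm(xx, intervals, h)
    if (method == "reflect")
      k <- k + stats::dnorm(xx, -intervals, h) +
        stats::dnorm(xx, 2 * T - intervals, h)
    mean(k)
  }, numeric(1))
  # trapezoid renormalisation on [0, T] (reflection already ~1; plain is not)
  dx <- x[2L] - x[1L]
  mass <- sum((f[-1L] + f[-n_grid]) / 2) * dx
  f <- f / mass
  below <- x <= threshold
  xb <- x[below]; fb <- f[below]
  p_below <- if (length(xb) > 1L)
    sum((fb[-1L] + fb[-length(fb)]) / 2) * dx else 0
  list(x = x, density = f, bandwidth = h, p_below = p_below,
       threshold = threshold, n = length(intervals))
}

#' Team scores
#'
#' The team gains one point per correct click and loses one per wrong click
#' (shadow, static or unknown); trials without a click contribute nothing.
#'
#' @param outcomes output of \code{\link{trial_outcomes}}.
#' @return named integer vector of scores, one per team.
#' @export
team_score <- function(outcomes) {
  lg <- outcomes_long(outcomes)
  teams <- sort(unique(outcomes$team_id))
  sc <- vapply(teams, function(j) {
    k <- lg$team_id == j
    sum(lg$correct[k]) - sum(!lg$correct[k])
  }, integer(1))
  names(sc) <- teams
  sc
}
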