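#' Flatten a session into model observation arrays
#'
#' Builds the observation-level design used by the hierarchical path model.
#' Individual success S is defined only for player-trials with a click
#' (success is undefined without a click); joint success G and the delay
#' indicator D are defined at trial level for every recorded trial, D being
#' 0 whenever fewer than two clicks occurred. PAS responses may be missing
#' (missing-at-random); a missing PAS contributes nothing to the fit.
#'
#' @param ds a \code{pc_session} with all click targets assigned, or a data
#'   frame of \code{\link{trial_outcomes}}.
#' @param delay_window dichotomization window in seconds.
#' @return object of class \code{pc_model_data}: list with \code{obs} (one
#'   row per click: \code{team, player, individual, trial, S, G, D, Y}),
#'   \code{trials} (one row per trial: \code{team, trial, G, D}),
#'   \code{n_teams}, \code{n_individuals}, \code{t_max}, and the team-id
#'   lookup \code{team_levels}.
#' @export
pc_model_data <- function(ds, delay_window = 3) {
  out <- if (inherits(ds, "pc_session")) trial_outcomes(ds, delay_window) else ds
  teams <- sort(unique(out$team_id))
  jidx <- match(out$team_id, teams)
  trials <- data.frame(team = jidx, trial = out$trial_number,
                       G = as.integer(out$joint_success),
                       D = out$delay_indicator)
  lg <- outcomes_long(out)
  lgj <- match(lg$team_id, teams)
  obs <- data.frame(team = lgj, player = lg$player,
                    individual = 2L * (lgj - 1L) + lg$player,
                    trial = lg$trial_number,
                    S = as.integer(lg$correct),
                    G = as.integer(lg$joint_success),
                    D = lg$delay_indicator,
                    Y = lg$pas)
  structure(list(obs = obs, trials = trials,
                 n_teams = length(teams),
                 n_individuals = 2L * length(teams),
                 t_max = max(out$trial_number),
                 team_levels = teams),
            class = "pc_model_data")
}

#' @export
print.pc_model_data <- function(x, ...) {
  cat("<pc_model_data>", nrow(x$obs), "click observations,",
      nrow(x$trials), "trials,", x$n_teams, "teams;",
      sum(!is.na(x$obs$Y)), "PAS responses\n")
  invisible(x)
}

# Pairs of PAS observations within a trial (both players clicked, both PAS
# observed) get the correlated bivariate residual; every other observed PAS
# is univariate. Returns row indices into md$obs.
pas_blocks <- function(md) {
  obs <- md$obs
  key <- paste(obs$team, obs$trial)
  haveY <- !is.na(obs$Y)
  pairs <- list()
  singles <- integer()
  for (k in unique(key)) {
    rows <- which(key == k & haveY)
    if (length(rows) == 2L) pairs[[length(pairs) + 1L]] <- rows
    else singles <- c(singles, rows)
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         matrix(integer(), 0, 2),
       singles = singles)
}
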