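#' Configuration for automatic click-target assignment
#'
#' A click is attributed to the candidate object nearest to the clicker's
#' avatar at the moment of the click, provided that distance does not exceed
#' \code{max_assign_distance}; otherwise the target is \code{"unknown"}.
#' When the two nearest candidates lie within \code{ambiguity_margin} of one
#' another the assignment is flagged for human review, standing in for the
#' trial-by-trial visual inspection an analyst would otherwise perform.
#'
#' @param max_assign_distance maximal anchor-to-anchor distance, in units,
#'   for a click to be attributed to an object (default 8: two object
#'   lengths).
#' @param ambiguity_margin distance margin, in units, below which the two
#'   nearest candidates are considered ambiguous.
#' @return an object of class \code{pc_assign}.
#' @export
assignment_config <- function(max_assign_distance = 8, ambiguity_margin = 2) {
  if (max_assign_distance <= 0 || ambiguity_margin <= 0)
    stop("invalid configuration: distances must be strictly positive")
  structure(list(max_assign_distance = max_assign_distance,
                 ambiguity_margin = ambiguity_margin), class = "pc_assign")
}

# Linear interpolation on the torus along the shorter arc between the two
# bracketing samples.
interp_torus <- function(times, positions, t, L) {
  if (!length(times)) stop("unassignable: no trajectory samples")
  if (t <= times[1L]) return(positions[1L])
  n <- length(times)
  if (t >= times[n]) return(positions[n])
  i <- findInterval(t, times)
  t0 <- times[i]; t1 <- times[i + 1L]
  p0 <- positions[i]; p1 <- positions[i + 1L]
  if (t1 == t0) return(p0)
  delta <- ((p1 - p0 + L / 2) %% L) - L / 2
  wrap_pos(p0 + delta * (t - t0) / (t1 - t0), L)
}

#' Assign a click to a target object
#'
#' The candidates are the three objects the clicking player can feel: the
#' partner's avatar, the partner's shadow, and the player's own static
#' object. Distances are torus distances between object anchors. Exact ties
#' are resolved by the fixed priority other_avatar > shadow > static; ties at
#' a measurable margin are reported through the ambiguity flag rather than
#' the priority order.
#'
#' @param click_position the clicker's avatar position at the click, units.
#' @param partner_avatar,partner_shadow,own_static candidate anchor
#'   positions at the click time, units.
#' @param world a \code{\link{world_config}}.
#' @param cfg an \code{\link{assignment_config}}.
#' @return list with \code{target} (one of \code{\link{object_kinds}}),
#'   \code{flagged} (logical), and the three candidate distances
#'   \code{d_avatar, d_shadow, d_static}.
#' @export
assign_target <- function(click_position, partner_avatar, partner_shadow,
                          own_static, world = world_config(),
                          cfg = assignment_config()) {
  L <- world$space_length
  d <- c(other_avatar = torus_distance(click_position, partner_avatar, L),
         shadow = torus_distance(click_position, partner_shadow, L),
         static = torus_distance(click_position, own_static, L))
  ord <- order(d)  # stable: earlier (higher-priority) name wins exact ties
  flagged <- (d[ord[2L]] - d[ord[1L]]) < cfg$ambiguity_margin
  target <- if (d[ord[1L]] <= cfg$max_assign_distance)
    names(d)[ord[1L]] else "unknown"
  list(target = target, flagged = unname(flagged),
       d_avatar = unname(d[1L]), d_shadow = unname(d[2L]),
       d_static = unname(d[3L]))
}

#' Classify every unassigned click in a session
#'
#' Fills the \code{target} field of all clicks that do not already carry one,
#' interpolating the partner's trajectory at the click time, and returns an
#' ambiguity report listing the flagged assignments with the distances to
#' all candidates. Clicks with pre-filled targets are left untouched and do
#' not appear in the report.
#'
#' @param ds a \code{pc_session} with trajectories (or fully pre-filled
#'   targets).
#' @param cfg an \code{\link{assignment_config}}.
#' @return list with \code{dataset} (targets filled) and \code{report}
#'   (data frame: \code{team_id, trial_number, player, click_time_s,
#'   d_avatar, d_shadow, d_static, assigned, flagged}).
#' @export
classify_session <- function(ds, cfg = assignment_config()) {
  stopifnot(inherits(ds, "pc_session"))
  ev <- ds$events
  todo <- which(is.na(ev$target))
  rep_rows <- vector("list", length(todo))
  if (length(todo) && is.null(ds$trajectories))
    stop("unassignable: clicks without targets and no trajectories; ",
         "run the simulator with trajectories or supply targets")
  for (idx in seq_along(todo)) {
    i <- todo[idx]
    partner <- 3L - ev$player[i]
    tj <- ds$trajectories
    sel <- tj$team_id == ev$team_id[i] & tj$trial_number == ev$trial_number[i] &
      tj$player == partner
    if (!any(sel))
      stop(sprintf("unassignable: no trajectory for team %d trial %d player %d",
                   ev$team_id[i], ev$trial_number[i], partner))
    tjs <- tj[sel, , drop = FALSE]
    tjs <- tjs[order(tjs$time_s), , drop = FALSE]
    pa <- interp_torus(tjs$time_s, tjs$avatar_position, ev$click_time_s[i],
                       ds$world$space_length)
    res <- assign_target(ev$click_position[i], pa,
                         shadow_position(pa, ds$world),
                         ds$world$static_positions[ev$player[i]],
                         ds$world, cfg)
    ev$target[i] <- res$target
    rep_rows[[idx]] <- data.frame(
      team_id = ev$team_id[i], trial_number = ev$trial_number[i],
      player = ev$player[i], click_time_s = ev$click_time_s[i],
      d_avatar = res$d_avatar, d_shadow = res$d_shadow,
      d_static = res$d_static, assigned = res$target,
      flagged = res$flagged, stringsAsFactors = FALSE)
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(team_id = integer(), trial_number = integer(),
               player = integer(), click_time_s = numeric(),
               d_avatar = numeric(), d_shadow = numeric(),
               d_static = numeric(), assigned = character(),
               flagged = logical(), stringsAsFactors = FALSE)
  ds$events <- ev
  list(dataset = ds, report = report[report$flagged, , drop = FALSE],
       full_report = report)
}

#' Sensitivity of outcome counts to the assignment radius
#'
#' Re-runs classification over a grid of \code{max_assign_distance} values
#' and tabulates the headline counts, quantifying how much the choice of
#' radius matters for the reported tables.
#'
#' @param ds a \code{pc_session} with trajectories.
#' @param radii numeric vector of radii to evaluate, in units.
#' @param cfg base \code{\link{assignment_config}}.
#' @return data frame: one row per radius with click/correct/joint counts.
#' @export
classify_sensitivity <- function(ds, radii = c(4, 6, 8, 12, 16),
                                 cfg = assignment_config()) {
  ds$events$target <- NA_character_
  do.call(rbind, lapply(radii, function(r) {
    cfg$max_assign_distance <- r
    cl <- classify_session(ds, cfg)
    cs <- count_summary(trial_outcomes(cl$dataset))
    data.frame(max_assign_distance = r, n_clicks = cs$n_clicks,
               n_correct = cs$n_correct, n_unknown = sum(
                 cl$dataset$events$target == "unknown", na.rm = TRUE),
               n_joint_trials = cs$n_joint_trials,
               n_flagged = nrow(cl$report))
  }))
}
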