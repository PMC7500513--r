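#' Simulate one perceptual-crossing trial
#'
#' Runs the two-player world forward at the configured tick, driving each
#' avatar with a controller function (a behavioural stand-in for a human
#' player). A controller is called once per tick as
#' \code{controller(k, t, sensor, pos)} where \code{k} is the tick index,
#' \code{t} the current time in seconds, \code{sensor} the player's own
#' binary sensor stream up to and including the current tick, and \code{pos}
#' the player's current avatar position. It must return a list with
#' \code{velocity} (displacement in units per tick) and optionally
#' \code{click = TRUE} to emit a click at the current time. Controllers may
#' keep private state through closures.
#'
#' Each player may click at most once per trial; any further click is
#' ignored with a warning. All randomness a controller needs must come from
#' the R random number generator, so that \code{seed} makes the trial
#' reproducible.
#'
#' @param cfg a \code{\link{world_config}}.
#' @param controller_a,controller_b controller functions for players 1 and 2.
#' @param seed integer seed fixing all randomness in the trial.
#' @param init list with optional elements \code{avatars} (length-2 start
#'   positions) and \code{statics} (length-2 static-object positions,
#'   defaulting to the world configuration).
#' @param team_id,trial_number identifiers stored in the returned record.
#' @return a \code{pc_trial} record: identifiers, a trajectory data frame
#'   (\code{time_s, pos1, pos2}), sensor streams, clicks and (empty) PAS
#'   slots, plus the static positions in force.
#' @export
simulate_trial <- function(cfg, controller_a, controller_b, seed,
                           init = list(), team_id = 1L, trial_number = 1L) {
  stopifnot(inherits(cfg, "pc_world"))
  if (!missing(seed)) set.seed(as.integer(seed))
  L <- cfg$space_length
  n <- as.integer(round(cfg$trial_duration / cfg$tick))
  times <- seq(0, by = cfg$tick, length.out = n + 1L)

  avatars <- init$avatars
  if (is.null(avatars)) avatars <- c(0, L / 2)
  statics <- init$statics
  if (is.null(statics)) statics <- cfg$static_positions
  avatars <- wrap_pos(avatars, L)

  pos <- matrix(NA_real_, n + 1L, 2L)
  sens <- matrix(0L, n + 1L, 2L)
  pos[1L, ] <- avatars
  ctrl <- list(controller_a, controller_b)
  clicks <- data.frame(player = integer(), time = numeric(),
                       position = numeric(), target = character(),
                       stringsAsFactors = FALSE)
  clicked <- c(FALSE, FALSE)
  extra_clicks <- 0L

  for (k in seq_len(n + 1L)) {
    p <- pos[k, ]
    sens[k, 1L] <- as.integer(sensor_state(p[1L], p[2L], statics[1L], cfg))
    sens[k, 2L] <- as.integer(sensor_state(p[2L], p[1L], statics[2L], cfg))
    v <- numeric(2L)
    for (m in 1:2) {
      out <- ctrl[[m]](k, times[k], sens[seq_len(k), m], p[m])
      v[m] <- out$velocity
      if (isTRUE(out$click)) {
        if (clicked[m]) {
          extra_clicks <- extra_clicks + 1L
        } else {
          clicked[m] <- TRUE
          clicks <- rbind(clicks, data.frame(
            player = m, time = times[k], position = p[m],
            target = NA_character_, stringsAsFactors = FALSE))
        }
      }
    }
    if (k <= n) pos[k + 1L, ] <- wrap_pos(p + v, L)
  }
  if (extra_clicks > 0L)
    warning(sprintf("ignored %d click(s) beyond the first per player", extra_clicks))

  structure(list(
    team_id = team_id, trial_number = trial_number,
    trajectories = data.frame(time_s = times, pos1 = pos[, 1L], pos2 = pos[, 2L]),
    sensors = data.frame(time_s = times, sens1 = sens[, 1L], sens2 = sens[, 2L]),
    clicks = clicks,
    pas = data.frame(player = integer(), value = integer()),
    statics = statics), class = "pc_trial")
}

#' Basic controllers for simulated trials
#'
#' \code{controller_static} never moves and never clicks.
#' \code{controller_sweep} circles at a constant speed.
#' \code{controller_search_dwell} sweeps until its sensor fires, then
#' oscillates locally around the contact; once contact has been sustained,
#' it clicks with a constant hazard per tick.
#'
#' @param speed sweep speed in units per tick.
#' @param dwell_amplitude half-width of the local oscillation, in units.
#' @param contact_window number of recent ticks over which contact is
#'   integrated before the click hazard becomes active.
#' @param contact_fraction minimum fraction of the window in contact.
#' @param click_hazard per-tick click probability once contact is sustained.
#' @return a controller function (see \code{\link{simulate_trial}}).
#' @name controllers
NULL

#' @rdname controllers
#' @export
controller_static <- function() {
  function(k, t, sensor, pos) list(velocity = 0)
}

#' @rdname controllers
#' @export
controller_sweep <- function(speed = 1) {
  function(k, t, sensor, pos) list(velocity = speed)
}

#' @rdname controllers
#' @export
controller_search_dwell <- function(speed = 1.5, dwell_amplitude = 6,
                                    contact_window = 100,
                                    contact_fraction = 0.3,
                                    click_hazard = 0.01) {
  phase <- 0
  has_clicked <- FALSE
  dir <- sample(c(-1, 1), 1L)
  function(k, t, sensor, pos) {
    n <- length(sensor)
    recent <- sensor[max(1L, n - contact_window + 1L):n]
    frac <- mean(recent)
    click <- FALSE
    if (!has_clicked && frac >= contact_fraction && n >= contact_window) {
      click <- stats::runif(1) < click_hazard
      has_clicked <<- has_clicked || click
    }
    if (sensor[n] == 1L || frac > 0.05) {
      # dwell: small sinusoidal oscillation around the contact point
      phase <<- phase + 0.12
      v <- dwell_amplitude * 0.12 * cos(phase)
    } else {
      v <- dir * speed
    }
    list(velocity = v, click = click)
  }
}

# Recompute both sensor streams from a stored trajectory; used to verify the
# incrementally computed streams.
recompute_sensors <- function(trial, cfg) {
  p1 <- trial$trajectories$pos1
  p2 <- trial$trajectories$pos2
  data.frame(time_s = trial$trajectories$time_s,
             sens1 = as.integer(sensor_state(p1, p2, trial$statics[1L], cfg)),
             sens2 = as.integer(sensor_state(p2, p1, trial$statics[2L], cfg)))
}
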