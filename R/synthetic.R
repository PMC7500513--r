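#' Configuration for the synthetic event-level generator
#'
#' Defines the design sizes and the ground-truth parameters of the
#' generative process. Defaults mirror the study design (10 teams of 2
#' players, 20 trials of 60 s, roughly 80% click rate) and place the path
#' coefficients at the empirically relevant point estimates (joint-success
#' effect on PAS 0.69, delay effects 1.01 and 0.70, individual-success
#' effect -0.16, delay effect on PAS 0.14, breakpoint means 3.2 and 5.1
#' trials). Inter-click delays follow a mixture: with probability
#' \code{p_sync} the two clicks are separated by an Exponential gap with
#' mean \code{sync_mean_gap} seconds, otherwise both click times are
#' independent Uniform(0, trial_duration).
#'
#' @param n_teams,n_trials design size.
#' @param trial_duration trial length in seconds.
#' @param p_click per-player click probability per trial.
#' @param mu_a,sig_a hyper-mean/SD of individual success intercepts.
#' @param mu_b,sig_b hyper-mean/SD of (non-negative) learning slopes.
#' @param mu_tau_s,sig_tau_s hyper-mean/SD of success breakpoints.
#' @param lambda_s delay effect on individual success (probit scale).
#' @param mu_c,sig_c hyper-mean/SD of team joint-success intercepts.
#' @param lambda_g delay effect on joint success.
#' @param sig_u SD of individual PAS intercepts (hyper-mean fixed at 0).
#' @param mu_v,sig_v hyper-mean/SD of (non-negative) PAS learning slopes.
#' @param mu_tau_p,sig_tau_p hyper-mean/SD of PAS breakpoints.
#' @param gamma_s,gamma_g,gamma_d effects of individual success, joint
#'   success and delay on the latent PAS.
#' @param cutpoints ordinal probit cutpoints (length 3, increasing).
#' @param rho residual within-dyad PAS correlation.
#' @param p_sync,sync_mean_gap delay-mixture parameters.
#' @param delay_window dichotomization window in seconds.
#' @param p_pas_missing probability that a click's PAS response is missing.
#' @param joint_mode \code{"derived"}: joint success is 1 iff both players
#'   clicked correctly (consistent with what the event tables encode);
#'   \code{"submodel"}: joint success is drawn from its own probit submodel
#'   (the exact generative counterpart of the fitted path model, used for
#'   parameter recovery).
#' @return a list of class \code{pc_syncfg}.
#' @export
synthetic_config <- function(n_teams = 10, n_trials = 20, trial_duration = 60,
                             p_click = 0.8,
                             mu_a = 0.25, sig_a = 0.4,
                             mu_b = 0.15, sig_b = 0.1,
                             mu_tau_s = 3.2, sig_tau_s = 1.5,
                             lambda_s = 0.70,
                             mu_c = -0.4, sig_c = 0.4,
                             lambda_g = 1.01,
                             sig_u = 0.4,
                             mu_v = 0.12, sig_v = 0.08,
                             mu_tau_p = 5.1, sig_tau_p = 2,
                             gamma_s = -0.16, gamma_g = 0.69, gamma_d = 0.14,
                             cutpoints = c(-1.3, 0.3, 1.25),
                             rho = 0.1,
                             p_sync = 0.2, sync_mean_gap = 1.5,
                             delay_window = 3, p_pas_missing = 0.013,
                             joint_mode = c("derived", "submodel")) {
  joint_mode <- match.arg(joint_mode)
  stopifnot(p_click >= 0, p_click <= 1, p_sync >= 0, p_sync <= 1,
            p_pas_missing >= 0, p_pas_missing < 1,
            all(diff(cutpoints) > 0), abs(rho) < 1,
            mu_b >= 0, mu_v >= 0, mu_tau_s >= 1, mu_tau_p >= 1,
            n_teams >= 1, n_trials >= 1, trial_duration > 0,
            sync_mean_gap > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "pc_syncfg")
}

rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(pmax(mean, 0), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

rtnorm_range <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# draw the two click times of a both-click trial from the sync mixture
draw_click_pair <- function(cfg) {
  T <- cfg$trial_duration
  if (stats::runif(1) < cfg$p_sync) {
    gap <- stats::rexp(1, rate = 1 / cfg$sync_mean_gap)
    if (gap < T) {
      t1 <- stats::runif(1, 0, T - gap)
      ts <- c(t1, t1 + gap)
      if (stats::runif(1) < 0.5) ts <- rev(ts)
      return(ts)
    }
  }
  stats::runif(2, 0, T)
}

#' Closed-form mixture probability of a sub-threshold delay
#'
#' Probability that the inter-click delay of a both-click trial falls below
#' \code{d} under the generator's mixture: synchronized pairs have an
#' Exponential(mean \code{sync_mean_gap}) gap, independent pairs follow the
#' uniform-difference null.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param d threshold in seconds.
#' @return probability.
#' @export
sync_mixture_prob <- function(cfg, d = cfg$delay_window) {
  T <- cfg$trial_duration
  p_exp <- stats::pexp(d, 1 / cfg$sync_mean_gap)
  # exponential gaps >= T fall back to the uniform pair
  p_long <- stats::pexp(T, 1 / cfg$sync_mean_gap, lower.tail = FALSE)
  cfg$p_sync * (p_exp + p_long * null_interval_cdf(d, T)) +
    (1 - cfg$p_sync) * null_interval_cdf(d, T)
}

#' Generate an event-level synthetic session
#'
#' Draws a trajectory-free session directly from the path model's
#' generative process: clicks per player with probability \code{p_click},
#' click times from the delay mixture, individual success from the
#' piecewise probit with the delay effect, joint success either derived
#' (both correct) or from its own probit submodel, and PAS from the ordinal
#' probit given success, joint success and delay, with dyad-correlated
#' latent residuals. Incorrect clicks are attributed to the shadow, static
#' or unknown targets with fixed odds.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param seed integer seed.
#' @return list of class \code{pc_synth}: \code{dataset} (a trajectory-free
#'   \code{pc_session}), \code{truth} (all drawn team/individual parameters
#'   and the configuration), and \code{model_data} (a
#'   \code{\link{pc_model_data}} whose joint-success column is the
#'   generator's own G, which under \code{joint_mode = "submodel"} is the
#'   quantity the fitted model describes).
#' @export
generate_events <- function(cfg = synthetic_config(), seed = 1L) {
  stopifnot(inherits(cfg, "pc_syncfg"))
  set.seed(as.integer(seed))
  J <- cfg$n_teams; Tn <- cfg$n_trials
  NI <- 2L * J
  a <- stats::rnorm(NI, cfg$mu_a, cfg$sig_a)
  b <- rtnorm_pos(NI, cfg$mu_b, cfg$sig_b)
  tau_s <- rtnorm_range(NI, cfg$mu_tau_s, cfg$sig_tau_s, 1, Tn)
  u <- stats::rnorm(NI, 0, cfg$sig_u)
  v <- rtnorm_pos(NI, cfg$mu_v, cfg$sig_v)
  tau_p <- rtnorm_range(NI, cfg$mu_tau_p, cfg$sig_tau_p, 1, Tn)
  cj <- stats::rnorm(J, cfg$mu_c, cfg$sig_c)

  n_max <- 2L * J * Tn
  E <- list(team = integer(n_max), trial = integer(n_max),
            player = integer(n_max), time = numeric(n_max),
            pos = numeric(n_max), target = character(n_max),
            pas = integer(n_max), S = integer(n_max), G = integer(n_max),
            D = integer(n_max))
  TRL <- list(team = integer(J * Tn), trial = integer(J * Tn),
              G = integer(J * Tn), D = integer(J * Tn))
  ne <- 0L; nt <- 0L
  wrong_targets <- c("shadow", "static", "unknown")
  wrong_probs <- c(0.5, 0.35, 0.15)
  for (j in seq_len(J)) {
    for (t in seq_len(Tn)) {
      clicked <- stats::runif(2) < cfg$p_click
      times <- rep(NA_real_, 2)
      if (all(clicked)) {
        times <- draw_click_pair(cfg)
      } else if (any(clicked)) {
        times[clicked] <- stats::runif(1, 0, cfg$trial_duration)
      }
      D <- as.integer(all(clicked) &&
                        abs(times[1] - times[2]) < cfg$delay_window)
      S <- rep(NA_integer_, 2)
      for (m in 1:2) {
        if (!clicked[m]) next
        i <- 2L * (j - 1L) + m
        eta <- piecewise_predictor(t, tau_s[i], a[i], b[i]) + cfg$lambda_s * D
        S[m] <- as.integer(stats::runif(1) < stats::pnorm(eta))
      }
      G <- if (cfg$joint_mode == "submodel") {
        as.integer(stats::runif(1) < stats::pnorm(cj[j] + cfg$lambda_g * D))
      } else {
        as.integer(all(clicked) && all(S[clicked] == 1L))
      }
      # PAS latent residuals: correlated within the dyad when both clicked
      e <- stats::rnorm(2)
      if (all(clicked)) e[2] <- cfg$rho * e[1] + sqrt(1 - cfg$rho^2) * e[2]
      for (m in 1:2) {
        if (!clicked[m]) next
        i <- 2L * (j - 1L) + m
        eta_y <- piecewise_predictor(t, tau_p[i], u[i], v[i]) +
          cfg$gamma_s * S[m] + cfg$gamma_g * G + cfg$gamma_d * D
        z <- eta_y + e[m]
        Y <- 1L + sum(z > cfg$cutpoints)
        pas <- if (stats::runif(1) < cfg$p_pas_missing) NA_integer_ else Y
        target <- if (S[m] == 1L) "other_avatar" else
          sample(wrong_targets, 1L, prob = wrong_probs)
        ne <- ne + 1L
        E$team[ne] <- j; E$trial[ne] <- t; E$player[ne] <- m
        E$time[ne] <- round(times[m], 3)
        E$pos[ne] <- round(stats::runif(1, 0, 600), 6)
        E$target[ne] <- target; E$pas[ne] <- pas
        E$S[ne] <- S[m]; E$G[ne] <- G; E$D[ne] <- D
      }
      nt <- nt + 1L
      TRL$team[nt] <- j; TRL$trial[nt] <- t; TRL$G[nt] <- G; TRL$D[nt] <- D
    }
  }
  sel <- seq_len(ne)
  events <- if (ne) data.frame(
    team_id = E$team[sel], trial_number = E$trial[sel], player = E$player[sel],
    click_time_s = E$time[sel], click_position = E$pos[sel],
    target = E$target[sel], pas = E$pas[sel], stringsAsFactors = FALSE)
  else empty_events()
  trials <- expand.grid(trial_number = seq_len(Tn), team_id = seq_len(J))
  trials <- trials[, c("team_id", "trial_number")]
  ds <- session_dataset(events, trials, world_config())
  md <- structure(list(
    obs = data.frame(team = E$team[sel], player = E$player[sel],
                     individual = 2L * (E$team[sel] - 1L) + E$player[sel],
                     trial = E$trial[sel], S = E$S[sel], G = E$G[sel],
                     D = E$D[sel], Y = E$pas[sel]),
    trials = data.frame(team = TRL$team, trial = TRL$trial,
                        G = TRL$G, D = TRL$D),
    n_teams = J, n_individuals = NI, t_max = Tn,
    team_levels = seq_len(J)), class = "pc_model_data")
  truth <- list(config = cfg, seed = as.integer(seed),
                a = a, b = b, tau_s = tau_s, u = u, v = v, tau_p = tau_p,
                c = cj)
  structure(list(dataset = ds, truth = truth, model_data = md),
            class = "pc_synth")
}

#' Generate a behavioural synthetic session with trajectories
#'
#' Runs the trial simulator with stochastic search-and-dwell controllers
#' for both players: each sweeps the circle until its sensor fires, then
#' dwells, and clicks with a constant hazard once contact has been
#' sustained. Produces full avatar trajectories, click events with the
#' generator's own ground-truth targets (computed from the true, not
#' interpolated, geometry at the click), and PAS responses drawn from the
#' ordinal submodel given the realised success pattern. Suitable for
#' end-to-end tests of classification, descriptives and fitting.
#'
#' @param cfg a \code{\link{synthetic_config}} (design sizes and PAS
#'   parameters are used; the click mixture is replaced by the behavioural
#'   click hazard).
#' @param world a \code{\link{world_config}}.
#' @param seed integer seed.
#' @param click_hazard per-tick click probability under sustained contact;
#'   0 disables clicking entirely.
#' @param store_every store every k-th trajectory sample (thinning of the
#'   native tick for output size).
#' @return list of class \code{pc_synth}: \code{dataset} (with
#'   trajectories; click targets left unassigned), \code{truth} (including
#'   per-click \code{true_targets}), and \code{model_data} built from the
#'   true targets.
#' @export
generate_behavioral <- function(cfg = synthetic_config(), world = world_config(),
                                seed = 1L, click_hazard = 0.012,
                                store_every = 5L) {
  stopifnot(inherits(cfg, "pc_syncfg"))
  set.seed(as.integer(seed))
  J <- cfg$n_teams; Tn <- cfg$n_trials
  NI <- 2L * J
  u <- stats::rnorm(NI, 0, cfg$sig_u)
  v <- rtnorm_pos(NI, cfg$mu_v, cfg$sig_v)
  tau_p <- rtnorm_range(NI, cfg$mu_tau_p, cfg$sig_tau_p, 1, Tn)

  ev_rows <- list(); tj_rows <- list(); truth_rows <- list()
  for (j in seq_len(J)) {
    for (t in seq_len(Tn)) {
      trial_seed <- (as.integer(seed) %% 10000L) * 100000L +
        (j - 1L) * 100L + t
      set.seed(trial_seed)
      init <- list(avatars = stats::runif(2, 0, world$space_length))
      rec <- simulate_trial(world,
                            controller_search_dwell(click_hazard = click_hazard),
                            controller_search_dwell(click_hazard = click_hazard),
                            seed = trial_seed, init = init,
                            team_id = j, trial_number = t)
      keep <- seq(1L, nrow(rec$trajectories), by = store_every)
      if (keep[length(keep)] != nrow(rec$trajectories))
        keep <- c(keep, nrow(rec$trajectories))
      tj <- rec$trajectories[keep, ]
      tj_rows[[length(tj_rows) + 1L]] <- data.frame(
        team_id = j, trial_number = t,
        time_s = rep(round(tj$time_s, 3), 2L),
        player = rep(1:2, each = nrow(tj)),
        avatar_position = round(c(tj$pos1, tj$pos2), 6))
      if (!nrow(rec$clicks)) next
      # true targets from the exact simulator state at the click tick
      cl <- rec$clicks
      truth_target <- character(nrow(cl))
      for (r in seq_len(nrow(cl))) {
        m <- cl$player[r]
        kt <- which.min(abs(rec$trajectories$time_s - cl$time[r]))
        partner <- rec$trajectories[kt, c("pos1", "pos2")][[3L - m]]
        res <- assign_target(cl$position[r], partner,
                             shadow_position(partner, world),
                             rec$statics[m], world)
        truth_target[r] <- res$target
      }
      S <- rep(NA_integer_, 2)
      times <- rep(NA_real_, 2)
      for (r in seq_len(nrow(cl))) {
        S[cl$player[r]] <- as.integer(truth_target[r] == "other_avatar")
        times[cl$player[r]] <- cl$time[r]
      }
      both <- !anyNA(times)
      D <- as.integer(both && abs(times[1] - times[2]) < cfg$delay_window)
      G <- as.integer(both && all(S == 1L, na.rm = FALSE))
      e <- stats::rnorm(2)
      if (both) e[2] <- cfg$rho * e[1] + sqrt(1 - cfg$rho^2) * e[2]
      for (r in seq_len(nrow(cl))) {
        m <- cl$player[r]
        i <- 2L * (j - 1L) + m
        eta_y <- piecewise_predictor(t, tau_p[i], u[i], v[i]) +
          cfg$gamma_s * S[m] + cfg$gamma_g * G + cfg$gamma_d * D
        Y <- 1L + sum(eta_y + e[m] > cfg$cutpoints)
        pas <- if (stats::runif(1) < cfg$p_pas_missing) NA_integer_ else Y
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          team_id = j, trial_number = t, player = m,
          click_time_s = round(cl$time[r], 3),
          click_position = round(cl$position[r], 6),
          target = NA_character_, pas = pas, stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          team_id = j, trial_number = t, player = m,
          true_target = truth_target[r], S = S[m], G = G, D = D)
      }
    }
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else empty_events()
  trials <- expand.grid(trial_number = seq_len(Tn), team_id = seq_len(J))
  trials <- trials[, c("team_id", "trial_number")]
  ds <- session_dataset(events, trials, world,
                        do.call(rbind, tj_rows))
  truth <- list(config = cfg, seed = as.integer(seed),
                true_targets = if (length(truth_rows))
                  do.call(rbind, truth_rows) else NULL,
                u = u, v = v, tau_p = tau_p)
  # model data from the true targets
  ds_true <- ds
  if (nrow(events)) {
    key_ev <- paste(events$team_id, events$trial_number, events$player)
    tt <- truth$true_targets
    key_tt <- paste(tt$team_id, tt$trial_number, tt$player)
    ds_true$events$target <- tt$true_target[match(key_ev, key_tt)]
  }
  md <- pc_model_data(ds_true, delay_window = cfg$delay_window)
  structure(list(dataset = ds, truth = truth, model_data = md),
            class = "pc_synth")
}
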