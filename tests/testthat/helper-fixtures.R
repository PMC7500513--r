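# Hand-built fixture: 2 teams x 3 trials, 5 clicks.
# team 1 trial 1: both click correctly (joint success), PAS 4 and 3
# team 1 trial 2: player 1 clicks the shadow (wrong), PAS 2
# team 1 trial 3: nobody clicks
# team 2 trial 1: both click, player 2 wrong (static), PAS 3 / 1
# team 2 trials 2-3: nobody clicks
tiny_session <- function() {
  events <- data.frame(
    team_id = c(1L, 1L, 1L, 2L, 2L),
    trial_number = c(1L, 1L, 2L, 1L, 1L),
    player = c(1L, 2L, 1L, 1L, 2L),
    click_time_s = c(10.0, 12.9, 30.5, 5.0, 13.0),
    click_position = c(100, 250, 400, 50, 580),
    target = c("other_avatar", "other_avatar", "shadow",
               "other_avatar", "static"),
    pas = c(4L, 3L, 2L, 3L, 1L),
    stringsAsFactors = FALSE)
  trials <- expand.grid(trial_number = 1:3, team_id = 1:2)[, 2:1]
  session_dataset(events, trials, world_config())
}

# small random event-level session for round-trip properties
random_session <- function(seed, n_teams = 2, n_trials = 4) {
  cfg <- synthetic_config(n_teams = n_teams, n_trials = n_trials)
  generate_events(cfg, seed = seed)$dataset
}

# one shared small fitted model for structural tests (cached per session)
small_fit_cache <- new.env(parent = emptyenv())
small_fit <- function() {
  if (is.null(small_fit_cache$fit)) {
    syn <- generate_events(synthetic_config(n_teams = 6,
                                            joint_mode = "submodel"),
                           seed = 301)
    small_fit_cache$syn <- syn
    small_fit_cache$fit <- pc_fit(
      syn$model_data,
      mcmc = pc_mcmc_config(chains = 2, adapt = 150, burnin = 150,
                            iterations = 300),
      seed = 302)
  }
  small_fit_cache$fit
}
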