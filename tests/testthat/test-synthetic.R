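test_that("certain clicking and success yield universally joint trials", {
  cfg <- synthetic_config(n_teams = 3, p_click = 1, mu_a = 8, sig_a = 0,
                          mu_b = 0, sig_b = 0, p_pas_missing = 0)
  syn <- generate_events(cfg, seed = 91)
  out <- trial_outcomes(syn$dataset)
  expect_true(all(out$joint_success))
  expect_equal(count_summary(out)$n_clicks, 2 * nrow(out))
})

test_that("with null PAS effects the PAS distribution ignores success", {
  # flat learning curves: otherwise success and PAS share the trial trend
  # and are marginally dependent even without any direct link
  cfg <- synthetic_config(n_teams = 350, n_trials = 15, p_click = 1,
                          gamma_s = 0, gamma_g = 0, gamma_d = 0,
                          mu_b = 0, sig_b = 0, mu_v = 0, sig_v = 0,
                          p_pas_missing = 0)
  syn <- generate_events(cfg, seed = 93)
  obs <- syn$model_data$obs
  expect_gte(nrow(obs), 1e4)
  tab <- table(obs$S, obs$Y)
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
  # and with the default (non-null) effects the dependence is visible
  synd <- generate_events(synthetic_config(n_teams = 350, n_trials = 15,
                                           p_click = 1, mu_b = 0, sig_b = 0,
                                           mu_v = 0, sig_v = 0,
                                           p_pas_missing = 0), seed = 94)
  obsd <- synd$model_data$obs
  expect_lt(suppressWarnings(chisq.test(table(obsd$S, obsd$Y)))$p.value, 0.01)
})

test_that("the sub-3-s delay fraction matches the mixture closed form", {
  cfg <- synthetic_config(n_teams = 1000)
  syn <- generate_events(cfg, seed = 95)
  out <- trial_outcomes(syn$dataset)
  expect_gte(nrow(out), 1e4)
  both <- out$both_clicked
  frac <- mean(out$interclick_interval[both] < 3)
  expect_equal(frac, sync_mixture_prob(cfg, 3), tolerance = 0.01)
})

test_that("generation is seed-deterministic down to the written bytes", {
  cfg <- synthetic_config(n_teams = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(generate_events(cfg, seed = 97)$dataset, d1, "csv")
  write_session(generate_events(cfg, seed = 97)$dataset, d2, "csv")
  expect_identical(readLines(file.path(d1, "events.csv")),
                   readLines(file.path(d2, "events.csv")))
  b1 <- generate_behavioral(synthetic_config(n_teams = 1, n_trials = 2),
                            world_config(trial_duration = 5), seed = 98)
  b2 <- generate_behavioral(synthetic_config(n_teams = 1, n_trials = 2),
                            world_config(trial_duration = 5), seed = 98)
  expect_identical(b1$dataset$events, b2$dataset$events)
  expect_identical(b1$dataset$trajectories, b2$dataset$trajectories)
})

test_that("marginal click and consolidation success rates match closed forms", {
  # homogeneous individuals (zero hierarchy SDs) make the probit closed-form
  # exact at each delay state
  cfg <- synthetic_config(n_teams = 400, p_click = 0.8, sig_a = 0, sig_b = 0,
                          sig_tau_s = 0, p_pas_missing = 0)
  syn <- generate_events(cfg, seed = 99)
  obs <- syn$model_data$obs
  expect_equal(nrow(obs) / (2 * 400 * 20), cfg$p_click, tolerance = 0.01)
  consol <- obs$trial >= ceiling(cfg$mu_tau_s)
  for (d in 0:1) {
    sel <- consol & obs$D == d
    expected <- pnorm(cfg$mu_a + cfg$mu_b * (cfg$mu_tau_s - 1) +
                        cfg$lambda_s * d)
    expect_equal(mean(obs$S[sel]), expected, tolerance = 0.02)
  }
})

test_that("a zero click hazard produces a clickless behavioural session", {
  syn <- generate_behavioral(synthetic_config(n_teams = 1, n_trials = 2),
                             world_config(trial_duration = 5), seed = 101,
                             click_hazard = 0)
  expect_equal(nrow(syn$dataset$events), 0)
  expect_gt(nrow(syn$dataset$trajectories), 0)
})

test_that("behavioural ground truth matches classification on most clicks", {
  syn <- generate_behavioral(synthetic_config(n_teams = 3, n_trials = 5),
                             seed = 103)
  expect_gt(nrow(syn$dataset$events), 5)
  cl <- classify_session(syn$dataset)
  key <- function(df) paste(df$team_id, df$trial_number, df$player)
  tt <- syn$truth$true_targets
  assigned <- cl$dataset$events$target[match(key(tt), key(cl$dataset$events))]
  expect_gt(mean(assigned == tt$true_target), 0.9)
})
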