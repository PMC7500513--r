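test_that("inter-click intervals and the 3-s indicator use a strict boundary", {
  ds <- tiny_session()
  out <- trial_outcomes(ds)
  t11 <- out[out$team_id == 1 & out$trial_number == 1, ]
  expect_equal(t11$interclick_interval, 2.9)
  expect_equal(t11$delay_indicator, 1L)
  # team 2 trial 1: clicks at 5.0 and 13.0 -> interval 8, indicator 0
  t21 <- out[out$team_id == 2 & out$trial_number == 1, ]
  expect_equal(t21$interclick_interval, 8)
  expect_equal(t21$delay_indicator, 0L)
  # exactly 3.0 s apart is not "within 3 s"
  ds2 <- ds
  ds2$events$click_time_s[ds2$events$team_id == 1 &
                            ds2$events$player == 2][1] <- 13.0
  out2 <- trial_outcomes(ds2)
  expect_equal(out2$delay_indicator[out2$team_id == 1 &
                                      out2$trial_number == 1], 0L)
  # a lone click has no interval and indicator 0
  t12 <- out[out$team_id == 1 & out$trial_number == 2, ]
  expect_true(is.na(t12$interclick_interval))
  expect_equal(t12$delay_indicator, 0L)
})

test_that("the delay indicator is monotone in the window", {
  syn <- generate_events(synthetic_config(n_teams = 4), seed = 17)
  o3 <- trial_outcomes(syn$dataset, delay_window = 3)
  o6 <- trial_outcomes(syn$dataset, delay_window = 6)
  expect_true(all(o6$delay_indicator >= o3$delay_indicator))
})

test_that("count summary reproduces a hand count and its identities", {
  out <- trial_outcomes(tiny_session())
  cs <- count_summary(out)
  expect_equal(cs$n_trials, 6)
  expect_equal(cs$n_possible_clicks, 12)
  expect_equal(cs$n_clicks, 5)
  expect_equal(cs$n_correct, 3)
  expect_equal(cs$n_joint_trials, 1)
  expect_equal(cs$n_bothclick_nonjoint_trials, 1)
  expect_equal(cs$n_pas, 5)
  expect_equal(cs$n_joint_trials + cs$n_bothclick_nonjoint_trials,
               sum(out$both_clicked))
})

test_that("count summary is invariant to trial order", {
  syn <- generate_events(synthetic_config(n_teams = 3), seed = 23)
  out <- trial_outcomes(syn$dataset)
  set.seed(1); perm <- out[sample(nrow(out)), ]
  cs1 <- count_summary(out); cs2 <- count_summary(perm)
  expect_equal(cs1[1:7], cs2[1:7])
  expect_equal(cs1$pas_overall, cs2$pas_overall)
})

test_that("conditional PAS tables partition the clicked-with-PAS cases", {
  syn <- generate_events(synthetic_config(), seed = 29)
  out <- trial_outcomes(syn$dataset)
  total <- pas_crosstab(out, "all")
  parts <- pas_crosstab(out, "incorrect") +
    pas_crosstab(out, "correct_nonjoint") +
    pas_crosstab(out, "correct_joint")
  expect_equal(parts, total)
  expect_equal(sum(total), count_summary(out)$n_pas)
})

test_that("degenerate PAS data concentrates in one category", {
  ds <- tiny_session()
  ds$events$pas <- 4L
  out <- trial_outcomes(ds)
  expect_equal(pas_crosstab(out, "all"), c(0, 0, 0, 5))
})

test_that("the uniform-independence null CDF has its closed form", {
  expect_equal(null_interval_cdf(0), 0)
  expect_equal(null_interval_cdf(60), 1)
  expect_equal(null_interval_cdf(3, 60), 1 - (57 / 60)^2)
  expect_error(null_interval_cdf(-1), "\\[0, T\\]")
  expect_error(null_interval_cdf(61), "\\[0, T\\]")
})

test_that("interval density integrates to one and matches the null", {
  set.seed(47)
  iv <- abs(runif(10000, 0, 60) - runif(10000, 0, 60))
  est <- interval_density(iv, T = 60, threshold = 3)
  dx <- est$x[2] - est$x[1]
  mass <- sum((est$density[-1] + est$density[-length(est$density)]) / 2) * dx
  expect_equal(mass, 1, tolerance = 1e-6)
  expect_equal(est$p_below, null_interval_cdf(3, 60), tolerance = 0.02)
})

test_that("interval density flags degenerate and undersized inputs", {
  expect_error(interval_density(c(1, 2, 3)), "too few")
  est <- interval_density(rep(10, 50), T = 60, bandwidth = 0.2)
  expect_gt(sum(est$density[est$x > 9 & est$x < 11]) /
              sum(est$density), 0.99)
  p_lo <- interval_density(rep(10, 50), T = 60, bandwidth = 0.2,
                           threshold = 5)$p_below
  p_hi <- interval_density(rep(10, 50), T = 60, bandwidth = 0.2,
                           threshold = 15)$p_below
  expect_lt(p_lo, 0.01)
  expect_gt(p_hi, 0.99)
})

test_that("team scores add one per correct and subtract one per wrong click", {
  out <- trial_outcomes(tiny_session())
  sc <- team_score(out)
  # team 1: 2 correct + 1 wrong = 1; team 2: 1 correct + 1 wrong = 0
  expect_equal(unname(sc), c(1, 0))
  # all-correct and no-click extremes
  ds <- tiny_session()
  ds$events$target <- "other_avatar"
  expect_equal(unname(team_score(trial_outcomes(ds))), c(3, 2))
  ds0 <- session_dataset(empty_events(),
                         data.frame(team_id = 1L, trial_number = 1:2))
  out0 <- trial_outcomes(ds0)
  expect_equal(length(team_score(out0)), 1)
  expect_equal(unname(team_score(out0)), 0)
})

test_that("outcomes refuse unassigned targets", {
  ds <- tiny_session()
  ds$events$target[1] <- NA_character_
  expect_error(trial_outcomes(ds), "classify_session")
})
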