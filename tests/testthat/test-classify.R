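test_that("assignment picks the nearest felt object within the radius", {
  w <- world_config()
  # clicker sits on the partner avatar; everything else far away
  r <- assign_target(100, 100, shadow_position(100, w), 300, w)
  expect_equal(r$target, "other_avatar")
  expect_false(r$flagged)
  # all candidates beyond the radius
  r <- assign_target(0, 100, 250, 300, w)
  expect_equal(r$target, "unknown")
})

test_that("near-ties are assigned by distance but flagged as ambiguous", {
  w <- world_config(shadow_offset = 593.5)  # shadow lands 3.5 behind the click
  # partner avatar 3.0 ahead of the click, its shadow 3.5 behind it
  expect_equal(shadow_position(3, w), 596.5)
  r <- assign_target(0, 3, shadow_position(3, w), 300, w)
  expect_equal(r$target, "other_avatar")
  expect_true(r$flagged)
  # brute-force nearest-candidate oracle over the constructed state
  d <- c(torus_distance(0, 3, 600), torus_distance(0, 596.5, 600),
         torus_distance(0, 300, 600))
  expect_equal(r$target, c("other_avatar", "shadow", "static")[which.min(d)])
  expect_equal(sort(d)[2] - sort(d)[1] < 2, r$flagged)
})

test_that("assignment is rotation- and relabeling-invariant", {
  w <- world_config()
  set.seed(41)
  for (r in 1:50) {
    click <- runif(1, 0, 600); pa <- runif(1, 0, 600); st <- runif(1, 0, 600)
    shift <- runif(1, 0, 600)
    a1 <- assign_target(click, pa, shadow_position(pa, w), st, w)
    a2 <- assign_target((click + shift) %% 600, (pa + shift) %% 600,
                        shadow_position((pa + shift) %% 600, w),
                        (st + shift) %% 600, w)
    expect_equal(a1$target, a2$target)
    expect_equal(a1$flagged, a2$flagged)
  }
})

test_that("candidates never include the clicker's own avatar or shadow", {
  w <- world_config()
  # partner objects and own static all very far; the clicker's own shadow
  # anchor (click + 150) must not attract the assignment
  r <- assign_target(100, 400, shadow_position(400, w), 320, w)
  expect_equal(r$target, "unknown")
})

test_that("pre-filled targets are left untouched with an empty report", {
  ds <- tiny_session()
  res <- classify_session(ds)
  expect_identical(res$dataset$events$target, ds$events$target)
  expect_equal(nrow(res$full_report), 0)
})

test_that("classification recovers a simulated static-object click", {
  w <- world_config(trial_duration = 4, static_positions = c(100, 400))
  # player 2 parks far away; player 1 sweeps into its own static object and
  # clicks while overlapping it
  clicked <- FALSE
  clicker <- function() function(k, t, sensor, pos) {
    click <- FALSE
    if (!clicked && sensor[length(sensor)] == 1L) {
      click <- TRUE; clicked <<- TRUE
    }
    list(velocity = if (sensor[length(sensor)] == 1L) 0 else 1, click = click)
  }
  rec <- simulate_trial(w, clicker(), controller_static(), seed = 8,
                        init = list(avatars = c(60, 250)))
  expect_equal(nrow(rec$clicks), 1)
  keep <- seq(1, nrow(rec$trajectories), by = 5)
  tj <- data.frame(team_id = 1L, trial_number = 1L,
                   time_s = rep(rec$trajectories$time_s[keep], 2),
                   player = rep(1:2, each = length(keep)),
                   avatar_position = c(rec$trajectories$pos1[keep],
                                       rec$trajectories$pos2[keep]))
  ev <- data.frame(team_id = 1L, trial_number = 1L, player = 1L,
                   click_time_s = rec$clicks$time,
                   click_position = rec$clicks$position,
                   target = NA_character_, pas = 3L)
  ds <- session_dataset(ev, data.frame(team_id = 1L, trial_number = 1L), w, tj)
  res <- classify_session(ds)
  expect_equal(res$dataset$events$target, "static")
  expect_false(res$full_report$flagged[1])
})

test_that("classification needs trajectories when targets are missing", {
  ds <- tiny_session()
  ds$events$target <- NA_character_
  expect_error(classify_session(ds), "unassignable")
})

test_that("radius sensitivity report tabulates counts over radii", {
  syn <- generate_behavioral(synthetic_config(n_teams = 2, n_trials = 3),
                             seed = 5)
  sens <- classify_sensitivity(syn$dataset, radii = c(4, 8, 16))
  expect_equal(nrow(sens), 3)
  # unknown assignments cannot increase with a larger radius
  expect_true(all(diff(sens$n_unknown) <= 0))
})
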