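cfgE <- engine_config(rng_seed = 1)
tank <- tank_geometry()

test_that("move_arm uses the shortest arc", {
  expect_equal(move_arm(0, 180, 90)$duration, 2)
  expect_equal(move_arm(350, 10, 20)$duration, 1)
  same <- move_arm(90, 90, 90)
  expect_equal(same$duration, 0)
  expect_equal(same$events$kind, c("arm_move_start", "arm_move_end"))
  # brute-force shortest-arc oracle over both directions
  set.seed(1)
  for (i in 1:50) {
    a <- runif(1, 0, 360); b <- runif(1, 0, 360)
    cw <- (b - a) %% 360; ccw <- (a - b) %% 360
    expect_equal(move_arm(a, b, 30)$duration, min(cw, ccw) / 30)
  }
})

test_that("operant rep without a trigger: window spans the response window, no feed", {
  tpl <- quick_operant(response_window = 3)
  res <- run_rep(tpl, tank, list(still_agent()), cfgE, seed = 5)
  ev <- res$events
  expect_equal(sum(ev$kind == "feed"), 0)
  expect_false(res$fed)
  expect_equal(res$success, 0L)
  wo <- ev$t[ev$kind == "window_open"]
  wc <- ev$t[ev$kind == "window_close"]
  so <- ev$t[ev$kind == "stimulus_on"][1]
  expect_equal(wo, so)
  expect_equal(wc - wo, tpl$response_window)
  expect_equal(ev$t[ev$kind == "record_stop"], wc + tpl$record_end_delay)
})

test_that("operant rep with a beam crossing feeds within the latency contract", {
  # straight-line swimmer aimed at sensor s1 (disc at (12, 0), r = 2);
  # starting 8 cm from center it crosses the beam edge at t = 0.5 s after
  # the window opens at t = 1 s... place so the crossing falls mid-window
  tpl <- quick_operant(response_window = 3)
  ag <- scripted_agent(position = c(4, 0), heading = 0, speed = 4)
  res <- run_rep(tpl, tank, list(ag), cfgE, seed = 5)
  expect_equal(res$success, 1L)
  ev <- res$events
  t_feed <- ev$t[ev$kind == "feed"]
  t_trig <- min(ev$t[ev$kind == "sensor_high" &
                       grepl("sensor_id=s1", ev$payload) &
                       ev$t >= res$window["open"]])
  expect_lte(t_feed - t_trig, 1)
  expect_equal(unname(t_feed - t_trig), cfgE$feed_latency)
  expect_equal(ev$t[ev$kind == "record_stop"], t_feed + tpl$record_end_delay)
  expect_equal(res$trigger_latency, t_trig - res$sound_onset)
})

test_that("classical rep feeds at the fixed delay regardless of behavior", {
  tpl <- quick_classical(food_delay = 3, record_end_delay = 5)
  res <- run_rep(tpl, tank, list(still_agent()), cfgE, seed = 9)
  ev <- res$events
  expect_equal(ev$t[ev$kind == "feed"], 3)
  expect_equal(ev$t[ev$kind == "record_stop"], 3 + 5)
  expect_true(res$fed)
  expect_true(is.na(res$success))
})

test_that("a feed requested mid-arm-move waits for the arm and is flagged", {
  tpl <- rep_template("classical", list(quick_sound()), baseline_delay = 1,
                      food_delay = 1, arm_angle = 180, arm_speed = 20,
                      record_end_delay = 1)
  res <- run_rep(tpl, tank, list(still_agent()), cfgE, seed = 1,
                 arm_start_angle = 0)   # 180 deg at 20 deg/s = 9 s move
  ev <- res$events
  expect_equal(ev$t[ev$kind == "feed"], 9)
  expect_match(ev$payload[ev$kind == "feed"], "warning=arm_moving")
  expect_equal(ev$t[ev$kind == "arm_move_end"], 9)
})

test_that("event logs are canonical: one record_start/stop, nondecreasing t", {
  for (seed in 1:5) {
    res <- run_rep(quick_operant(), tank,
                   list(trained_agent(seed = seed)), cfgE, seed = seed)
    ev <- res$events
    expect_equal(sum(ev$kind == "record_start"), 1)
    expect_equal(sum(ev$kind == "record_stop"), 1)
    expect_equal(ev$t[1], 0)
    expect_equal(ev$kind[1], "rep_start")
    expect_equal(ev$kind[nrow(ev)], "rep_end")
    expect_true(all(diff(ev$t) >= 0))
    expect_true(all(ev$t >= 0))
  }
})

test_that("identical (inputs, seed) give identical logs and trajectories", {
  a <- run_rep(quick_operant(), tank, list(trained_agent()), cfgE, seed = 77)
  b <- run_rep(quick_operant(), tank, list(trained_agent()), cfgE, seed = 77)
  expect_identical(a$events, b$events)
  expect_identical(a$trajectory, b$trajectory)
  c <- run_rep(quick_operant(), tank, list(trained_agent()), cfgE, seed = 78)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("trajectory length tracks rep duration at the frame rate", {
  for (seed in 1:5) {
    res <- run_rep(quick_operant(), tank, list(trained_agent(seed = seed)),
                   cfgE, seed = seed)
    n_frames <- nrow(res$trajectory)
    expect_lte(abs(n_frames - ceiling(res$duration * cfgE$frame_rate)), 1)
  }
})

test_that("an empty agent list is an error", {
  expect_error(run_rep(quick_operant(), tank, list(), cfgE), "empty")
})

test_that("run_trial executes the preset day in order and persists one file per rep", {
  sch <- parse_schedule(condukt_preset("audiovisual-4day"))
  # shorten to keep the test fast: 2 runs of 2 reps
  sch <- trial_schedule(lapply(sch$runs[1:2], function(r) {
    r$rep_count <- 2L; r
  }), remix_24h = TRUE)
  cohort <- make_cohort(2, agent_params(), seed = 4)
  out <- withr::local_tempdir()
  res <- run_trial(sch, tank, cohort, engine_config(rng_seed = 3),
                   origin = "2026-01-05", horizon = 1, out_dir = out)
  expect_length(res, 4)
  expect_equal(vapply(res, `[[`, integer(1), "rep_index"), 1:4)
  walls <- do.call(c, lapply(res, `[[`, "wall_start"))
  expect_true(!is.unsorted(walls))
  m <- read_manifest(file.path(out, "manifest.tsv"))
  expect_equal(nrow(m), 4)
  # association state persists and grows across fed reps
  v_last <- res[[4]]$agents[[1]]$state$V
  expect_true(all(v_last >= agent_params()$V0 * (1 - 0.1 / 4)^4))
})

test_that("run_trial is reproducible byte for byte", {
  sch <- trial_schedule(list(run_spec("08:00", quick_operant(), rep_count = 2)))
  cohort <- make_cohort(1, agent_params(), seed = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_trial(sch, tank, cohort, engine_config(rng_seed = 11), out_dir = d1)
  run_trial(sch, tank, cohort, engine_config(rng_seed = 11), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("engine config contracts hold", {
  expect_error(engine_config(tick = 0.1, frame_rate = 30), "1 / frame_rate")
  expect_error(engine_config(feed_latency = 1.5), "feed_latency")
})
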