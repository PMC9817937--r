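test_that("learning_curve matches a direct kernel-weighted-average oracle", {
  set.seed(4)
  times <- sort(runif(40, 0, 20))
  scores <- rbinom(40, 1, 0.5)
  grid <- c(0, 5, 10, 15, 20)
  got <- learning_curve(times, scores, bandwidth = 3, grid = grid)
  for (i in seq_along(grid)) {
    w <- exp(-((times - grid[i]) / 3)^2 / 2)   # Gaussian kernel, direct sums
    expect_equal(got$p[i], sum(w * scores) / sum(w), tolerance = 1e-10)
    expect_equal(got$sd[i],
                 sqrt(sum(w * (scores - got$p[i])^2) / sum(w)),
                 tolerance = 1e-10)
  }
  expect_true(all(got$p >= 0 & got$p <= 1))
})

test_that("learning_curve limit cases and shift equivariance", {
  t <- 1:20
  all1 <- learning_curve(t, rep(1, 20), bandwidth = 2)
  expect_true(all(all1$p == 1))
  expect_true(all(all1$sd == 0))
  alt <- learning_curve(t, rep(c(0, 1), 10), bandwidth = 1000)
  expect_equal(alt$p, rep(0.5, nrow(alt)), tolerance = 1e-4)
  # invariant to adding a constant to all times
  s <- rbinom(20, 1, 0.5)
  a <- learning_curve(t, s, bandwidth = 2)
  b <- learning_curve(t + 1000, s, bandwidth = 2)
  expect_equal(a$p, b$p)
  expect_error(learning_curve(1, 1, 2), "at least 2")
})

test_that("pre_post_test reproduces hand-computed sums of squares", {
  # two groups (3,4,5) vs (7,8,9): SSB = 24, SSW = 4, df (1,4), F = 24
  res <- pre_post_test(list(PRE = c(3, 4, 5), POST2 = c(7, 8, 9)))
  expect_equal(res$F, 24)
  expect_equal(res$df, c(1, 4))
  expect_equal(res$p, 0.008, tolerance = 0.01)
  # identical values in all windows: F = 0, p = 1 by convention
  same <- pre_post_test(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # zero within-group variance with unequal means: p = 0
  sep <- pre_post_test(list(a = c(1, 1), b = c(2, 2)))
  expect_equal(sep$p, 0)
})

test_that("pre_post_test agrees with stats::aov on random data", {
  set.seed(11)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) rnorm(6, mean = j * runif(1)))
    names(g) <- c("PRE", "POST2", "POST3")
    mine <- pre_post_test(g)
    df <- data.frame(y = unlist(g), w = rep(names(g), each = 6))
    ref <- summary(stats::aov(y ~ w, data = df))[[1]]
    expect_equal(mine$F, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("rm_learning_test decomposes subject and time effects", {
  # no change, identical subjects: both effects vanish
  flat <- data.frame(subject = rep(1:4, each = 6), time_h = rep(1:6, 4),
                     score = rep(1, 24))
  r0 <- rm_learning_test(flat, block_size = 3)
  expect_equal(r0$F_time, 0)
  expect_equal(r0$p_time, 1)
  # all 7 subjects jump from 0.2 to 0.8 with no noise: time effect certain
  prof <- data.frame(subject = rep(1:7, each = 10),
                     time_h = rep(1:10, 7),
                     score = rep(c(1, 0, 0, 0, 0, 1, 1, 1, 1, 0), 7))
  r1 <- rm_learning_test(prof, block_size = 5)
  expect_equal(unique(r1$profile$success_rate), c(0.2, 0.8))
  expect_lt(r1$p_time, 0.001)
  # unbalanced designs are refused with the missing cell named
  unb <- flat[-(1:3), ]
  expect_error(rm_learning_test(unb, block_size = 3), "subject 1")
})

test_that("rm_learning_test agrees with stats::aov on random profiles", {
  set.seed(21)
  for (i in 1:10) {
    d <- expand.grid(subject = factor(1:7), block = factor(1:4))
    d$score <- runif(nrow(d))
    d$time_h <- as.numeric(d$block)
    mine <- rm_learning_test(data.frame(subject = d$subject, time_h = d$time_h,
                                        score = d$score),
                             blocks = as.integer(d$block))
    ref <- summary(stats::aov(score ~ subject + block, data = d))[[1]]
    expect_equal(mine$F_time, ref["block", "F value"], tolerance = 1e-10)
    expect_equal(mine$p_time, ref["block", "Pr(>F)"], tolerance = 1e-10)
    expect_equal(mine$F_subject, ref["subject", "F value"], tolerance = 1e-10)
  }
})

test_that("learning tests agree with a permutation alternative in direction", {
  set.seed(31)
  hits <- 0
  for (i in 1:20) {
    g <- list(PRE = rnorm(6, 10), POST2 = rnorm(6, 10 - 3))
    mine <- pre_post_test(g)
    y <- unlist(g); lab <- rep(c(1, 2), each = 6)
    obs <- abs(mean(y[lab == 1]) - mean(y[lab == 2]))
    perm <- replicate(200, {
      p <- sample(lab)
      abs(mean(y[p == 1]) - mean(y[p == 2]))
    })
    p_perm <- mean(perm >= obs)
    if ((mine$p < 0.05) == (p_perm < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("fit_learning_model behaves at its edges and recovers quickly", {
  # a trendless alternating series needs no learning term
  f0 <- fit_learning_model(rep(c(0, 1), 30))
  expect_lt(f0$alpha, 0.05)
  # degenerate all-success data are flagged as boundary
  f1 <- fit_learning_model(rep(1, 30))
  expect_true(f1$boundary)
  # quick recovery smoke (full-scale recovery lives in the acceptance suite)
  ah <- vapply(1:5, function(s)
    fit_learning_model(simulate_model_scores(200, alpha = 0.3, V0 = 0.05,
                                             guess = 0.1, seed = s))$alpha,
    numeric(1))
  expect_lt(abs(median(ah) - 0.3), 0.15)
  expect_error(fit_learning_model(c(0, 1)), "at least 10")
})

test_that("simulate_model_scores is deterministic in its seed", {
  expect_identical(simulate_model_scores(50, seed = 3),
                   simulate_model_scores(50, seed = 3))
  expect_false(identical(simulate_model_scores(50, seed = 3),
                         simulate_model_scores(50, seed = 4)))
})

test_that("score_series collects operant outcomes from trial results", {
  sch <- trial_schedule(list(run_spec("08:00", quick_operant(), rep_count = 3)))
  cohort <- make_cohort(1, agent_params(), seed = 2)
  res <- run_trial(sch, tank_geometry(), cohort, engine_config(rng_seed = 5))
  ss <- score_series(res)
  expect_equal(nrow(ss), 3)
  expect_true(all(ss$score %in% 0:1))
  expect_true(all(diff(ss$time_h) > 0))
})

test_that("fast score generator and full engine agree on outcomes", {
  tpl <- quick_operant()
  tank <- tank_geometry()
  cfg <- engine_config()
  params <- agent_params()
  seed <- 17
  ss <- simulate_operant_series(1, 5, params = params, template = tpl,
                                tank = tank, config = cfg, seed = seed)
  # replay the same derived seeds through run_rep
  cohort <- make_cohort(1, params, seed = derive_seed(seed, "subject", 1),
                        tank = tank)
  replay <- integer(5)
  for (r in 1:5) {
    res <- run_rep(tpl, tank, cohort, cfg,
                   seed = derive_seed(seed, "subject", 1, "rep", r))
    replay[r] <- res$success
    cohort <- res$agents
    cohort <- condukt:::recover_satiation(cohort, 0.5)
  }
  expect_equal(ss$score, replay)
})
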