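test_that("the train/test split partitions the augmented grid", {
  target <- lv_fixture(t_end = 90)   # 181 half-yearly points over 0-90
  parts <- split_series(target, 60)
  expect_equal(nrow(parts$train), 121)
  expect_equal(nrow(parts$test), 60)
  expect_equal(c(parts$train$time, parts$test$time), target$time)
  expect_equal(log_means(parts$train), log_means(target))
  expect_error(split_series(target, 95), "inside")
  expect_error(split_series(target, -1), "inside")
})

test_that("posterior trajectory ensembles draw without replacement, seeded", {
  spec <- model_spec("ode", 2)
  # small spread of parameter sets around a mild stable system
  base <- flatten_params(spec, list(S = matrix(c(-0.2, 0.4, -0.4, -0.2), 2),
                                    b = c(0, 0)))
  smp <- t(sapply(1:12, function(i) base + 0.01 * stats::rnorm(6)))
  ens <- make_fake_ensemble(spec, smp, c(0.5, -0.5))
  times <- seq(0, 10, 0.5)

  all_used <- ensemble_predict(ens, times, K = 12, seed = 1)
  expect_setequal(all_used$draws, 1:12)

  te <- ensemble_predict(ens, times, K = 5, seed = 2)
  expect_equal(length(unique(te$trajectories$member)), 5)
  expect_equal(nrow(te$trajectories), 5 * length(times))
  te2 <- ensemble_predict(ens, times, K = 5, seed = 2)
  expect_identical(te$draws, te2$draws)
  expect_error(ensemble_predict(ens, times, K = 13), "more members")
  expect_s3_class(autoplot(te), "ggplot")
})

test_that("members that diverge are excluded and reported", {
  spec <- model_spec("ode", 2, activation = "identity")
  good <- flatten_params(spec, list(S = matrix(c(-0.5, 0, 0, -0.5), 2),
                                    b = c(0, 0)))
  bad <- flatten_params(spec, list(S = matrix(c(60, 0, 0, 60), 2),
                                   b = c(0, 0)))
  smp <- rbind(good, bad, good)
  ens <- make_fake_ensemble(spec, smp, c(1, 1))
  te <- ensemble_predict(ens, seq(0, 50, 1), K = 3, seed = 1,
                         control = solver_config(max_steps = 100))
  expect_equal(length(te$failed), 1)
  expect_equal(length(unique(te$trajectories$member)), 2)
})

test_that("loss summaries report the sample mean and unbiased SD", {
  spec <- model_spec("ode", 2, activation = "identity")
  thA <- flatten_params(spec, list(S = matrix(c(-1, 0, 0, -1), 2), b = c(0, 0)))
  thB <- flatten_params(spec, list(S = matrix(c(-2, 0, 0, -2), 2), b = c(0, 0)))
  u0 <- c(1, 1)
  times <- seq(0, 4, 0.5)
  target <- tibble::tibble(time = times, x = 0, y = 0)
  ens <- make_fake_ensemble(spec, rbind(thA, thB), u0)

  # independent per-member losses
  lA <- weighted_loss(solve_trajectory(spec, thA, u0, times), target)
  lB <- weighted_loss(solve_trajectory(spec, thB, u0, times), target)
  summ <- ensemble_loss_summary(ens, target, M = 2, seed = 1)
  expect_equal(summ$mean, mean(c(lA, lB)), tolerance = 1e-8)
  expect_equal(summ$sd, sd(c(lA, lB)), tolerance = 1e-8)
  expect_equal(summ$n, 2)

  # identical members: SD exactly zero
  ens_same <- make_fake_ensemble(spec, rbind(thA, thA, thA), u0)
  expect_equal(ensemble_loss_summary(ens_same, target, M = 3, seed = 1)$sd, 0)
})

test_that("repeated subsample means agree across seeds within sampling error", {
  spec <- model_spec("ode", 2, activation = "identity")
  base <- flatten_params(spec, list(S = matrix(c(-0.5, 0.2, -0.2, -0.5), 2),
                                    b = c(0, 0)))
  smp <- t(sapply(1:60, function(i) base + 0.02 * stats::rnorm(6)))
  ens <- make_fake_ensemble(spec, smp, c(1, -1))
  times <- seq(0, 5, 0.5)
  target <- tibble::tibble(time = times, x = 0, y = 0)
  s1 <- ensemble_loss_summary(ens, target, M = 30, seed = 1)
  s2 <- ensemble_loss_summary(ens, target, M = 30, seed = 99)
  se <- sqrt(s1$sd^2 / s1$n + s2$sd^2 / s2$n)
  expect_lt(abs(s1$mean - s2$mean), 3 * se + 1e-12)
})

test_that("repeated-sample comparison fractions behave at the extremes", {
  spec <- model_spec("ode", 2, activation = "identity")
  goodS <- matrix(c(-3, 0, 0, -3), 2)
  badS <- matrix(c(-0.05, 0, 0, -0.05), 2)
  u0 <- c(1, 1)
  times <- seq(0, 4, 0.5)
  target <- tibble::tibble(time = times, x = 0, y = 0)
  mk <- function(S, jitter) {
    t(sapply(1:40, function(i) {
      flatten_params(spec, list(S = S, b = c(0, 0))) +
        jitter * stats::rnorm(6)
    }))
  }
  withr::with_seed(8, {
    fast <- make_fake_ensemble(spec, mk(goodS, 0.01), u0)  # small losses
    slow <- make_fake_ensemble(spec, mk(badS, 0.01), u0)   # large losses
  })
  cmp <- compare_repeated(fast, slow, target, reps = 20, M = 10, seed = 3)
  expect_equal(cmp$fraction, 1)
  expect_length(cmp$means, 20)

  # identical distributions with the exact mean as reference: repeated
  # subsample means fall on either side about equally often
  exact_mean <- ensemble_loss_summary(fast, target, M = 40, seed = 1)$mean
  cmp2 <- compare_repeated(fast, exact_mean, target, reps = 100, M = 10,
                           seed = 4)
  expect_gt(cmp2$fraction, 0.25)
  expect_lt(cmp2$fraction, 0.75)
})

test_that("phase tables borrow dummy coordinates from the model", {
  target <- lv_fixture(t_end = 20)
  n_t <- nrow(target)
  traj <- tibble::tibble(time = target$time,
                         u1 = stats::rnorm(n_t), u2 = stats::rnorm(n_t),
                         u3 = seq_len(n_t) / n_t)
  # observed-only phase path needs no model
  ph2 <- phase_table(target, NULL, dims = c(1, 2))
  expect_equal(nrow(ph2), n_t)
  expect_named(ph2, c("time", "source", "dim1", "dim2"))
  expect_equal(ph2$dim1, as.matrix(target[, -1])[, 1], ignore_attr = TRUE)

  ph3 <- phase_table(target, traj, dims = c(1, 2, 3))
  expect_equal(nrow(ph3), 2 * n_t)
  d <- ph3[ph3$source == "data", ]
  m <- ph3[ph3$source == "model", ]
  # data rows: observed dims from data, dummy dim copied from the model
  expect_equal(d$dim1, as.matrix(target[, -1])[, 1], ignore_attr = TRUE)
  expect_equal(d$dim3, traj$u3)
  expect_equal(m$dim1, traj$u1)
  expect_error(phase_table(target, NULL, dims = c(1, 2, 3)), "trajectory")
})

test_that("ensemble spread measures across-member variation in a window", {
  spec <- model_spec("ode", 2, activation = "identity")
  th0 <- flatten_params(spec, list(S = matrix(c(-0.3, 0, 0, -0.3), 2),
                                   b = c(0, 0)))
  withr::with_seed(2, {
    smp <- t(sapply(1:8, function(i) th0 + 0.05 * stats::rnorm(6)))
  })
  ens <- make_fake_ensemble(spec, smp, c(1, 1))
  te <- ensemble_predict(ens, seq(0, 10, 0.5), K = 8, seed = 1)
  s_early <- ensemble_spread(te, c(0, 2))
  s_late <- ensemble_spread(te, c(8, 10))
  expect_gt(s_early, 0)
  expect_gt(s_late, 0)
})
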