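test_that("a drift-free step is pure noise with variance epsilon / lam", {
  hy <- psgld_hyper(epsilon = 0.04, alpha = 0.5, lam = 2,
                    n_warmup = 1, n_collect = 1)
  # shared noise: the update with g = 0, V = 0 must equal theta + noise
  # with per-coordinate sd sqrt(epsilon / lam)
  th <- c(1, -2, 0.5)
  set.seed(42)
  st <- psgld_step(th, c(0, 0, 0), c(0, 0, 0), hy)
  set.seed(42)
  eta <- rnorm(3, 0, sqrt(0.04 / 2))
  expect_equal(st$params, th + eta, tolerance = 1e-14)
  expect_equal(st$V, c(0, 0, 0))
})

test_that("the epsilon -> 0 limit freezes the parameters", {
  hy <- psgld_hyper(epsilon = 1e-20, alpha = 0.9, lam = 1,
                    n_warmup = 1, n_collect = 1)
  th <- c(3, -1)
  set.seed(1)
  st <- psgld_step(th, c(10, -5), c(1, 1), hy)
  expect_lt(max(abs(st$params - th)), 1e-8)
})

test_that("with alpha near 1, V0 = 0, lam = 1 the update reduces to plain SGLD", {
  hy <- psgld_hyper(epsilon = 0.01, alpha = 1 - 1e-12, lam = 1,
                    n_warmup = 1, n_collect = 1)
  th <- c(0.4, -0.8); g <- c(1.3, 0.7)
  set.seed(7)
  st <- psgld_step(th, g, c(0, 0), hy)
  set.seed(7)
  eta <- rnorm(2, 0, sqrt(0.01 * 1 / (1 + sqrt(1e-12 * g^2))))
  sgld <- th - (0.01 / 2) * g + eta
  expect_equal(st$params, sgld, tolerance = 1e-6)
})

test_that("non-finite gradients are rejected with the parameter snapshot", {
  hy <- psgld_hyper()
  err <- tryCatch(psgld_step(c(1, 2), c(NaN, 0), c(0, 0), hy),
                  nodefit_integration_error = function(e) e)
  expect_s3_class(err, "nodefit_integration_error")
  expect_equal(err$params, c(1, 2))
})

test_that("long-run samples of a quadratic loss reach the Langevin stationary variance", {
  # L(theta) = theta^2 / 2, identity preconditioning: stationary density
  # prop. to exp(-L), variance 1 (discretization inflates it by ~eps/4)
  hy <- psgld_hyper(epsilon = 0.01, alpha = 1 - 1e-12, lam = 1,
                    n_warmup = 1, n_collect = 1)
  set.seed(2024)
  n <- 200000
  th <- 0; V <- 0
  out <- numeric(n)
  for (i in seq_len(n)) {
    st <- psgld_step(th, th, V, hy)
    th <- st$params; V <- st$V
    out[i] <- th
  }
  v <- stats::var(out[-(1:20000)])
  expect_lt(abs(v - 1), 0.1)
})

test_that("pSGLD sampling is seeded, sized, and spreads around the optimum", {
  truth <- toy_ode_truth()
  target <- toy_ode_target(truth)[1:16, ]
  cfg <- fit_config(segments = 1, ramp_iters = 0, iters_per_segment = 10,
                    lr = 0.01, seed = 1,
                    solver = solver_config(method = "lsoda", max_steps = 2000))
  fit <- fit_model(truth$spec, target, cfg,
                   params0 = truth$params, u0 = truth$u0)

  hy1 <- psgld_hyper(epsilon = 1e-4, n_warmup = 2, n_collect = 1, seed = 5)
  one <- psgld_sample(fit, target, hy1)
  expect_equal(nrow(one$samples), 1)
  expect_length(one$losses, 1)

  hy <- psgld_hyper(epsilon = 1e-4, n_warmup = 5, n_collect = 20, seed = 5)
  e1 <- psgld_sample(fit, target, hy)
  e2 <- psgld_sample(fit, target, hy)
  expect_identical(e1$samples, e2$samples)
  expect_identical(e1$losses, e2$losses)
  expect_equal(nrow(e1$samples), 20)

  # samples fluctuate around the optimum: mean sampled loss >= fitted loss
  ok <- vapply(1:10, function(s) {
    ens <- psgld_sample(fit, target,
                        psgld_hyper(epsilon = 1e-4, n_warmup = 3,
                                    n_collect = 10, seed = s))
    mean(ens$losses) >= fit$final_loss
  }, logical(1))
  expect_true(all(ok))
})

test_that("the split-half diagnostic flags diverging loss distributions", {
  same <- split_half_diagnostic(rep(c(1, 2, 3, 4), 10))
  expect_equal(same$ks_statistic, 0)
  expect_true(same$pass)
  expect_equal(nrow(same$summary), 2)

  far <- split_half_diagnostic(c(rep(1, 50), rep(2, 50)))
  expect_equal(far$ks_statistic, 1)
  expect_false(far$pass)
  expect_equal(far$summary$mean, c(1, 2))
  expect_equal(far$summary$sd, c(0, 0))
})

test_that("the KS statistic stays under the 5% critical value for iid halves", {
  # null calibration: both halves from one distribution, 5000 each
  crit <- 1.358 * sqrt(2 / 5000)
  hits <- vapply(1:20, function(s) {
    losses <- withr::with_seed(s, stats::rchisq(10000, df = 3))
    split_half_diagnostic(losses)$ks_statistic < crit
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ensembles persist to a directory and back", {
  spec <- model_spec("ode", 2)
  smp <- matrix(stats::rnorm(60), 10, 6)
  ens <- make_fake_ensemble(spec, smp, c(0.5, -0.5),
                            losses = stats::runif(10, 1, 2))
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  expect_true(all(file.exists(file.path(dir, c("samples.csv", "losses.csv",
                                               "hyper.json",
                                               "diagnostic.json")))))
  back <- read_ensemble(dir)
  expect_equal(back$samples, ens$samples, tolerance = 1e-15)
  expect_equal(back$losses, ens$losses, tolerance = 1e-15)
  expect_equal(back$hyper$epsilon, ens$hyper$epsilon)
  td <- tidy(back)
  expect_named(td, c("sample", "loss"))
  expect_equal(nrow(td), 10)
  expect_s3_class(glance(back), "tbl_df")
})
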