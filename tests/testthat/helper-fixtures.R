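# Shared fixtures and independent oracles, all generated in code.

# scaled oscillatory fixture: ~4 predator-prey cycles, 41 yearly points
lv_fixture <- function(t_end = 40, step = 1, sigma = 1) {
  preprocess_series(simulate_lv(lv_params(), 0, t_end, step), sigma)
}

# damped-oscillation target generated from known ODE parameters; the fit
# experiments try to recover this trajectory from random initialization
toy_ode_truth <- function() {
  spec <- model_spec("ode", 2)
  S <- matrix(c(0, 1, -1, -0.15), 2, 2)
  b <- c(0, 0)
  list(spec = spec,
       params = flatten_params(spec, list(S = S, b = b)),
       u0 = c(0.8, 0),
       times = seq(0, 15, 0.5))
}

toy_ode_target <- function(truth = toy_ode_truth()) {
  tr <- solve_trajectory(truth$spec, truth$params, truth$u0, truth$times,
                         solver_config(rtol = 1e-10, atol = 1e-12))
  names(tr) <- c("time", "x", "y")
  tr
}

# central finite differences of the trajectory loss: the independent
# oracle for every gradient-through-the-solver check
fd_loss_gradient <- function(spec, params, u0, target, weights = NULL,
                             control = solver_config(rtol = 1e-10,
                                                     atol = 1e-12),
                             h = 1e-5) {
  loss_at <- function(th) {
    tr <- solve_trajectory(spec, th, u0, target$time, control)
    weighted_loss(tr, target, weights, n_obs = spec$n_obs)
  }
  vapply(seq_along(params), function(i) {
    tp <- params; tp[i] <- tp[i] + h
    tm <- params; tm[i] <- tm[i] - h
    (loss_at(tp) - loss_at(tm)) / (2 * h)
  }, numeric(1))
}

# hand-rolled two-layer network, written without the package's own
# param_views machinery
node_field_oracle <- function(n, N, flat, u) {
  i <- 0
  W1 <- matrix(flat[i + 1:(N * n)], N, n); i <- i + N * n
  b1 <- flat[i + 1:N]; i <- i + N
  W2 <- matrix(flat[i + 1:(n * N)], n, N); i <- i + n * N
  b2 <- flat[i + 1:n]
  out <- numeric(n)
  hidden <- numeric(N)
  for (k in 1:N) hidden[k] <- tanh(sum(W1[k, ] * u) + b1[k])
  for (j in 1:n) out[j] <- sum(W2[j, ] * hidden) + b2[j]
  out
}

# a hand-built posterior ensemble (no sampling run needed) for the
# prediction-module contracts
make_fake_ensemble <- function(spec, params_matrix, u0, losses = NULL) {
  stopifnot(ncol(params_matrix) == n_parameters(spec))
  ens <- structure(list(samples = params_matrix,
                        losses = losses %||% rep(1, nrow(params_matrix)),
                        hyper = psgld_hyper(n_warmup = 1,
                                            n_collect = nrow(params_matrix)),
                        spec = spec, u0 = u0, n_failed_steps = 0L,
                        diagnostic = NULL),
                   class = "nodefit_ensemble")
  ens$diagnostic <- split_half_diagnostic(ens)
  ens
}

`%||%` <- function(x, y) if (is.null(x)) y else x
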