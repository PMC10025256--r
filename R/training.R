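#' Sequential ramped-weight schedule
#'
#' Simultaneously fitting every point of an oscillatory series from random
#' parameters often stalls: the loss surface is too rugged. The curriculum
#' fits the first part of the series, then activates later points segment
#' by segment, ramping each newly added point's weight linearly from 0 to 1
#' so no discontinuity jolts the optimizer. Segment `k` of `segments`
#' activates the first `ceiling(k T / segments)` points; points already
#' active keep weight 1; within a segment, iteration `j` (1-based) gives new
#' points weight `min(1, (j - 1) / ramp_iters)`. The final entry is all
#' ones.
#'
#' @param T_grid number of target time points
#' @param segments number of sequential stages, `>= 1`
#' @param ramp_iters iterations over which new points ramp 0 to 1; must be
#'   less than `iters_per_segment` so the schedule ends at full weight
#' @param iters_per_segment Adam iterations per stage
#' @return list of weight vectors, one per iteration
#'   (`segments * iters_per_segment` in total)
#' @export
weight_schedule <- function(T_grid, segments, ramp_iters, iters_per_segment) {
  if (segments < 1 || ramp_iters < 0 || iters_per_segment < 1) {
    stop("invalid schedule configuration", call. = FALSE)
  }
  if (segments > 1 && ramp_iters >= iters_per_segment) {
    stop("ramp_iters must be smaller than iters_per_segment", call. = FALSE)
  }
  schedule <- vector("list", segments * iters_per_segment)
  prev_active <- if (segments == 1) 0L else ceiling(T_grid / segments)
  # segment 1's points are the "initial part": full weight from the start
  active1 <- ceiling(T_grid / segments)
  it <- 0L
  for (k in seq_len(segments)) {
    active <- ceiling(k * T_grid / segments)
    base <- as.numeric(seq_len(T_grid) <= (if (k == 1) active1 else prev_active))
    new_pts <- if (k == 1) integer(0) else setdiff(seq_len(active), seq_len(prev_active))
    for (j in seq_len(iters_per_segment)) {
      w <- base
      if (length(new_pts) > 0) {
        w[new_pts] <- if (ramp_iters == 0) 1 else min(1, (j - 1) / ramp_iters)
      }
      it <- it + 1L
      schedule[[it]] <- w
    }
    prev_active <- active
  }
  schedule
}

#' Fitting configuration
#'
#' @param segments sequential stages (1 = plain simultaneous fitting)
#' @param ramp_iters linear ramp length for newly activated points
#' @param iters_per_segment Adam iterations per stage
#' @param lr Adam learning rate
#' @param adam_betas Adam momentum constants `(beta1, beta2)`
#' @param seed RNG seed controlling parameter init and dummy initial values
#' @param solver a [solver_config()]
#' @param max_failures total integration-failure budget for one run; once
#'   exhausted the fit stops and returns the best parameters seen, so a
#'   run through a persistently divergent region terminates in bounded
#'   work instead of rejecting candidates forever
#' @return an object of class `fit_config`
#' @export
fit_config <- function(segments = 4, ramp_iters = 100, iters_per_segment = 500,
                       lr = 0.01, adam_betas = c(0.9, 0.999), seed = 1,
                       solver = solver_config(), max_failures = 200L) {
  if (lr <= 0) stop("lr must be positive", call. = FALSE)
  structure(list(segments = as.integer(segments),
                 ramp_iters = as.integer(ramp_iters),
                 iters_per_segment = as.integer(iters_per_segment),
                 lr = lr, adam_betas = adam_betas, seed = as.integer(seed),
                 solver = solver, max_failures = as.integer(max_failures)),
            class = "fit_config")
}

#' Fit a model to a smoothed target with Adam
#'
#' Runs Adam over the sequential ramped-weight schedule. Each iteration
#' integrates the augmented sensitivity system once to get the exact loss
#' gradient. Integration failures are treated as an infinite-loss
#' candidate: the step is rejected, the previous iterate restored, and the
#' step retried with a halved learning rate (up to 8 halvings) before the
#' iteration is abandoned. The returned parameters are the best seen by
#' all-ones (uncurriculum) loss.
#'
#' @param spec a `model_spec`
#' @param target a `smoothed_series` fitting target
#' @param config a [fit_config()]
#' @param params0 optional starting parameters (default: random init from
#'   the config seed)
#' @param u0 optional initial state (default: [initial_state()] from the
#'   target with the config seed)
#' @return an object of class `nodefit_fit` with elements `spec`, `params`,
#'   `u0`, `loss_trace` (tibble: iteration, segment, weighted loss),
#'   `final_loss` (all-ones loss at the returned parameters) and `config`
#' @export
fit_model <- function(spec, target, config = fit_config(),
                      params0 = NULL, u0 = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "fit_config"))
  validate_series(target)
  params <- params0 %||% init_parameters(spec, seed = config$seed)
  u0 <- u0 %||% initial_state(target, spec, seed = config$seed + 1L)
  schedule <- weight_schedule(nrow(target), config$segments,
                              config$ramp_iters, config$iters_per_segment)
  total <- length(schedule)
  b1 <- config$adam_betas[1]; b2 <- config$adam_betas[2]
  m <- numeric(length(params)); v <- numeric(length(params))
  trace <- numeric(total)
  best_params <- NULL; best_loss <- Inf
  n_fail <- 0L
  consec_abandoned <- 0L
  prev_params <- params
  for (it in seq_len(total)) {
    w <- schedule[[it]]
    lr_it <- config$lr
    res <- NULL
    for (try in 0:3) {
      res <- tryCatch(
        loss_and_gradient(spec, params, u0, target, w, config$solver),
        nodefit_integration_error = function(e) NULL)
      if (!is.null(res)) break
      # reject the step that produced these params; retry smaller
      n_fail <- n_fail + 1L
      params <- prev_params
      lr_it <- lr_it / 2
      if (it == 1L) break
      params <- adam_retry(prev_params, m, v, b1, b2, it - 1L, lr_it)
    }
    if (is.null(res)) {
      if (is.null(best_params) && it == 1L) {
        stop("fitting failed: integration diverged from the start",
             call. = FALSE)
      }
      trace[it] <- NA_real_
      consec_abandoned <- consec_abandoned + 1L
      # persistently divergent region: stop and keep the best seen
      if (consec_abandoned >= 30L || n_fail >= config$max_failures) break
      next
    }
    consec_abandoned <- 0L
    trace[it] <- res$loss
    if (all(w == 1) && res$loss < best_loss) {
      best_loss <- res$loss
      best_params <- params
    }
    g <- res$gradient
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^it)
    vhat <- v / (1 - b2^it)
    prev_params <- params
    params <- params - lr_it * mhat / (sqrt(vhat) + 1e-8)
  }
  # final candidate: current params under all-ones weights
  final <- tryCatch(
    loss_and_gradient(spec, params, u0, target, NULL, config$solver),
    nodefit_integration_error = function(e) NULL)
  if (!is.null(final) && final$loss < best_loss) {
    best_loss <- final$loss
    best_params <- params
  }
  if (is.null(best_params)) {
    stop("fitting failed: no finite all-ones loss was ever reached",
         call. = FALSE)
  }
  # report the all-ones loss along the plainly solved trajectory, so the
  # reported value matches an independent recomputation exactly
  best_loss <- tryCatch({
    tr <- solve_trajectory(spec, best_params, u0, target$time, config$solver)
    weighted_loss(tr, target, n_obs = spec$n_obs)
  }, nodefit_integration_error = function(e) best_loss)
  structure(list(spec = spec, params = best_params, u0 = u0,
                 loss_trace = tibble::tibble(
                   iteration = seq_len(total),
                   segment = rep(seq_len(config$segments),
                                 each = config$iters_per_segment),
                   loss = trace),
                 final_loss = best_loss,
                 n_integration_failures = n_fail,
                 config = config),
            class = "nodefit_fit")
}

# one Adam step from a frozen optimizer state, used when retrying a
# rejected step at a reduced learning rate (a handful of tries: repeated
# failures are cheaper to skip than to grind through)
adam_retry <- function(prev_params, m, v, b1, b2, t_prev, lr) {
  if (t_prev < 1) return(prev_params)
  mhat <- m / (1 - b1^t_prev)
  vhat <- v / (1 - b2^t_prev)
  prev_params - lr * mhat / (sqrt(vhat) + 1e-8)
}

#' @export
print.nodefit_fit <- function(x, ...) {
  cat(sprintf("<nodefit_fit> %s n=%d: final loss %.6g after %d iterations (%d integration failures)\n",
              x$spec$family, x$spec$n, x$final_loss, nrow(x$loss_trace),
              x$n_integration_failures))
  invisible(x)
}

#' Tidy a fitted model
#'
#' @param x a `nodefit_fit`
#' @param ... unused
#' @return a tibble with one row per parameter (`term`, `estimate`)
#' @export
tidy.nodefit_fit <- function(x, ...) {
  tibble::tibble(term = param_labels(x$spec), estimate = x$params)
}

#' @rdname tidy.nodefit_fit
#' @return `glance`: one-row tibble of fit-level summaries
#' @export
glance.nodefit_fit <- function(x, ...) {
  tibble::tibble(family = x$spec$family, n = x$spec$n,
                 n_parameters = n_parameters(x$spec),
                 final_loss = x$final_loss,
                 n_iterations = nrow(x$loss_trace),
                 n_integration_failures = x$n_integration_failures)
}

#' Plot a fit: loss trace and fitted trajectory against the target
#'
#' @param object a `nodefit_fit`
#' @param target the fitting target, needed for the trajectory panel;
#'   if `NULL` only the loss trace is drawn
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.nodefit_fit <- function(object, target = NULL, ...) {
  if (is.null(target)) {
    return(ggplot2::ggplot(object$loss_trace,
                           ggplot2::aes(x = .data$iteration, y = .data$loss)) +
             ggplot2::geom_line() +
             ggplot2::scale_y_log10() +
             ggplot2::labs(x = "iteration", y = "weighted loss"))
  }
  traj <- solve_trajectory(object$spec, object$params, object$u0,
                           target$time, object$config$solver)
  obs <- seq_len(object$spec$n_obs)
  tl <- tidyr::pivot_longer(target, -"time",
                            names_to = "variable", values_to = "value")
  ml <- tidyr::pivot_longer(traj[, c(1, 1 + obs)], -"time",
                            names_to = "dim", values_to = "value")
  ml$variable <- series_names(target)[match(ml$dim, paste0("u", obs))]
  ggplot2::ggplot(tl, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_line(data = ml, colour = "goldenrod") +
    ggplot2::facet_wrap(~variable, ncol = 1) +
    ggplot2::labs(x = "time (years)", y = "centered log abundance")
}

#' Serialize a fit to JSON (+ CSV loss trace)
#'
#' @param fit a `nodefit_fit`
#' @param path JSON path; the loss trace goes to `<path>.trace.csv`
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(spec = unclass(fit$spec),
              params = as.numeric(fit$params),
              u0 = as.numeric(fit$u0),
              u0_seed = attr(fit$u0, "seed"),
              final_loss = fit$final_loss,
              n_integration_failures = fit$n_integration_failures,
              config = config_to_list(fit$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  readr::write_csv(fit$loss_trace, paste0(path, ".trace.csv"))
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- obj$spec
  spec <- model_spec(sp$family, n = sp$n, n_obs = sp$n_obs,
                     N = if (is.null(sp$N) || is.na(sp$N)) 20 else sp$N,
                     activation = sp$activation)
  u0 <- as.numeric(obj$u0)
  attr(u0, "seed") <- obj$u0_seed
  cfgl <- obj$config
  method <- cfgl$solver$method
  if (length(method) == 0) method <- NULL
  cfg <- fit_config(segments = cfgl$segments, ramp_iters = cfgl$ramp_iters,
                    iters_per_segment = cfgl$iters_per_segment, lr = cfgl$lr,
                    adam_betas = as.numeric(cfgl$adam_betas), seed = cfgl$seed,
                    solver = solver_config(method, cfgl$solver$rtol,
                                           cfgl$solver$atol,
                                           cfgl$solver$max_steps),
                    max_failures = cfgl$max_failures %||% 200L)
  trace_path <- paste0(path, ".trace.csv")
  trace <- if (file.exists(trace_path)) {
    readr::read_csv(trace_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  structure(list(spec = spec, params = as.numeric(obj$params), u0 = u0,
                 loss_trace = trace, final_loss = obj$final_loss,
                 n_integration_failures = obj$n_integration_failures,
                 config = cfg),
            class = "nodefit_fit")
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$solver <- unclass(out$solver)
  out
}
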