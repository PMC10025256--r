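#' Train/test split of a target series
#'
#' Training keeps every point with `time <= t_split`; the test side keeps
#' the remainder. On the 181-point half-yearly grid over years 0-90, a
#' split at year 60 gives 121 training and 60 test points per variable.
#' The two parts partition the original grid exactly.
#'
#' @param target a series tibble (usually a `smoothed_series`)
#' @param t_split split time (years), strictly inside the observed range
#' @return list with elements `train` and `test`, attributes preserved
#' @export
split_series <- function(target, t_split) {
  validate_series(target)
  tm <- target$time
  if (t_split < min(tm) || t_split >= max(tm)) {
    stop("t_split must lie strictly inside the observed time range",
         call. = FALSE)
  }
  take <- function(idx) {
    out <- target[idx, ]
    keep <- setdiff(names(attributes(target)), names(attributes(out)))
    attributes(out)[keep] <- attributes(target)[keep]
    class(out) <- class(target)
    out
  }
  train <- take(tm <= t_split)
  test <- take(tm > t_split)
  if (nrow(train) == 0 || nrow(test) == 0) {
    stop("split leaves one side empty", call. = FALSE)
  }
  list(train = train, test = test)
}

draw_members <- function(ensemble, K, seed) {
  m <- nrow(ensemble$samples)
  if (K > m) stop("cannot draw more members than ensemble samples",
                  call. = FALSE)
  withr::with_seed(seed, sample.int(m, K, replace = FALSE))
}

#' Posterior trajectory ensemble
#'
#' Draws `K` parameter sets uniformly without replacement from the
#' posterior ensemble (seeded) and solves each over the full grid from the
#' training-period initial state, so trajectories run continuously across
#' the train/test boundary. Members whose integration diverges are
#' excluded and reported, never silently dropped.
#'
#' @param ensemble a `nodefit_ensemble`
#' @param times full (train + test) time grid
#' @param K number of posterior draws (30 reproduces a typical figure-scale
#'   ensemble)
#' @param seed RNG seed for the draw
#' @param control a [solver_config()]
#' @return an object of class `nodefit_trajectory_ensemble`: `trajectories`
#'   (long tibble: member, time, one column per dimension), `draws`
#'   (sampled row indices), `failed` (indices of excluded members)
#' @export
ensemble_predict <- function(ensemble, times, K = 30, seed = 1,
                             control = solver_config()) {
  stopifnot(inherits(ensemble, "nodefit_ensemble"))
  draws <- draw_members(ensemble, K, seed)
  spec <- ensemble$spec
  trajs <- vector("list", K)
  failed <- integer(0)
  for (i in seq_len(K)) {
    tr <- tryCatch(
      solve_trajectory(spec, ensemble$samples[draws[i], ], ensemble$u0,
                       times, control),
      nodefit_integration_error = function(e) NULL)
    if (is.null(tr)) {
      failed <- c(failed, draws[i])
    } else {
      tr$member <- i
      trajs[[i]] <- tr
    }
  }
  structure(list(trajectories = dplyr::bind_rows(trajs),
                 draws = draws, failed = failed, times = times,
                 spec = spec, u0 = ensemble$u0),
            class = "nodefit_trajectory_ensemble")
}

#' @export
print.nodefit_trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory ensemble> %d members on %d time points (%d excluded for divergence)\n",
              length(x$draws) - length(x$failed), length(x$times),
              length(x$failed)))
  invisible(x)
}

# unweighted per-member loss on a window target for a set of ensemble rows;
# losses for repeated rows are computed once
member_window_losses <- function(ensemble, target, rows,
                                 control = solver_config()) {
  unique_rows <- unique(rows)
  ll <- vapply(unique_rows, function(r) {
    tr <- tryCatch(
      solve_trajectory(ensemble$spec, ensemble$samples[r, ], ensemble$u0,
                       target$time, control),
      nodefit_integration_error = function(e) NULL)
    if (is.null(tr)) NA_real_
    else weighted_loss(tr, target, n_obs = ensemble$spec$n_obs)
  }, numeric(1))
  ll[match(rows, unique_rows)]
}

#' Mean and SD of posterior window losses
#'
#' Draws `M` posterior members (without replacement, seeded), computes each
#' member's unweighted quadratic loss over the given window target, and
#' returns the sample mean and unbiased sample SD, the usual
#' "mean +/- SD over a sample of trajectories" summary. The window is
#' typically the test period when judging predictions; pass the full-grid
#' target to score the whole record.
#'
#' @param ensemble a `nodefit_ensemble`
#' @param target window target series (test, train, or full)
#' @param M sample size (e.g. 3000 at full scale)
#' @param seed RNG seed
#' @param control a [solver_config()]
#' @return one-row tibble: `mean`, `sd`, `n` (members scored), `n_failed`
#' @export
ensemble_loss_summary <- function(ensemble, target, M = 3000, seed = 1,
                                  control = solver_config()) {
  rows <- draw_members(ensemble, M, seed)
  ll <- member_window_losses(ensemble, target, rows, control)
  ok <- ll[!is.na(ll)]
  tibble::tibble(mean = mean(ok), sd = stats::sd(ok), n = length(ok),
                 n_failed = sum(is.na(ll)))
}

#' Repeated-sample model comparison
#'
#' Repeats the `M`-member mean-loss computation `reps` times for ensemble
#' A and counts how often the mean falls below a reference mean from model
#' B (either a precomputed scalar or a second ensemble summarized once).
#' Two models of similar quality give a fraction near one half; a clearly
#' better A gives a fraction near one.
#'
#' @param ensembleA a `nodefit_ensemble`
#' @param reference either a scalar reference mean loss, or a second
#'   `nodefit_ensemble` summarized once with the same `M`
#' @param target window target series on which losses are computed
#' @param reps number of repeated samples (e.g. 80)
#' @param M members per sample (e.g. 3000)
#' @param seed RNG seed
#' @param control a [solver_config()]
#' @return list with `fraction` (in [0, 1]), `means` (length-`reps`
#'   vector of A's sampled mean losses) and `reference`
#' @export
compare_repeated <- function(ensembleA, reference, target, reps = 80,
                             M = 3000, seed = 1,
                             control = solver_config()) {
  if (inherits(reference, "nodefit_ensemble")) {
    reference <- ensemble_loss_summary(reference, target, M = M,
                                       seed = seed + 1L,
                                       control = control)$mean
  }
  # score every member once, then resample cheaply
  all_rows <- seq_len(nrow(ensembleA$samples))
  ll <- member_window_losses(ensembleA, target, all_rows, control)
  means <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      rows <- sample.int(length(ll), M, replace = FALSE)
      mean(ll[rows], na.rm = TRUE)
    }, numeric(1))
  })
  list(fraction = mean(means < reference), means = means,
       reference = reference)
}

#' Phase-path table
#'
#' Maps trajectories into state space: each time point becomes a point
#' whose coordinates are the selected dimensions. Data rows use the
#' observed variables from the target; when a dummy dimension is
#' requested, the data path borrows that coordinate from the model
#' trajectory (the data carry no dummy values of their own), and the model
#' rows take every coordinate from the trajectory.
#'
#' @param target observed series tibble (observed dimensions only)
#' @param trajectory model trajectory tibble on the same grid, or `NULL`
#' @param dims integer vector of state dimensions to keep
#' @return tibble with columns `time`, `source` (`"data"` / `"model"`),
#'   and one `dim<k>` column per selected dimension
#' @export
phase_table <- function(target, trajectory = NULL, dims = c(1, 2)) {
  n_obs <- length(series_names(target))
  needs_model <- any(dims > n_obs)
  if (needs_model && is.null(trajectory)) {
    stop("dummy dimensions for the data path require a model trajectory",
         call. = FALSE)
  }
  if (!is.null(trajectory) &&
      (nrow(trajectory) != nrow(target) ||
       max(abs(trajectory$time - target$time)) > 1e-8)) {
    stop("trajectory and target time grids differ", call. = FALSE)
  }
  tv <- series_values(target)
  mv <- if (!is.null(trajectory)) series_values(trajectory)
  grab <- function(mat_obs, mat_model) {
    cols <- lapply(dims, function(d) {
      if (d <= ncol(mat_obs)) mat_obs[, d] else mat_model[, d]
    })
    names(cols) <- paste0("dim", dims)
    tibble::as_tibble(cols)
  }
  data_part <- dplyr::bind_cols(
    tibble::tibble(time = target$time, source = "data"), grab(tv, mv))
  if (is.null(trajectory)) return(data_part)
  if (max(dims) > ncol(mv)) stop("dims exceed trajectory dimensions",
                                 call. = FALSE)
  model_part <- dplyr::bind_cols(
    tibble::tibble(time = target$time, source = "model"), grab(mv, mv))
  dplyr::bind_rows(data_part, model_part)
}

#' Plot a posterior trajectory ensemble over the data
#'
#' @param object a `nodefit_trajectory_ensemble`
#' @param target full-grid target series to overlay
#' @param t_split optional split time drawn as a dotted line
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.nodefit_trajectory_ensemble <- function(object, target = NULL,
                                                 t_split = NULL, ...) {
  obs <- seq_len(object$spec$n_obs)
  tl <- tidyr::pivot_longer(object$trajectories[, c("time", paste0("u", obs),
                                                    "member")],
                            -c("time", "member"),
                            names_to = "dim", values_to = "value")
  p <- ggplot2::ggplot(tl, ggplot2::aes(x = .data$time, y = .data$value,
                                        group = .data$member)) +
    ggplot2::geom_line(alpha = 0.3, colour = "goldenrod") +
    ggplot2::facet_wrap(~dim, ncol = 1) +
    ggplot2::labs(x = "time (years)", y = "centered log abundance")
  if (!is.null(target)) {
    dl <- tidyr::pivot_longer(target, -"time",
                              names_to = "variable", values_to = "value")
    dl$dim <- paste0("u", match(dl$variable, series_names(target)))
    dl <- dl[dl$dim %in% paste0("u", obs), ]
    p <- p + ggplot2::geom_line(
      data = dl, ggplot2::aes(x = .data$time, y = .data$value),
      inherit.aes = FALSE, colour = "grey30", linewidth = 0.3)
  }
  if (!is.null(t_split)) {
    p <- p + ggplot2::geom_vline(xintercept = t_split, linetype = "dotted")
  }
  p
}

#' Spread of an ensemble within a time window
#'
#' Mean (over window times and observed dimensions) of the across-member
#' standard deviation of the trajectories: a scalar measure of prediction
#' precision. Overfit models show markedly wider spread in the test window
#' than in the training window.
#'
#' @param traj_ensemble a `nodefit_trajectory_ensemble`
#' @param window length-2 numeric, inclusive time range
#' @return scalar spread
#' @export
ensemble_spread <- function(traj_ensemble, window) {
  obs <- seq_len(traj_ensemble$spec$n_obs)
  tr <- traj_ensemble$trajectories
  tr <- tr[tr$time >= window[1] & tr$time <= window[2], ]
  long <- tidyr::pivot_longer(tr[, c("time", paste0("u", obs), "member")],
                              -c("time", "member"),
                              names_to = "dim", values_to = "value")
  spread <- dplyr::summarise(dplyr::group_by(long, .data$time, .data$dim),
                             s = stats::sd(.data$value), .groups = "drop")
  mean(spread$s)
}
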