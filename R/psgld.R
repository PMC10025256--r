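#' pSGLD hyperparameters
#'
#' Preconditioned stochastic gradient Langevin dynamics explores the
#' neighbourhood of a fitted optimum: a deterministic force pulls each
#' parameter toward a locally better fit while a calibrated stochastic
#' force makes it fluctuate, approximately sampling a Bayesian posterior
#' (non-informative prior, quadratic loss as negative log-posterior). The
#' noise dominates the drift in the regime `epsilon * g << 1`. Warm-up and
#' collection defaults follow typical run sizes of 5000 discarded and
#' 10,000 retained samples.
#'
#' @param epsilon step size, positive
#' @param alpha preconditioner decay in (0, 1); the running accumulator is
#'   `V <- alpha V + (1 - alpha) g^2`
#' @param lam preconditioner damping, positive
#' @param n_warmup discarded initial samples, `>= 1`
#' @param n_collect retained samples, `>= 1`
#' @param seed RNG seed
#' @param temperature scales the loss used as negative log-posterior
#'   (gradient divided by this); default 1
#' @param fail_tol maximal tolerated fraction of integration-failed steps
#' @return an object of class `psgld_hyper`
#' @export
psgld_hyper <- function(epsilon = 1e-4, alpha = 0.99, lam = 1e-5,
                        n_warmup = 5000, n_collect = 10000, seed = 1,
                        temperature = 1, fail_tol = 0.2) {
  if (epsilon <= 0 || lam <= 0 || alpha <= 0 || alpha >= 1) {
    stop("need epsilon > 0, lam > 0, 0 < alpha < 1", call. = FALSE)
  }
  if (n_warmup < 1 || n_collect < 1) {
    stop("n_warmup and n_collect must be >= 1", call. = FALSE)
  }
  structure(list(epsilon = epsilon, alpha = alpha, lam = lam,
                 n_warmup = as.integer(n_warmup),
                 n_collect = as.integer(n_collect),
                 seed = as.integer(seed), temperature = temperature,
                 fail_tol = fail_tol),
            class = "psgld_hyper")
}

#' One pSGLD update
#'
#' Following the preconditioned Langevin update: the squared-gradient
#' accumulator is decayed first, `V <- alpha V + (1 - alpha) g^2`; the
#' diagonal preconditioner is `G = 1 / (lam + sqrt(V))`; then
#' `theta <- theta - (epsilon / 2) G g + eta` with
#' `eta ~ Normal(0, epsilon G)` elementwise. The curvature correction term
#' of the full update is omitted, standard practice for `alpha` near 1
#' where it is negligible. Uses R's current RNG stream; seed at the caller.
#'
#' @param params flat parameter vector
#' @param grad loss gradient at `params`
#' @param V squared-gradient accumulator (same length; start at 0)
#' @param hyper a [psgld_hyper()]
#' @return list with updated `params` and `V`
#' @export
psgld_step <- function(params, grad, V, hyper) {
  if (!all(is.finite(grad))) {
    stop(integration_error("non-finite gradient in pSGLD step", params))
  }
  V <- hyper$alpha * V + (1 - hyper$alpha) * grad^2
  G <- 1 / (hyper$lam + sqrt(V))
  eta <- stats::rnorm(length(params), 0, sqrt(hyper$epsilon * G))
  list(params = params - (hyper$epsilon / 2) * G * grad + eta, V = V)
}

#' Sample a posterior parameter ensemble by pSGLD
#'
#' Starts from the fitted optimum, runs `n_warmup` discarded steps then
#' `n_collect` retained steps, all with unit weights; each retained sample
#' is recorded with its all-ones-weight loss. A step whose gradient
#' evaluation diverges is rejected (parameters kept); if more than
#' `fail_tol` of all steps fail, sampling aborts. Deterministic given the
#' seed.
#'
#' @param fit a `nodefit_fit` with finite final loss
#' @param target the fitting target (training-window `smoothed_series`)
#' @param hyper a [psgld_hyper()]
#' @param control a [solver_config()]; defaults to the fit's own
#' @return an object of class `nodefit_ensemble`: `samples`
#'   (`n_collect` x p matrix), `losses`, `hyper`, `diagnostic` (split-half
#'   record), plus the spec and initial state for downstream prediction
#' @export
psgld_sample <- function(fit, target, hyper = psgld_hyper(),
                         control = NULL) {
  stopifnot(inherits(fit, "nodefit_fit"), inherits(hyper, "psgld_hyper"))
  if (!is.finite(fit$final_loss)) stop("fit has non-finite loss", call. = FALSE)
  control <- control %||% fit$config$solver
  spec <- fit$spec
  params <- fit$params
  V <- numeric(length(params))
  total <- hyper$n_warmup + hyper$n_collect
  samples <- matrix(NA_real_, hyper$n_collect, length(params))
  losses <- numeric(hyper$n_collect)
  n_fail <- 0L
  prev_params <- params
  last_loss <- fit$final_loss
  withr::with_seed(hyper$seed, {
    for (it in seq_len(total)) {
      res <- tryCatch(
        loss_and_gradient(spec, params, fit$u0, target, NULL, control),
        nodefit_integration_error = function(e) NULL)
      if (is.null(res)) {
        # the noise step wandered into a region where integration diverges:
        # reject the move and stay at the previous (evaluated) state
        n_fail <- n_fail + 1L
        if (n_fail > hyper$fail_tol * total) {
          stop(sprintf("pSGLD aborted: %d of %d steps failed integration",
                       n_fail, it), call. = FALSE)
        }
        params <- prev_params
        if (it > hyper$n_warmup) {
          k <- it - hyper$n_warmup
          samples[k, ] <- params
          losses[k] <- last_loss
        }
        next
      }
      if (it > hyper$n_warmup) {
        k <- it - hyper$n_warmup
        samples[k, ] <- params
        losses[k] <- res$loss
      }
      prev_params <- params
      last_loss <- res$loss
      st <- psgld_step(params, res$gradient / hyper$temperature, V, hyper)
      params <- st$params
      V <- st$V
    }
  })
  ens <- structure(list(samples = samples,
                        losses = losses,
                        hyper = hyper, spec = spec, u0 = fit$u0,
                        n_failed_steps = n_fail,
                        diagnostic = NULL),
                   class = "nodefit_ensemble")
  if (length(ens$losses) >= 2) ens$diagnostic <- split_half_diagnostic(ens)
  ens
}

#' Split-half convergence diagnostic
#'
#' The sampling run is judged long enough when the loss distribution over
#' the first half of the collected samples is reasonably close to that
#' over the second half. Both halves are summarized (mean, SD, quantiles)
#' and compared by the two-sample Kolmogorov-Smirnov statistic; the run
#' passes when the statistic falls below the threshold.
#'
#' @param ensemble a `nodefit_ensemble`, or a numeric vector of losses
#' @param threshold KS-statistic threshold for the "reasonably close" flag
#'   (default 0.1)
#' @return list with `summary` (tibble, one row per half: n, mean, sd,
#'   quantiles), `ks_statistic`, `threshold` and logical `pass`
#' @export
split_half_diagnostic <- function(ensemble, threshold = 0.1) {
  losses <- if (inherits(ensemble, "nodefit_ensemble")) ensemble$losses
            else as.numeric(ensemble)
  m <- length(losses)
  if (m < 2) stop("need at least 2 samples", call. = FALSE)
  half <- floor(m / 2)
  a <- losses[seq_len(half)]
  b <- losses[(half + 1):m]
  summarize_half <- function(x, label) {
    q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    tibble::tibble(half = label, n = length(x), mean = mean(x),
                   sd = stats::sd(x), q05 = q[1], q25 = q[2], median = q[3],
                   q75 = q[4], q95 = q[5])
  }
  ks <- suppressWarnings(stats::ks.test(a, b)$statistic)
  list(summary = dplyr::bind_rows(summarize_half(a, "first"),
                                  summarize_half(b, "second")),
       ks_statistic = unname(ks), threshold = threshold,
       pass = unname(ks) < threshold)
}

#' @export
print.nodefit_ensemble <- function(x, ...) {
  diag_txt <- if (is.null(x$diagnostic)) "not computed" else {
    sprintf("%.3f (%s)", x$diagnostic$ks_statistic,
            if (x$diagnostic$pass) "pass" else "fail")
  }
  cat(sprintf("<nodefit_ensemble> %d samples of %d parameters; loss %.4g +/- %.4g; split-half KS %s\n",
              nrow(x$samples), ncol(x$samples), mean(x$losses),
              stats::sd(x$losses), diag_txt))
  invisible(x)
}

#' Tidy a posterior ensemble
#'
#' @param x a `nodefit_ensemble`
#' @param ... unused
#' @return a tibble with one row per retained sample (`sample`, `loss`)
#' @export
tidy.nodefit_ensemble <- function(x, ...) {
  tibble::tibble(sample = seq_along(x$losses), loss = x$losses)
}

#' @rdname tidy.nodefit_ensemble
#' @export
glance.nodefit_ensemble <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$samples),
                 n_parameters = ncol(x$samples),
                 mean_loss = mean(x$losses), sd_loss = stats::sd(x$losses),
                 ks_statistic = x$diagnostic$ks_statistic,
                 diagnostic_pass = x$diagnostic$pass,
                 n_failed_steps = x$n_failed_steps)
}

#' Persist / load a posterior ensemble
#'
#' Writes a directory holding `samples.csv` (one row per sample),
#' `losses.csv`, `hyper.json` and `diagnostic.json`.
#'
#' @param ensemble a `nodefit_ensemble`
#' @param dir directory path (created if needed)
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smp <- tibble::as_tibble(ensemble$samples, .name_repair = "minimal")
  names(smp) <- param_labels(ensemble$spec)
  readr::write_csv(smp, file.path(dir, "samples.csv"))
  readr::write_csv(tibble::tibble(loss = ensemble$losses),
                   file.path(dir, "losses.csv"))
  jsonlite::write_json(unclass(ensemble$hyper), file.path(dir, "hyper.json"),
                       auto_unbox = TRUE, digits = I(17))
  diag <- ensemble$diagnostic
  if (!is.null(diag)) diag$summary <- as.list(diag$summary)
  jsonlite::write_json(diag %||% list(), file.path(dir, "diagnostic.json"),
                       auto_unbox = TRUE, digits = I(17))
  jsonlite::write_json(list(spec = unclass(ensemble$spec),
                            u0 = as.numeric(ensemble$u0),
                            n_failed_steps = ensemble$n_failed_steps),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  smp <- as.matrix(readr::read_csv(file.path(dir, "samples.csv"),
                                   show_col_types = FALSE, progress = FALSE))
  dimnames(smp) <- NULL
  losses <- readr::read_csv(file.path(dir, "losses.csv"),
                            show_col_types = FALSE, progress = FALSE)$loss
  h <- jsonlite::read_json(file.path(dir, "hyper.json"), simplifyVector = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  sp <- meta$spec
  spec <- model_spec(sp$family, n = sp$n, n_obs = sp$n_obs,
                     N = if (is.null(sp$N) || is.na(sp$N)) 20 else sp$N,
                     activation = sp$activation)
  ens <- structure(list(samples = smp, losses = losses,
                        hyper = psgld_hyper(h$epsilon, h$alpha, h$lam,
                                            h$n_warmup, h$n_collect, h$seed,
                                            h$temperature, h$fail_tol),
                        spec = spec, u0 = as.numeric(meta$u0),
                        n_failed_steps = meta$n_failed_steps,
                        diagnostic = NULL),
                   class = "nodefit_ensemble")
  if (length(ens$losses) >= 2) ens$diagnostic <- split_half_diagnostic(ens)
  ens
}
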