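#' Time-series tibbles
#'
#' Throughout the package a time series is an ordinary tibble whose first
#' column is `time` (strictly increasing, in years) and whose remaining
#' columns are observed variables on the abundance scale (strictly positive
#' for raw data). Helper accessors below keep the rest of the code honest
#' about that layout.
#'
#' @param series a series tibble
#' @name series
NULL

series_names <- function(series) setdiff(names(series), "time")

series_values <- function(series) {
  as.matrix(series[series_names(series)])
}

validate_series <- function(series, positive = FALSE) {
  if (!is.data.frame(series) || !"time" %in% names(series)) {
    stop("a series must be a data frame with a 'time' column", call. = FALSE)
  }
  if (names(series)[1] != "time") {
    stop("the 'time' column must come first", call. = FALSE)
  }
  if (ncol(series) < 2) stop("series has no variable columns", call. = FALSE)
  tm <- series$time
  if (anyNA(tm) || any(diff(tm) <= 0)) {
    stop("series times must be strictly increasing", call. = FALSE)
  }
  vals <- series_values(series)
  if (!all(is.finite(vals))) stop("series values must be finite", call. = FALSE)
  if (positive && any(vals <= 0)) {
    bad <- which(vals <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive value in variable '%s' at time %g",
                 series_names(series)[bad[2]], tm[bad[1]]), call. = FALSE)
  }
  invisible(series)
}

new_series <- function(times, values, names) {
  values <- matrix(values, nrow = length(times))
  colnames(values) <- names
  tibble::as_tibble(cbind(tibble::tibble(time = times),
                          tibble::as_tibble(values)))
}

#' Lotka-Volterra parameter set
#'
#' Parameters of the classic two-species predator-prey system
#' \deqn{du_1/dt = \alpha u_1 - \beta u_1 u_2, \quad
#'       du_2/dt = \delta u_1 u_2 - \gamma u_2.}
#' The defaults give a cycle period of roughly ten years
#' (period near the coexistence point is \eqn{2\pi/\sqrt{\alpha\gamma}}),
#' so a 90-year window shows about nine full oscillations, a convenient
#' stand-in for multi-decade predator-prey records.
#'
#' @param alpha prey per-capita growth rate (1/year)
#' @param beta predation rate (1/(abundance * year))
#' @param gamma predator per-capita death rate (1/year)
#' @param delta conversion rate of prey into predators (1/(abundance * year))
#' @param u0 initial abundances, positive length-2 vector (prey, predator)
#' @return an object of class `lv_params`
#' @export
lv_params <- function(alpha = 0.6, beta = 0.03, gamma = 0.66, delta = 0.022,
                      u0 = c(40, 15)) {
  rates <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("Lotka-Volterra rates must be non-negative", call. = FALSE)
  }
  if (alpha <= 0 || gamma <= 0) {
    stop("alpha and gamma must be strictly positive", call. = FALSE)
  }
  if (length(u0) != 2 || any(u0 <= 0)) {
    stop("u0 must be two strictly positive abundances", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 u0 = as.numeric(u0)),
            class = "lv_params")
}

#' Simulate a Lotka-Volterra predator-prey series
#'
#' Integrates the deterministic system on a regular time grid with a
#' high-accuracy solver (`lsoda`, rtol = atol = 1e-8) so that fixture error
#' is negligible relative to downstream test tolerances.
#'
#' @param params an [lv_params()] object
#' @param t_start,t_end simulation window (years), `t_end > t_start`
#' @param step output spacing (years), positive
#' @param names variable labels for the two species
#' @return a series tibble with columns `time`, and the two species
#' @examples
#' sim <- simulate_lv(lv_params(), 0, 90, 1)
#' nrow(sim)  # 91 yearly observations
#' @export
simulate_lv <- function(params, t_start = 0, t_end = 90, step = 1,
                        names = c("prey", "predator")) {
  stopifnot(inherits(params, "lv_params"))
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  times <- seq(t_start, t_end, by = step)
  rhs <- function(t, u, p) {
    list(c(p$alpha * u[1] - p$beta * u[1] * u[2],
           p$delta * u[1] * u[2] - p$gamma * u[2]))
  }
  sol <- deSolve::ode(y = params$u0, times = times, func = rhs, parms = params,
                      method = "lsoda", rtol = 1e-8, atol = 1e-8)
  check_solver_output(sol, times, params)
  out <- new_series(times, sol[, -1, drop = FALSE], names)
  validate_series(out, positive = TRUE)
}

#' Add multiplicative lognormal observation noise
#'
#' Each value is multiplied by `exp(e)` with `e ~ Normal(0, sigma^2)` drawn
#' independently per point. On the log scale used for fitting this is plain
#' additive Gaussian noise, and abundances stay positive.
#'
#' @param series a positive series tibble
#' @param sigma standard deviation of the log-scale noise, `>= 0`
#' @param seed integer RNG seed; same seed gives identical output
#' @return a series tibble of the same shape
#' @export
add_noise <- function(series, sigma = 0.1, seed = 1) {
  validate_series(series, positive = TRUE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  vals <- series_values(series)
  eps <- withr::with_seed(seed, stats::rnorm(length(vals), 0, sigma))
  noisy <- vals * exp(matrix(eps, nrow = nrow(vals)))
  new_series(series$time, noisy, series_names(series))
}

#' Read and write series CSV files
#'
#' The on-disk dialect is a plain UTF-8 CSV with a header row
#' `time,<var1>,<var2>,...`, times in years, no index column. Values
#' round-trip at full double precision.
#'
#' @param series a series tibble
#' @param path file path
#' @return `read_series_csv` returns a validated series tibble.
#' @export
write_series_csv <- function(series, path) {
  validate_series(series)
  # 17 significant digits guarantee a bit-exact double round trip
  out <- series
  out[] <- lapply(out, function(x) sprintf("%.17g", x))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  # base read.csv: strtod is correctly rounded, so 17-digit values
  # round-trip bit-exactly (fast float parsers can be off by one ulp)
  df <- tryCatch(
    tibble::as_tibble(utils::read.csv(path, check.names = FALSE)),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (ncol(df) < 2 || names(df)[1] != "time") {
    stop(sprintf("'%s': first column must be 'time', found '%s'",
                 path, names(df)[1]), call. = FALSE)
  }
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad) > 0) {
    stop(sprintf("'%s': non-numeric column '%s'", path, names(df)[bad[1]]),
         call. = FALSE)
  }
  if (any(diff(df$time) <= 0)) {
    i <- which(diff(df$time) <= 0)[1]
    stop(sprintf("'%s': times not strictly increasing at data line %d",
                 path, i + 1), call. = FALSE)
  }
  validate_series(tibble::as_tibble(df))
}

#' Plot a time series
#'
#' @param series a series tibble
#' @return a ggplot object, one facet panel per variable
#' @export
plot_series <- function(series) {
  validate_series(series)
  long <- tidyr::pivot_longer(series, -"time",
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = NULL)
}
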