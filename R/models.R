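#' Model specification
#'
#' Two derivative-field families share one interface:
#'
#' * `ode`: \eqn{du/dt = f(S u - b)} with an `n x n` matrix `S` and an
#'   `n`-vector `b` (so `n^2 + n` parameters), the activation `f` applied
#'   independently to each dimension;
#' * `node`: a two-layer neural network, `n` inputs to `N` hidden nodes
#'   (weights plus one constant each, then the activation), then a linear
#'   layer back to `n` outputs (weights plus one constant each, no
#'   activation), giving `(n + 1) N + n (N + 1)` parameters.
#'
#' The first `n_obs` state dimensions are compared to data; the remaining
#' `n - n_obs` are dummy variables that lift the trajectory geometry into
#' higher dimensions without being observed.
#'
#' @param family `"ode"` or `"node"`
#' @param n total number of state variables (observed + dummy)
#' @param n_obs number of observed variables (2 for a predator-prey pair)
#' @param N hidden-node count, NODE only
#' @param activation `"tanh"` (default) or `"identity"`
#' @return an object of class `model_spec`
#' @examples
#' n_parameters(model_spec("node", n = 2, N = 20))  # 102
#' n_parameters(model_spec("ode", n = 3))           # 12
#' @export
model_spec <- function(family = c("ode", "node"), n = 2, n_obs = 2, N = 20,
                       activation = c("tanh", "identity")) {
  family <- match.arg(family)
  activation <- match.arg(activation)
  if (n_obs < 1 || n < n_obs) stop("need n >= n_obs >= 1", call. = FALSE)
  if (family == "node" && N < 1) stop("need N >= 1 for node", call. = FALSE)
  structure(list(family = family, n = as.integer(n),
                 n_obs = as.integer(n_obs),
                 N = if (family == "node") as.integer(N) else NA_integer_,
                 activation = activation),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: n = %d (%d observed)%s, activation = %s, %d parameters\n",
              x$family, x$n, x$n_obs,
              if (x$family == "node") sprintf(", N = %d", x$N) else "",
              x$activation, n_parameters(x)))
  invisible(x)
}

#' @rdname model_spec
#' @param spec a `model_spec`
#' @export
n_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  n <- spec$n
  if (spec$family == "ode") n * n + n
  else (n + 1L) * spec$N + n * (spec$N + 1L)
}

activation_fun <- function(name) {
  switch(name,
         tanh = list(f = tanh, df = function(x) 1 - tanh(x)^2),
         identity = list(f = identity, df = function(x) rep(1, length(x))),
         stop("unknown activation: ", name, call. = FALSE))
}

#' Structured views of a flat parameter vector
#'
#' The flat order is `c(vec(S), b)` for the ODE family and
#' `c(vec(W1), b1, vec(W2), b2)` for the NODE family (matrices stored
#' column-major, R's native `vec`). `param_views` and `flatten_params`
#' round-trip exactly.
#'
#' @param spec a `model_spec`
#' @param flat numeric vector of length `n_parameters(spec)`
#' @return `param_views`: a named list of matrices/vectors;
#'   `flatten_params`: the flat numeric vector; `param_labels`: one label
#'   per flat entry (e.g. `"S[2,1]"`, `"W1[3,2]"`).
#' @export
param_views <- function(spec, flat) {
  p <- n_parameters(spec)
  if (length(flat) != p) {
    stop(sprintf("expected %d parameters, got %d", p, length(flat)),
         call. = FALSE)
  }
  n <- spec$n
  if (spec$family == "ode") {
    list(S = matrix(flat[1:(n * n)], n, n), b = flat[n * n + 1:n])
  } else {
    N <- spec$N
    i <- 0
    W1 <- matrix(flat[i + 1:(N * n)], N, n); i <- i + N * n
    b1 <- flat[i + 1:N]; i <- i + N
    W2 <- matrix(flat[i + 1:(n * N)], n, N); i <- i + n * N
    b2 <- flat[i + 1:n]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
}

#' @rdname param_views
#' @param views a list as returned by `param_views`
#' @export
flatten_params <- function(spec, views) {
  flat <- if (spec$family == "ode") {
    c(as.vector(views$S), views$b)
  } else {
    c(as.vector(views$W1), views$b1, as.vector(views$W2), views$b2)
  }
  stopifnot(length(flat) == n_parameters(spec))
  as.numeric(flat)
}

#' @rdname param_views
#' @export
param_labels <- function(spec) {
  n <- spec$n
  idx <- function(nm, nr, nc) {
    as.vector(outer(seq_len(nr), seq_len(nc),
                    function(i, j) sprintf("%s[%d,%d]", nm, i, j)))
  }
  if (spec$family == "ode") {
    c(idx("S", n, n), sprintf("b[%d]", seq_len(n)))
  } else {
    N <- spec$N
    c(idx("W1", N, n), sprintf("b1[%d]", seq_len(N)),
      idx("W2", n, N), sprintf("b2[%d]", seq_len(n)))
  }
}

#' Random parameter initialization for fitting
#'
#' ODE entries are drawn Normal(0, 0.1); NODE weights use fan-in-scaled
#' normals (sd `1/sqrt(fan_in)`) with zero biases, the standard neural
#' network starting point.
#'
#' @param spec a `model_spec`
#' @param seed integer RNG seed
#' @return flat numeric parameter vector
#' @export
init_parameters <- function(spec, seed = 1) {
  n <- spec$n
  withr::with_seed(seed, {
    if (spec$family == "ode") {
      stats::rnorm(n_parameters(spec), 0, 0.1)
    } else {
      N <- spec$N
      flatten_params(spec, list(
        W1 = matrix(stats::rnorm(N * n, 0, 1 / sqrt(n)), N, n),
        b1 = rep(0, N),
        W2 = matrix(stats::rnorm(n * N, 0, 1 / sqrt(N)), n, N),
        b2 = rep(0, n)))
    }
  })
}

#' Initial state for a trajectory
#'
#' The observed dimensions are pinned to the target data at its first time
#' point; dummy dimensions get random draws from Uniform(-1, 1) on the
#' working (log-centered) scale, reproducible from the seed.
#'
#' @param target a `smoothed_series` (or any series tibble)
#' @param spec a `model_spec`
#' @param seed integer RNG seed for the dummy draws
#' @return numeric state vector of length `spec$n`, with attribute `seed`
#' @export
initial_state <- function(target, spec, seed = 1) {
  vals <- series_values(target)
  if (ncol(vals) < spec$n_obs) {
    stop("target has fewer variables than n_obs", call. = FALSE)
  }
  u0 <- numeric(spec$n)
  u0[seq_len(spec$n_obs)] <- vals[1, seq_len(spec$n_obs)]
  n_dummy <- spec$n - spec$n_obs
  if (n_dummy > 0) {
    u0[spec$n_obs + seq_len(n_dummy)] <-
      withr::with_seed(seed, stats::runif(n_dummy, -1, 1))
  }
  attr(u0, "seed") <- seed
  u0
}

#' Evaluate a derivative field
#'
#' @param spec a `model_spec`
#' @param flat flat parameter vector
#' @param u state vector of length `spec$n`
#' @return `du/dt`, numeric vector of length `spec$n`
#' @export
field_eval <- function(spec, flat, u) {
  if (length(u) != spec$n) {
    stop(sprintf("state has length %d, expected %d", length(u), spec$n),
         call. = FALSE)
  }
  v <- param_views(spec, flat)
  act <- activation_fun(spec$activation)
  if (spec$family == "ode") {
    as.vector(act$f(v$S %*% u - v$b))
  } else {
    as.vector(v$W2 %*% act$f(v$W1 %*% u + v$b1) + v$b2)
  }
}

#' Field Jacobians for forward sensitivity analysis
#'
#' Returns the field value together with its Jacobian with respect to the
#' state (`Ju`, n x n) and to the flat parameter vector (`Jtheta`, n x p).
#' These drive the sensitivity ODE \eqn{\dot S_u = J_u S_u + J_\theta} that
#' differentiates a trajectory through the solver.
#'
#' @inheritParams field_eval
#' @return list with elements `f`, `Ju`, `Jtheta`
#' @export
field_jacobians <- function(spec, flat, u) {
  v <- param_views(spec, flat)
  act <- activation_fun(spec$activation)
  n <- spec$n
  if (spec$family == "ode") {
    z <- as.vector(v$S %*% u - v$b)
    a <- act$df(z)
    Ju <- a * v$S                       # diag(a) %*% S
    # d f_i / d S[k,l] = a_i u_l [i == k]; column-major S => kron(u', diag(a))
    Jtheta <- cbind(kronecker(t(u), diag(a, n)), diag(-a, n))
    list(f = act$f(z), Ju = Ju, Jtheta = Jtheta)
  } else {
    h <- as.vector(v$W1 %*% u + v$b1)
    a <- act$df(h)
    phi <- act$f(h)
    W2a <- sweep(v$W2, 2, a, `*`)       # W2 %*% diag(a), n x N
    Ju <- W2a %*% v$W1
    J_W1 <- kronecker(t(u), W2a)        # n x (N n)
    J_b1 <- W2a                         # n x N
    J_W2 <- kronecker(t(phi), diag(1, n))  # n x (n N)
    J_b2 <- diag(1, n)
    list(f = as.vector(v$W2 %*% phi + v$b2),
         Ju = Ju, Jtheta = cbind(J_W1, J_b1, J_W2, J_b2))
  }
}

#' Serialize parameters to JSON
#'
#' Writes the flat vector plus a spec header; values survive the round trip
#' bit-exactly (17 significant digits).
#'
#' @param spec a `model_spec`
#' @param flat flat parameter vector
#' @param path output path
#' @export
write_params_json <- function(spec, flat, path) {
  stopifnot(length(flat) == n_parameters(spec))
  obj <- list(spec = unclass(spec), flat = as.numeric(flat))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_params_json
#' @return `read_params_json`: list with elements `spec` and `flat`
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- obj$spec
  spec <- model_spec(sp$family, n = sp$n, n_obs = sp$n_obs,
                     N = if (is.null(sp$N) || is.na(sp$N)) 20 else sp$N,
                     activation = sp$activation)
  list(spec = spec, flat = as.numeric(obj$flat))
}
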