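#' Shared time discretisation of all paths
#'
#' @param dt Positive time step \eqn{\Delta t}.
#' @param n_steps Number of steps \eqn{N_t \ge 1}; positions are indexed
#'   `0..n_steps` at times \eqn{t = i \Delta t}, so the duration is always
#'   the derived quantity \eqn{T = N_t \Delta t}.
#' @return Object of class `bd_grid` with elements `dt`, `n_steps`,
#'   `duration`.
#' @examples
#' time_grid(1e-3, 1000)$duration  # 1
#' @export
time_grid <- function(dt, n_steps) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive finite number", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L)
    stop("n_steps must be a positive integer", call. = FALSE)
  structure(list(dt = dt, n_steps = n_steps, duration = dt * n_steps),
            class = "bd_grid")
}

#' @export
print.bd_grid <- function(x, ...) {
  cat(sprintf("<bd_grid> dt = %g, n_steps = %d, T = %g\n",
              x$dt, x$n_steps, x$duration))
  invisible(x)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(a$dt, b$dt)) && a$n_steps == b$n_steps
}

#' Pair a potential with a temperature to define a Brownian process
#'
#' A process is the overdamped Langevin SDE
#' \eqn{dx_t = f(x_t) dt + \sqrt{2\epsilon}\, dW_t} determined by the drift
#' \eqn{f = -U'} of `potential` and the reservoir temperature `temperature`
#' (\eqn{\epsilon}, in energy units).
#'
#' @param potential A [make_potential()] object.
#' @param temperature Positive temperature \eqn{\epsilon}.
#' @return Object of class `bd_process`.
#' @export
process_spec <- function(potential, temperature) {
  stopifnot(inherits(potential, "bd_potential"))
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a positive finite number", call. = FALSE)
  structure(list(potential = potential, temperature = temperature),
            class = "bd_process")
}

#' @export
print.bd_process <- function(x, ...) {
  cat(sprintf("<bd_process> potential = %s, eps = %g\n",
              x$potential$name, x$temperature))
  invisible(x)
}

#' Wrap a position matrix as a path ensemble
#'
#' Paths are stored column-wise: a `(n_steps + 1) x n_paths` numeric matrix
#' whose row `i + 1` holds the positions at time \eqn{i \Delta t}. The grid
#' (and optionally the generating process) travel with the matrix as
#' attributes so functionals never need them re-stated.
#'
#' @param x Numeric vector (one path) or matrix (one column per path).
#' @param grid A [time_grid()].
#' @param process Optional generating [process_spec()], kept as provenance.
#' @param provenance Optional list (seed, generator name).
#' @return Object of class `bd_paths`.
#' @export
as_paths <- function(x, grid, process = NULL, provenance = NULL) {
  stopifnot(inherits(grid, "bd_grid"))
  x <- as.matrix(x)
  if (nrow(x) != grid$n_steps + 1L)
    stop(sprintf("paths must have n_steps + 1 = %d rows, got %d",
                 grid$n_steps + 1L, nrow(x)), call. = FALSE)
  if (!all(is.finite(x)))
    stop("path positions must all be finite", call. = FALSE)
  structure(x, grid = grid, process = process, provenance = provenance,
            class = c("bd_paths", "matrix", "array"))
}

#' @export
print.bd_paths <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<bd_paths> %d path(s), n_steps = %d, dt = %g\n",
              ncol(x), g$n_steps, g$dt))
  invisible(x)
}

path_grid <- function(paths) {
  g <- attr(paths, "grid")
  if (is.null(g)) stop("paths carry no time grid; use as_paths()", call. = FALSE)
  g
}

#' Sample independent noise histories
#'
#' A noise history is the sequence \eqn{\{\xi_i\}} of `n_steps` iid standard
#' normal variates that drives one Euler-Maruyama path. Histories are drawn
#' from R's Mersenne-Twister stream seeded once with `seed` and filled
#' column-major, so path `k` always occupies the same contiguous block of
#' the stream: the ensemble is fully reproducible from
#' `(seed, grid, n_paths)` and extending `n_paths` leaves earlier paths
#' unchanged.
#'
#' @param grid A [time_grid()].
#' @param n_paths Number of independent histories (columns), `>= 1`.
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @return `n_steps x n_paths` matrix of class `bd_noise` with attributes
#'   `grid` and `seed`.
#' @export
sample_noise <- function(grid, n_paths, seed = NULL) {
  stopifnot(inherits(grid, "bd_grid"))
  n_paths <- as.integer(n_paths)
  if (is.na(n_paths) || n_paths < 1L)
    stop("n_paths must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  xi <- matrix(stats::rnorm(grid$n_steps * n_paths), grid$n_steps, n_paths)
  structure(xi, grid = grid, seed = seed,
            class = c("bd_noise", "matrix", "array"))
}

#' Propagate paths by the explicit Euler-Maruyama scheme
#'
#' Applies
#' \eqn{x_i = x_{i-1} + f(x_{i-1}) \Delta t + \sqrt{2 \epsilon \Delta t}\,\xi_i}
#' with the drift evaluated at the left endpoint. Every column of `noise`
#' produces one path; all paths start at `x0`.
#'
#' @param process A [process_spec()].
#' @param grid A [time_grid()]; must equal the grid the noise was drawn on.
#' @param noise `n_steps x n_paths` matrix (e.g. from [sample_noise()]).
#' @param x0 Starting position (scalar, or vector of length `n_paths`).
#' @return A [as_paths()] ensemble carrying `process` as provenance.
#' @export
propagate <- function(process, grid, noise, x0 = 0) {
  stopifnot(inherits(process, "bd_process"), inherits(grid, "bd_grid"))
  ng <- attr(noise, "grid")
  if (!is.null(ng) && !grids_equal(ng, grid))
    stop("noise was sampled on a different time grid", call. = FALSE)
  noise <- as.matrix(noise)
  if (nrow(noise) != grid$n_steps)
    stop("noise must have n_steps rows", call. = FALSE)
  n <- ncol(noise)
  dt <- grid$dt
  amp <- sqrt(2 * process$temperature * dt)
  f <- process$potential$force
  x <- matrix(0, grid$n_steps + 1L, n)
  x[1L, ] <- x0
  cur <- x[1L, ]
  for (i in seq_len(grid$n_steps)) {
    cur <- cur + f(cur) * dt + amp * noise[i, ]
    if (!all(is.finite(cur)))
      stop(sprintf(
        "non-finite position at step %d: dt = %g is unstable for potential '%s'",
        i, dt, process$potential$name), call. = FALSE)
    x[i + 1L, ] <- cur
  }
  as_paths(x, grid, process = process,
           provenance = list(seed = attr(noise, "seed"),
                             generator = "euler_maruyama"))
}

#' Recover the noise history that generated a path
#'
#' Inverts the Euler-Maruyama update:
#' \eqn{\xi_i = \sqrt{\Delta t / 2\epsilon}\,
#' \left( (x_i - x_{i-1}) / \Delta t - f(x_{i-1}) \right)}.
#' Composed with [propagate()] this is an exact bijection between noise
#' histories and paths (to floating-point roundoff).
#'
#' @param process A [process_spec()].
#' @param paths A [as_paths()] ensemble.
#' @return `n_steps x n_paths` matrix of class `bd_noise`.
#' @export
recover_noise <- function(process, paths) {
  stopifnot(inherits(process, "bd_process"))
  grid <- path_grid(paths)
  x <- unclass(paths)
  dt <- grid$dt
  eps <- process$temperature
  n1 <- nrow(x)
  dx <- x[-1L, , drop = FALSE] - x[-n1, , drop = FALSE]
  fl <- process$potential$force(x[-n1, , drop = FALSE])
  xi <- sqrt(dt / (2 * eps)) * (dx / dt - fl)
  structure(xi, grid = grid, seed = NULL,
            class = c("bd_noise", "matrix", "array"))
}

#' Map paths of one process onto another through the common noise
#'
#' Realises the bijective map between two processes driven by the same
#' thermal reservoir: the noise history of each path under its generating
#' process `source` is extracted and re-propagated under `target` from the
#' same starting point. Both processes must share the grid and temperature
#' (the reservoir is common to both).
#'
#' @param paths Paths generated under `source`.
#' @param target The process to map onto.
#' @param source Generating process; defaults to the `process` attribute
#'   carried by `paths`.
#' @return Paths under `target` sharing noise and start point with `paths`.
#' @export
map_path <- function(paths, target, source = NULL) {
  stopifnot(inherits(target, "bd_process"))
  if (is.null(source)) source <- attr(paths, "process")
  if (is.null(source))
    stop("paths carry no generating process; pass `source`", call. = FALSE)
  if (!isTRUE(all.equal(source$temperature, target$temperature)))
    stop("common-noise map requires identical temperatures", call. = FALSE)
  grid <- path_grid(paths)
  xi <- recover_noise(source, paths)
  propagate(target, grid, xi, x0 = unclass(paths)[1L, ])
}

#' Exact one-step transition of the Ornstein-Uhlenbeck process
#'
#' The OU process \eqn{dx = -Ax\,dt + \sqrt{2\epsilon}\,dW} has the exact
#' discrete transition
#' \eqn{x' = x e^{-A \Delta t} +
#' \sqrt{(\epsilon/A)(1 - e^{-2 A \Delta t})}\;\xi}.
#' Used as a reference against Euler-Maruyama and inside the OU bridge
#' sampler.
#'
#' @param x Current position(s).
#' @param A OU stiffness, `> 0`.
#' @param eps Temperature \eqn{\epsilon > 0}.
#' @param dt Time step.
#' @param xi Standard normal variate(s), same length as `x` or scalar.
#' @return Position(s) after one step.
#' @export
ou_exact_step <- function(x, A, eps, dt, xi) {
  stopifnot(A > 0, eps > 0, dt > 0)
  x * exp(-A * dt) + sqrt((eps / A) * (1 - exp(-2 * A * dt))) * xi
}

#' Sample exact Brownian bridges
#'
#' Draws paths of the free Brownian process
#' \eqn{dz = \sqrt{2\epsilon}\,dW} conditioned on `z(0) = x0` and
#' `z(T) = xT`. Because the discrete free path is a Gaussian random walk,
#' conditioning on the terminal value is realised exactly by the linear
#' correction \eqn{B_i = x_0 + W_i - (t_i / T)(W_{N_t} - (x_T - x_0))}
#' applied to a free path \eqn{W}; endpoints are then pinned exactly and
#' all interior marginals have the bridge law, with variance
#' \eqn{2 \epsilon t (1 - t/T)}.
#'
#' @param grid A [time_grid()].
#' @param eps Temperature.
#' @param x0,xT Pinned endpoints.
#' @param n_paths Number of bridges.
#' @param seed Optional integer seed.
#' @return A [as_paths()] ensemble (no `process` attribute: the bridge is a
#'   conditioned law, not a drift process).
#' @export
sample_brownian_bridge <- function(grid, eps, x0 = 0, xT = 0,
                                   n_paths = 1L, seed = NULL) {
  stopifnot(inherits(grid, "bd_grid"), eps > 0)
  xi <- sample_noise(grid, n_paths, seed)
  amp <- sqrt(2 * eps * grid$dt)
  w <- apply(amp * unclass(xi), 2L, cumsum)
  w <- rbind(0, matrix(w, grid$n_steps, n_paths))
  frac <- seq(0, 1, length.out = grid$n_steps + 1L)
  drift_off <- outer(frac, w[grid$n_steps + 1L, ] - (xT - x0))
  b <- x0 + w - drift_off
  b[grid$n_steps + 1L, ] <- xT  # exact pin (kills roundoff in frac*wT)
  as_paths(b, grid, provenance = list(seed = seed, generator = "brownian_bridge"))
}

#' Sample exact Ornstein-Uhlenbeck bridges
#'
#' Draws OU paths (stiffness `A`, temperature `eps`) conditioned on both
#' endpoints by sequential Gaussian conditioning: the exact OU transition
#' kernel of [ou_exact_step()] is combined at each step with the exact
#' Gaussian likelihood of reaching `xT` over the remaining time (the Doob
#' h-transform of the linear process, closed-form because the process is
#' Gaussian). Marginals are therefore unbiased at any `dt`.
#'
#' @inheritParams sample_brownian_bridge
#' @param A OU stiffness, `> 0`.
#' @return A [as_paths()] ensemble with pinned endpoints.
#' @export
sample_ou_bridge <- function(grid, eps, A, x0 = 0, xT = 0,
                             n_paths = 1L, seed = NULL) {
  stopifnot(inherits(grid, "bd_grid"), eps > 0, A > 0)
  xi <- unclass(sample_noise(grid, n_paths, seed))
  nt <- grid$n_steps
  dt <- grid$dt
  v1 <- (eps / A) * (1 - exp(-2 * A * dt))   # one-step conditional variance
  x <- matrix(0, nt + 1L, n_paths)
  x[1L, ] <- x0
  cur <- x[1L, ]
  for (i in seq_len(nt)) {
    m1 <- cur * exp(-A * dt)
    if (i == nt) {
      cur <- rep(xT, n_paths)
    } else {
      trem <- (nt - i) * dt                  # time remaining after this step
      cfac <- exp(-A * trem)
      v2 <- (eps / A) * (1 - exp(-2 * A * trem))
      post_var <- 1 / (1 / v1 + cfac^2 / v2)
      post_mean <- post_var * (m1 / v1 + xT * cfac / v2)
      cur <- post_mean + sqrt(post_var) * xi[i, ]
    }
    x[i + 1L, ] <- cur
  }
  as_paths(x, grid, provenance = list(seed = seed, generator = "ou_bridge"))
}
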