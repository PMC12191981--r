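ensemble_parts <- function(paths) {
  grid <- path_grid(paths)
  x <- unclass(paths)
  n1 <- nrow(x)
  list(grid = grid,
       dx = x[-1L, , drop = FALSE] - x[-n1, , drop = FALSE],
       left = x[-n1, , drop = FALSE],
       x0 = x[1L, ], xT = x[n1, ])
}

#' Discrete Onsager-Machlup functional
#'
#' Negative log path density (up to the Gaussian normalisation) of a
#' discrete Brownian path under `process`:
#' \deqn{I = \frac{\Delta t}{4\epsilon} \sum_{i=1}^{N_t}
#'   \left( \frac{x_i - x_{i-1}}{\Delta t} - f(x_{i-1}) \right)^2 .}
#' Equivalently \eqn{I = \frac{1}{2}\sum_i \xi_i^2} in terms of the
#' recovered noise, so over self-generated paths \eqn{I} is
#' chi-square-distributed with mean and variance \eqn{N_t / 2}: it is a
#' property of the reservoir noise, not of where the path goes.
#'
#' @param process A [process_spec()].
#' @param paths A [as_paths()] ensemble.
#' @return Numeric vector, one non-negative value per path.
#' @export
om_functional <- function(process, paths) {
  p <- ensemble_parts(paths)
  dt <- p$grid$dt
  fl <- process$potential$force(p$left)
  p$grid$dt / (4 * process$temperature) * colSums((p$dx / dt - fl)^2)
}

#' Drift-dependent part of the Onsager-Machlup functional
#'
#' The difference of two OM functionals evaluated on the *same* path
#' cancels the drift-independent kinetic term; what survives is
#' \deqn{J = \frac{\Delta t}{2\epsilon} \sum_{i=1}^{N_t}
#'   \left( \tfrac{1}{2} f^2(z_{i-1}) -
#'   \frac{z_i - z_{i-1}}{\Delta t} f(z_{i-1}) \right),}
#' so that \eqn{I_a - I_b = J_a - J_b} exactly for any two processes
#' sharing the grid and temperature. `J` vanishes identically for zero
#' force.
#'
#' @inheritParams om_functional
#' @return Numeric vector, one value per path.
#' @export
j_functional <- function(process, paths) {
  p <- ensemble_parts(paths)
  dt <- p$grid$dt
  fl <- process$potential$force(p$left)
  dt / (2 * process$temperature) *
    colSums(0.5 * fl^2 - (p$dx / dt) * fl)
}

#' Continuous-time limit of the J functional
#'
#' Applying Ito's integration by parts to the stochastic integral in `J`
#' turns it into a boundary term plus an ordinary time integral:
#' \deqn{J^{CT} = \frac{U(z_T) - U(z_0)}{2\epsilon} +
#'   \frac{1}{2\epsilon} \int_0^T
#'   \left( \tfrac{1}{2} f^2(z_t) - \epsilon U''(z_t) \right) dt,}
#' the \eqn{-\epsilon U''} term being the Ito correction. The boundary term
#' uses exact endpoint energies; the integral is a left-point (Ito)
#' Riemann sum on the grid — a trapezoid rule would smuggle in a
#' Stratonovich correction.
#'
#' @inheritParams om_functional
#' @return Numeric vector, one value per path.
#' @export
j_continuous <- function(process, paths) {
  p <- ensemble_parts(paths)
  dt <- p$grid$dt
  eps <- process$temperature
  pot <- process$potential
  fl <- pot$force(p$left)
  boundary <- (pot$energy(p$xT) - pot$energy(p$x0)) / (2 * eps)
  boundary + dt / (2 * eps) *
    colSums(0.5 * fl^2 - eps * pot$curvature(p$left))
}

#' Path potential of the Ito-Girsanov action
#'
#' \deqn{G(x) = \tfrac{1}{2} f^2(x) - \epsilon U''(x).}
#' The state-dependent part of the continuous-time (Ito-Girsanov) action;
#' its Laplacian term is what makes that action path-dependent and, on
#' discrete-time paths, an uncontrolled approximation.
#'
#' @param potential A [make_potential()] object.
#' @param eps Temperature \eqn{\epsilon}.
#' @param x Position(s).
#' @return Numeric, same shape as `x`.
#' @export
path_potential_G <- function(potential, eps, x) {
  stopifnot(inherits(potential, "bd_potential"))
  0.5 * potential$force(x)^2 - eps * potential$curvature(x)
}

#' Ito-Girsanov action on a discrete path
#'
#' The continuous-time change of measure written as an OM-like functional,
#' evaluated on the discrete grid:
#' \deqn{I_{IG} = \frac{\Delta t}{2\epsilon} \sum_{i=1}^{N_t}
#'   \left( \tfrac{1}{2} \left(\frac{x_i - x_{i-1}}{\Delta t}\right)^2 +
#'   G(x_{i-1}) \right).}
#'
#' @inheritParams om_functional
#' @return Numeric vector, one value per path.
#' @export
ig_action <- function(process, paths) {
  p <- ensemble_parts(paths)
  dt <- p$grid$dt
  eps <- process$temperature
  g <- path_potential_G(process$potential, eps, p$left)
  dt / (2 * eps) * colSums(0.5 * (p$dx / dt)^2 + g)
}

#' Quadratic variation of discrete paths
#'
#' \eqn{[X]_T = \sum_i (x_i - x_{i-1})^2}. For any of these diffusions the
#' continuous-time limit is \eqn{2 \epsilon T} almost surely, independent
#' of the drift — the drift contributes only \eqn{O(\Delta t)}.
#'
#' @param paths A [as_paths()] ensemble.
#' @return Numeric vector of non-negative values, one per path.
#' @export
quadratic_variation <- function(paths) {
  p <- ensemble_parts(paths)
  colSums(p$dx^2)
}
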