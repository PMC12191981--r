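#' Construct a built-in one-dimensional potential
#'
#' A potential bundles three vectorised callables: the energy \eqn{U(x)}, the
#' force \eqn{f(x) = -U'(x)} that enters the drift of the overdamped Langevin
#' equation, and the curvature \eqn{U''(x)} needed by the continuous-time
#' (Ito-Girsanov) functionals. All built-in forms are smooth and bounded
#' below, as thermodynamic consistency requires (Kato-class potentials).
#'
#' Built-in families:
#' \describe{
#'   \item{`zero`}{\eqn{U = 0}; free Brownian motion.}
#'   \item{`linear`}{\eqn{U(x) = -c x}, i.e. constant drift \eqn{f \equiv c}.
#'     Parameter `c`.}
#'   \item{`harmonic`}{\eqn{U(x) = A x^2 / 2}, the Ornstein-Uhlenbeck
#'     restoring potential with stiffness `A > 0`.}
#'   \item{`double_well`}{\eqn{U(x) = h (1 - (s/a)^2)^2} with
#'     \eqn{s = x} for \eqn{x \le 0} and \eqn{s = x / w} for \eqn{x > 0}:
#'     two degenerate minima near \eqn{-a} and \eqn{+aw} separated by a
#'     barrier of height `h` at the origin, the right-hand well broader by
#'     the factor `w`. The piecewise rescaling makes the potential
#'     continuously differentiable everywhere but the curvature jumps at
#'     \eqn{x = 0} when \eqn{w \neq 1} (see [check_consistency()]).}
#' }
#'
#' @param name One of `"zero"`, `"linear"`, `"harmonic"`, `"double_well"`.
#' @param params Named list of parameters for the chosen family. `linear`
#'   needs `c`; `harmonic` needs `A > 0`; `double_well` needs `h > 0`,
#'   `a > 0`, `w > 0`.
#' @return An object of class `bd_potential`: a list with elements `name`,
#'   `params`, and the vectorised functions `energy`, `force`, `curvature`.
#'   Each callable preserves the shape (including `dim`) of its input.
#' @examples
#' ou <- make_potential("harmonic", list(A = 2))
#' ou$force(0.5)      # -1
#' ou$curvature(0.4)  # 2
#' @export
make_potential <- function(name, params = list()) {
  name <- match.arg(name, c("zero", "linear", "harmonic", "double_well"))
  need <- function(key, check = function(v) TRUE, what = "finite") {
    v <- params[[key]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("potential '%s' requires a finite numeric parameter '%s'",
                   name, key), call. = FALSE)
    if (!check(v))
      stop(sprintf("parameter '%s' of potential '%s' must be %s (got %g)",
                   key, name, what, v), call. = FALSE)
    v
  }
  pos <- function(v) v > 0

  pot <- switch(name,
    zero = list(
      energy    = function(x) x * 0,
      force     = function(x) x * 0,
      curvature = function(x) x * 0,
      params    = list()
    ),
    linear = {
      cc <- need("c")
      list(
        energy    = function(x) -cc * x,
        force     = function(x) x * 0 + cc,
        curvature = function(x) x * 0,
        params    = list(c = cc)
      )
    },
    harmonic = {
      A <- need("A", pos, "positive")
      list(
        energy    = function(x) A * x^2 / 2,
        force     = function(x) -A * x,
        curvature = function(x) x * 0 + A,
        params    = list(A = A)
      )
    },
    double_well = {
      h <- need("h", pos, "positive")
      a <- need("a", pos, "positive")
      w <- need("w", pos, "positive")
      # s(x) rescales only the right branch; s' = 1 (x<=0) or 1/w (x>0)
      list(
        energy = function(x) {
          s <- ifelse(x <= 0, x, x / w)
          h * (1 - (s / a)^2)^2
        },
        force = function(x) {
          sp <- ifelse(x <= 0, 1, 1 / w)
          s  <- x * sp
          4 * h * s * (1 - (s / a)^2) * sp / a^2
        },
        curvature = function(x) {
          sp <- ifelse(x <= 0, 1, 1 / w)
          s  <- x * sp
          -4 * h * (1 - 3 * (s / a)^2) * sp^2 / a^2
        },
        params = list(h = h, a = a, w = w)
      )
    }
  )
  structure(list(name = name, params = pot$params, energy = pot$energy,
                 force = pot$force, curvature = pot$curvature),
            class = "bd_potential")
}

#' @export
print.bd_potential <- function(x, ...) {
  ps <- if (length(x$params) == 0L) "" else
    paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  cat(sprintf("<bd_potential> %s(%s)\n", x$name, ps))
  invisible(x)
}

#' Finite-difference self-consistency check of a potential
#'
#' Verifies on a probe grid that the analytic force matches the central
#' finite difference of the energy, and the analytic curvature matches the
#' second central difference. Errors are reported relative to
#' \eqn{\max(1, |value|)} so points where the force vanishes (minima) do not
#' produce spurious failures. For the asymmetric `double_well` the curvature
#' is discontinuous at the blend point \eqn{x = 0}; probe grids should avoid
#' an `h`-neighbourhood of the origin there.
#'
#' @param potential A [make_potential()] object.
#' @param grid Numeric vector of probe positions (non-empty, finite).
#' @param h Finite-difference step (default `1e-5`).
#' @param tol_force,tol_curvature Pass thresholds for the maximum scaled
#'   error (defaults `1e-6` and `1e-4`).
#' @return A list with `max_force_error`, `max_curvature_error`, the
#'   thresholds, and logical `pass`.
#' @export
check_consistency <- function(potential, grid, h = 1e-5,
                              tol_force = 1e-6, tol_curvature = 1e-4) {
  stopifnot(inherits(potential, "bd_potential"))
  if (length(grid) == 0L || !all(is.finite(grid)))
    stop("probe grid must be non-empty and finite", call. = FALSE)
  U <- potential$energy
  fd_force <- -(U(grid + h) - U(grid - h)) / (2 * h)
  fd_curv  <- (U(grid + h) - 2 * U(grid) + U(grid - h)) / h^2
  fa <- potential$force(grid)
  ca <- potential$curvature(grid)
  err_f <- max(abs(fd_force - fa) / pmax(1, abs(fa)))
  err_c <- max(abs(fd_curv - ca) / pmax(1, abs(ca)))
  list(max_force_error = err_f, max_curvature_error = err_c,
       tol_force = tol_force, tol_curvature = tol_curvature,
       pass = err_f < tol_force && err_c < tol_curvature)
}
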