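kl_estimate <- function(value, std_error, n_paths, construction, direction,
                        config = NULL) {
  structure(list(value = value, std_error = std_error,
                 n_paths = as.integer(n_paths), construction = construction,
                 direction = direction, config = config),
            class = "kl_estimate")
}

#' @export
print.kl_estimate <- function(x, ...) {
  cat(sprintf("<kl_estimate> D(%s) = %.6g +/- %.3g nats  [%s, n = %d]\n",
              paste(x$direction, collapse = " || "), x$value, x$std_error,
              x$construction, x$n_paths))
  invisible(x)
}

check_common_reservoir <- function(q1, q2) {
  if (!isTRUE(all.equal(q1$temperature, q2$temperature)))
    stop("both processes must share the reservoir temperature eps",
         call. = FALSE)
}

#' Change of measure under the common-noise construction
#'
#' Two processes attached to the same thermal reservoir receive the same
#' noise history, which links their paths through a bijective map. The
#' reweighting between a path `z` generated by `q2` and its common-noise
#' image under `q1` is the ratio of discrete path densities,
#' \eqn{L = \exp(I_{q1}(\tilde x) - I_{q2}(z))}. Both OM values equal
#' \eqn{\frac{1}{2}\sum_i \xi_i^2} for the shared noise, so `L = 1` exactly
#' in reals and the log ratio vanishes to roundoff for every path and every
#' positive time step.
#'
#' @param q1 Target [process_spec()].
#' @param q2 Generating [process_spec()]; defaults to the process carried by
#'   `z`.
#' @param z Paths generated by `q2`.
#' @return Numeric vector of per-path log change-of-measure values.
#' @export
change_of_measure_common_noise <- function(q1, q2 = NULL, z) {
  if (is.null(q2)) q2 <- attr(z, "process")
  if (is.null(q2)) stop("z carries no generating process; pass q2", call. = FALSE)
  check_common_reservoir(q1, q2)
  xt <- map_path(z, target = q1, source = q2)
  om_functional(q1, xt) - om_functional(q2, z)
}

#' KL divergence under the common-noise construction
#'
#' \eqn{D_{KL}(Q_2 \| Q_1) = -E_2[\ln(Q_2 / Q_1)]} over common-noise path
#' pairs. Because the change of measure is identically one, the estimate is
#' zero (to floating-point roundoff) for every process pair at every
#' \eqn{\Delta t > 0}.
#'
#' @inheritParams change_of_measure_common_noise
#' @param ensemble Paths generated by `q2`.
#' @return A `kl_estimate`.
#' @export
kl_common_noise <- function(q1, q2 = NULL, ensemble) {
  if (is.null(q2)) q2 <- attr(ensemble, "process")
  lr <- change_of_measure_common_noise(q1, q2, ensemble)
  n <- length(lr)
  se <- if (n > 1L) stats::sd(lr) / sqrt(n) else 0
  kl_estimate(mean(-lr), se, n, "common_noise",
              c(q2$potential$name, q1$potential$name))
}

#' KL divergence under the common-path construction
#'
#' Evaluates both processes' path densities on the *same* paths (generated
#' by `qa`) and averages the log ratio. With the convention
#' \eqn{\tilde D(Q_a \| Q_b) = E_a[J_b - J_a]} this is the standard KL
#' divergence of the generating measure from the reference, the kinetic
#' terms having cancelled exactly. `mode = "discrete"` uses the discrete
#' `J`; `mode = "continuous"` its Ito integration-by-parts limit
#' ([j_continuous()]): the two agree in the mean as \eqn{\Delta t \to 0}.
#'
#' @param qa Generating process.
#' @param qb Reference process (same grid and temperature).
#' @param ensemble Paths generated by `qa`.
#' @param mode `"discrete"` or `"continuous"`.
#' @return A `kl_estimate`.
#' @export
kl_common_path <- function(qa, qb, ensemble,
                           mode = c("discrete", "continuous")) {
  mode <- match.arg(mode)
  check_common_reservoir(qa, qb)
  if (ncol(ensemble) < 1L) stop("empty ensemble", call. = FALSE)
  jfun <- if (mode == "discrete") j_functional else j_continuous
  vals <- jfun(qb, ensemble) - jfun(qa, ensemble)
  n <- length(vals)
  se <- if (n > 1L) stats::sd(vals) / sqrt(n) else 0
  kl_estimate(mean(vals), se, n,
              paste0("common_path_", mode),
              c(qa$potential$name, qb$potential$name))
}

#' Closed-form common-path KL divergence for constant drift
#'
#' \eqn{\tilde D(Q_0 \| Q_c) = c^2 T / (4 \epsilon)}: the price, in nats,
#' of describing free Brownian paths with a constant-drift process.
#'
#' @param c Drift.
#' @param T Path duration, `> 0`.
#' @param eps Temperature, `> 0`.
#' @return Non-negative number, zero iff `c = 0`.
#' @export
kl_constant_drift_analytic <- function(c, T, eps) {
  stopifnot(T > 0, eps > 0)
  c^2 * T / (4 * eps)
}

#' Closed-form common-path KL divergences for the OU process
#'
#' With stiffness `A` and duration `T`:
#' forward \eqn{\tilde D(Q_0 \| Q_{OU}) = A^2 T^2 / 4};
#' reverse \eqn{\tilde D(Q_{OU} \| Q_0) =
#' \frac{1}{8}\left(e^{-2AT} - 1 + 2AT\right)}. Both follow from the
#' Gaussian moments \eqn{E_0[z_t^2] = 2\epsilon t} and
#' \eqn{E_{OU}[z_t^2] = (\epsilon/A)(1 - e^{-2At})}; neither depends on
#' \eqn{\epsilon}.
#'
#' @param A OU stiffness, `> 0`.
#' @param T Duration, `> 0`.
#' @param direction `"forward"` (free paths, OU reference) or `"reverse"`.
#' @return Non-negative number.
#' @export
kl_ou_analytic <- function(A, T, direction = c("forward", "reverse")) {
  stopifnot(A > 0, T > 0)
  direction <- match.arg(direction)
  if (direction == "forward") A^2 * T^2 / 4
  else (exp(-2 * A * T) - 1 + 2 * A * T) / 8
}

#' Closed-form bridge common-path KL expression
#'
#' For Brownian-bridge paths evaluated against the OU-bridge reference the
#' common-path construction gives
#' \eqn{\tilde D^{CT} = \frac{AT}{12}(AT - 6)}: negative whenever
#' `AT < 6`, a violation of Jensen's inequality showing the construction is
#' invalid on endpoint-constrained path spaces. Independent of
#' \eqn{\epsilon}.
#'
#' @inheritParams kl_ou_analytic
#' @return A number, negative iff `AT < 6`.
#' @export
kl_bridge_analytic <- function(A, T) {
  stopifnot(A > 0, T > 0)
  (A * T / 12) * (A * T - 6)
}

#' Bridge KL expression from the bridge-variance integral
#'
#' Computes \eqn{E_{BB}[J_{OU}]} by inserting the Brownian-bridge variance
#' \eqn{E[z_t^2] = 2\epsilon t (1 - t/T)} into
#' \eqn{\frac{1}{2\epsilon}\int_0^T (\frac{A^2}{2} z_t^2 - \epsilon A)\,dt}
#' and integrating by adaptive quadrature. Serves as an independent route
#' to [kl_bridge_analytic()] and as the objective for the zero-crossing
#' root-finder; \eqn{\epsilon} cancels.
#'
#' @inheritParams kl_ou_analytic
#' @param eps Temperature (cancels; kept to mirror the Monte Carlo route).
#' @return A number.
#' @export
kl_bridge_quadrature <- function(A, T, eps = 0.5) {
  stopifnot(A > 0, T > 0, eps > 0)
  integrand <- function(t) {
    var_bb <- 2 * eps * t * (1 - t / T)
    (A^2 / 2 * var_bb - eps * A) / (2 * eps)
  }
  stats::integrate(integrand, 0, T, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

#' Monte Carlo bridge common-path KL estimate
#'
#' Samples Brownian bridges pinned at the origin and averages the J
#' functional of the unconditioned OU force \eqn{f = -Ax} over them (the
#' bridge's own conditioning drift never enters `J`; the zero-force
#' reference contributes nothing). With endpoints pinned at zero the
#' boundary term vanishes, leaving exactly the variance integral of
#' [kl_bridge_quadrature()]. The estimate goes negative for `AT < 6`.
#'
#' @param A OU stiffness.
#' @param T Duration.
#' @param eps Temperature (the estimate is invariant to it).
#' @param n_paths Number of bridges.
#' @param dt Time step.
#' @param seed Optional seed.
#' @param mode Passed to [kl_common_path()]-style evaluation: `"continuous"`
#'   (default, the Ito-limit J) or `"discrete"`.
#' @return A `kl_estimate`.
#' @export
kl_bridge_mc <- function(A, T, eps, n_paths = 10000L, dt = 1e-3,
                         seed = NULL, mode = c("continuous", "discrete")) {
  mode <- match.arg(mode)
  stopifnot(A > 0, T > 0, eps > 0)
  grid <- time_grid(dt, round(T / dt))
  bb <- sample_brownian_bridge(grid, eps, 0, 0, n_paths, seed)
  q_ou <- process_spec(make_potential("harmonic", list(A = A)), eps)
  jfun <- if (mode == "continuous") j_continuous else j_functional
  vals <- jfun(q_ou, bb)  # J of the zero-force reference is identically 0
  kl_estimate(mean(vals), stats::sd(vals) / sqrt(n_paths), n_paths,
              paste0("common_path_", mode), c("brownian_bridge", "ou_bridge"),
              config = list(A = A, T = T, eps = eps, dt = dt, seed = seed))
}

#' Scan the bridge KL expression for the Jensen-inequality violation
#'
#' Tabulates the analytic bridge expression \eqn{(AT/12)(AT-6)} against its
#' Monte Carlo estimate over a set of stiffnesses, flags negative analytic
#' values (the Jensen violation), and locates the positive zero crossing in
#' `AT` by root-finding on the quadrature route.
#'
#' @param T Duration.
#' @param eps Temperature.
#' @param A_values Positive stiffnesses to scan.
#' @param n_paths Bridges per Monte Carlo point.
#' @param dt Time step for the Monte Carlo column.
#' @param seed Optional seed (per-row seeds derived by offset).
#' @return A list with `table` (data.frame sorted by `AT` with columns
#'   `A`, `AT`, `analytic`, `mc`, `mc_se`, `negative`) and `zero_crossing`
#'   (the root of the quadrature expression, in `AT`).
#' @export
jensen_scan <- function(T, eps, A_values, n_paths = 2000L, dt = 1e-3,
                        seed = NULL) {
  stopifnot(all(A_values > 0))
  A_values <- sort(A_values)
  rows <- lapply(seq_along(A_values), function(k) {
    A <- A_values[k]
    sk <- if (is.null(seed)) NULL else as.integer(seed) + k
    est <- kl_bridge_mc(A, T, eps, n_paths, dt, seed = sk)
    data.frame(A = A, AT = A * T, analytic = kl_bridge_analytic(A, T),
               mc = est$value, mc_se = est$std_error)
  })
  tab <- do.call(rbind, rows)
  tab$negative <- tab$analytic < 0
  g <- function(A) kl_bridge_quadrature(A, T, eps)
  root_A <- stats::uniroot(g, lower = 1e-3 / T, upper = 1e3 / T,
                           tol = 1e-12)$root
  list(table = tab, zero_crossing = root_A * T)
}
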