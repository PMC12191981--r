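#' Define two basins by a dividing point
#'
#' Basin A is the set of positions at or below `dividing_point`, basin B the
#' set above it (samples landing exactly on the divider count as A, a fixed
#' tie-break that matters only on a set of measure zero).
#'
#' @param dividing_point Finite position of the dividing surface.
#' @return Object of class `bd_basins`.
#' @export
basin_definition <- function(dividing_point) {
  stopifnot(is.finite(dividing_point))
  structure(list(dividing_point = dividing_point), class = "bd_basins")
}

#' Locate the barrier top of a double-well potential
#'
#' Numerically finds the local maximum of the energy between the two
#' minima; the barrier top is the standard dividing surface between basins.
#'
#' @param potential A [make_potential()] object with two wells.
#' @param lower,upper Bracketing interval containing the barrier.
#' @return A [basin_definition()] at the located maximum.
#' @export
find_dividing_point <- function(potential, lower = -1, upper = 1) {
  opt <- stats::optimize(potential$energy, c(lower, upper), maximum = TRUE)
  basin_definition(opt$maximum)
}

#' Basin occupancy times of a trajectory
#'
#' Assigns each of the \eqn{N_t + 1} samples (endpoints included, full
#' `dt` weight each) to a basin and accumulates residence times. Counting
#' is order-free, so the result is invariant under time reversal.
#'
#' @param paths A [as_paths()] trajectory (columns pooled if several).
#' @param basins A [basin_definition()].
#' @return List of class `bd_occupancy`: `time_A`, `time_B` (their sum is
#'   the total sampled time `(n_steps + 1) * dt * n_paths`), and
#'   `n_crossings`, the number of divider crossings along each column,
#'   summed.
#' @export
assign_basins <- function(paths, basins) {
  stopifnot(inherits(basins, "bd_basins"))
  grid <- path_grid(paths)
  x <- unclass(paths)
  in_a <- x <= basins$dividing_point
  n_a <- sum(in_a)
  crossings <- sum(apply(in_a, 2L, function(col) sum(diff(col) != 0L)))
  structure(list(time_A = n_a * grid$dt,
                 time_B = (length(x) - n_a) * grid$dt,
                 n_crossings = crossings,
                 dividing_point = basins$dividing_point),
            class = "bd_occupancy")
}

#' Free-energy difference from residence times
#'
#' For an ergodic trajectory the equivalence of microcanonical and
#' canonical ensembles gives
#' \eqn{F_B - F_A = -\epsilon \ln(t_B / t_A)}.
#'
#' @param occ A `bd_occupancy` from [assign_basins()].
#' @param eps Temperature.
#' @return `F_B - F_A` in energy units of \eqn{\epsilon}.
#' @export
free_energy_from_residence <- function(occ, eps) {
  stopifnot(inherits(occ, "bd_occupancy"), eps > 0)
  if (occ$time_A <= 0 || occ$time_B <= 0)
    stop("zero occupancy in one basin: trajectory too short for a free-energy estimate",
         call. = FALSE)
  -eps * log(occ$time_B / occ$time_A)
}

#' Boltzmann quadrature reference for the basin free-energy difference
#'
#' Independent equilibrium reference:
#' \eqn{F_B - F_A = -\epsilon \ln\left(
#' \int_B e^{-U/\epsilon} dx / \int_A e^{-U/\epsilon} dx \right)}
#' by adaptive quadrature over the two sides of the dividing point.
#'
#' @param potential A [make_potential()] object.
#' @param eps Temperature.
#' @param basins A [basin_definition()].
#' @param range Length-2 integration range covering both basins; the
#'   Boltzmann weight must have decayed at its ends.
#' @return Reference `F_B - F_A`.
#' @export
boltzmann_reference <- function(potential, eps, basins, range = c(-10, 10)) {
  stopifnot(inherits(basins, "bd_basins"), eps > 0, length(range) == 2L)
  d <- basins$dividing_point
  if (d <= range[1] || d >= range[2])
    stop("integration range must bracket the dividing point", call. = FALSE)
  wt <- function(x) exp(-potential$energy(x) / eps)
  za <- stats::integrate(wt, range[1], d, rel.tol = 1e-10)
  zb <- stats::integrate(wt, d, range[2], rel.tol = 1e-10)
  -eps * log(zb$value / za$value)
}

#' Residence-time free energy with a block-bootstrap error bar
#'
#' Simulates `n_chains` independent Euler-Maruyama trajectories on
#' `potential` (starts alternating between the two well positions to
#' symmetrise initial-condition bias), pools their occupancy statistics,
#' and attaches a block-bootstrap standard error: each chain is cut into
#' blocks much longer than the correlation time, per-block occupancy pairs
#' are resampled with replacement, and the free-energy estimator is
#' recomputed per replicate.
#'
#' @param potential A double-well [make_potential()] object.
#' @param eps Temperature; crossings are frequent when `eps` is comparable
#'   to the barrier height.
#' @param dt Time step.
#' @param total_time Total simulated time pooled over chains.
#' @param basins Optional [basin_definition()]; default locates the barrier
#'   top numerically.
#' @param starts Length-2 starting positions (defaults to the two minima of
#'   the built-in asymmetric double well parameterisation).
#' @param n_chains Number of independent chains.
#' @param n_blocks Bootstrap blocks per chain.
#' @param n_boot Bootstrap replicates.
#' @param seed Optional seed.
#' @return List: `delta_F`, `std_error`, `occupancy`, `reference` (the
#'   Boltzmann quadrature value), `n_crossings`.
#' @export
residence_free_energy <- function(potential, eps, dt, total_time,
                                  basins = NULL, starts = NULL,
                                  n_chains = 16L, n_blocks = 3L,
                                  n_boot = 400L, seed = NULL) {
  stopifnot(inherits(potential, "bd_potential"), eps > 0)
  if (is.null(basins)) {
    a <- potential$params$a %||% 1
    basins <- find_dividing_point(potential, -a, a)
  }
  if (is.null(starts)) {
    a <- potential$params$a %||% 1
    w <- potential$params$w %||% 1
    starts <- c(-a, a * w)
  }
  steps_per_chain <- ceiling(total_time / dt / n_chains)
  grid <- time_grid(dt, steps_per_chain)
  proc <- process_spec(potential, eps)
  noise <- sample_noise(grid, n_chains, seed)
  x0 <- rep_len(starts, n_chains)
  paths <- propagate(proc, grid, noise, x0 = x0)
  occ <- assign_basins(paths, basins)
  dF <- free_energy_from_residence(occ, eps)

  # per-block occupancy (time_A, time_B), blocks within chains
  x <- unclass(paths)
  in_a <- x <= basins$dividing_point
  rows_per_block <- max(1L, nrow(x) %/% n_blocks)
  blk <- pmin((seq_len(nrow(x)) - 1L) %/% rows_per_block + 1L, n_blocks)
  block_a <- do.call(rbind, lapply(seq_len(n_chains), function(j)
    cbind(a = tapply(in_a[, j], blk, sum),
          n = tapply(rep(1L, nrow(x)), blk, sum))))
  if (!is.null(seed)) set.seed(as.integer(seed) + 1L)
  nb <- nrow(block_a)
  boot <- replicate(n_boot, {
    idx <- sample.int(nb, nb, replace = TRUE)
    ta <- sum(block_a[idx, "a"])
    tn <- sum(block_a[idx, "n"])
    if (ta == 0 || ta == tn) NA_real_ else -eps * log((tn - ta) / ta)
  })
  se <- stats::sd(boot, na.rm = TRUE)
  ref <- boltzmann_reference(potential, eps, basins)
  list(delta_F = dF, std_error = se, occupancy = occ,
       reference = ref, n_crossings = occ$n_crossings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chord_detrend <- function(p) {
  x <- unclass(p)
  nr <- nrow(x)
  frac <- seq(0, 1, length.out = nr)
  x - rep(x[1L, ], each = nr) - outer(frac, x[nr, ] - x[1L, ])
}

#' Per-frequency comparison of two path ensembles
#'
#' Computes per-path chord-detrended DFT power for both ensembles and a
#' Welch z-statistic per frequency bin for the difference of their means.
#' Under the hypothesis that a bin's power distribution is
#' drift-independent the z-values are approximately standard normal.
#'
#' Detrending subtracts each path's endpoint chord (the line from
#' \eqn{x_0} to \eqn{x_T}) rather than just its mean: the chord carries the
#' smooth secular displacement whose periodic-extension discontinuity would
#' otherwise leak \eqn{O(1)} drift-dependent power into every frequency
#' bin, masking the drift independence of the genuine high-frequency
#' fluctuations. A constant drift lives entirely in the chord, so for that
#' case the detrended spectra of drifted and free paths agree in law at
#' *all* frequencies; a state-dependent force (e.g. Ornstein-Uhlenbeck)
#' reshapes the low-frequency fluctuation spectrum while leaving the bins
#' above a finite cutoff unchanged.
#'
#' @param paths_a,paths_b Two [as_paths()] ensembles on a common grid.
#' @return Data frame with `freq_index`, `power_a`, `power_b`, `z`.
#' @export
spectral_compare <- function(paths_a, paths_b) {
  per_path_power <- function(p) Mod(stats::mvfft(chord_detrend(p)))^2
  pa <- per_path_power(paths_a)
  pb <- per_path_power(paths_b)
  ma <- rowMeans(pa); mb <- rowMeans(pb)
  va <- apply(pa, 1L, stats::var) / ncol(pa)
  vb <- apply(pb, 1L, stats::var) / ncol(pb)
  z <- (ma - mb) / sqrt(pmax(va + vb, .Machine$double.xmin))
  data.frame(freq_index = seq_len(nrow(pa)) - 1L,
             power_a = ma, power_b = mb, z = z)
}

#' Ensemble-averaged spectral profile of paths
#'
#' Discrete Fourier magnitude-squared of each path after removing its
#' endpoint chord (see [spectral_compare()] for why), averaged over the
#' ensemble. Above a finite frequency cutoff the profile of a smooth-drift
#' process is indistinguishable from the zero-drift one: the drift, being
#' smooth, reshapes only O(1) low-frequency modes while the reservoir
#' noise populates all of them.
#'
#' @param paths A [as_paths()] ensemble on a common grid.
#' @return Data frame with `freq_index` (bin 0 vanishes only up to the
#'   detrending) and `power`, the mean squared DFT magnitude per frequency.
#' @export
spectral_profile <- function(paths) {
  ft <- stats::mvfft(chord_detrend(paths))
  power <- rowMeans(Mod(ft)^2)
  data.frame(freq_index = seq_len(nrow(paths)) - 1L, power = power)
}
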