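test_that("time grids derive the duration and validate inputs", {
  g <- time_grid(1e-3, 1000)
  expect_identical(g$duration, 1e-3 * 1000)
  expect_error(time_grid(0, 10), "positive")
  expect_error(time_grid(0.1, 0), "positive")
  expect_error(process_spec(make_potential("zero"), -1), "positive")
})

test_that("noise sampling is reproducible and distributionally sound", {
  g <- time_grid(0.01, 500)
  a <- sample_noise(g, 20, seed = 7)
  b <- sample_noise(g, 20, seed = 7)
  expect_identical(unclass(a), unclass(b))
  expect_identical(dim(a), c(500L, 20L))
  expect_error(sample_noise(g, 0), "positive")

  # pooled variance of 10^4 histories of length 500: chi-square sampling
  # theory gives SE(var) = sqrt(2 / (n - 1)) for iid standard normals
  big <- sample_noise(time_grid(0.01, 500), 10000, seed = 11)
  n <- length(big)
  expect_lt(abs(mean(big)), 4 / sqrt(n))
  expect_lt(abs(var(as.vector(big)) - 1), 3 * sqrt(2 / (n - 1)))
})

test_that("Euler-Maruyama propagation follows the explicit update", {
  g <- time_grid(0.1, 10)
  still <- propagate(proc_zero(), g, matrix(0, 10, 1), x0 = 0.3)
  expect_equal(as.vector(still), rep(0.3, 11))

  # deterministic Euler under constant drift: x_i = c * i * dt
  det <- propagate(proc_linear(1), g, matrix(0, 10, 1), x0 = 0)
  expect_equal(as.vector(det), seq(0, 1, by = 0.1))
  expect_equal(unclass(det)[11, 1], 1.0)

  # unstable step fails loudly with the step index
  stiff <- process_spec(make_potential("harmonic", list(A = 1e6)), 0.5)
  g_long <- time_grid(0.1, 100)
  expect_error(propagate(stiff, g_long, matrix(1, 100, 1), x0 = 1),
               "non-finite position at step")
})

test_that("propagate and recover_noise are mutually inverse bijections", {
  g <- time_grid(0.02, 64)
  set.seed(21)
  for (proc in process_pool()) {
    xi <- sample_noise(g, 5)
    x0 <- rnorm(1)
    p <- propagate(proc, g, xi, x0)
    expect_lt(max(abs(recover_noise(proc, p) - unclass(xi))), 1e-12)
    # and the other composition order, starting from a random smooth path
    q <- as_paths(matrix(cumsum(rnorm(65, sd = 0.1)), 65, 1), g)
    xi2 <- recover_noise(proc, q)
    p2 <- propagate(proc, g, xi2, x0 = unclass(q)[1, 1])
    expect_lt(max(abs(unclass(p2) - unclass(q))), 1e-12)
  }
})

test_that("recover_noise inverts hand-built paths", {
  g <- time_grid(0.01, 100)
  p <- straight_path(g, 0, 1)  # x_i = i * dt
  xi <- recover_noise(proc_zero(eps = 0.5), p)
  expect_equal(as.vector(xi), rep(0.1, 100))  # sqrt(dt/2eps) * (1 - 0)
  flat <- as_paths(rep(0.4, 101), g)
  expect_equal(as.vector(recover_noise(proc_zero(), flat)), rep(0, 100))
})

test_that("the common-noise map is the drift shift for constant drift", {
  g <- time_grid(1e-3, 500)
  z <- propagate(proc_zero(), g, sample_noise(g, 50, seed = 31))
  cc <- 1.3
  x <- map_path(z, proc_linear(cc), proc_zero())
  tt <- seq(0, g$duration, length.out = g$n_steps + 1)
  expect_lt(max(abs(unclass(x) - (unclass(z) + cc * tt))), 1e-10)
})

test_that("the common-noise map is an invertible identity-respecting bijection", {
  g <- time_grid(0.01, 80)
  qa <- proc_harmonic(2)
  qb <- proc_linear(-0.5)
  z <- propagate(qb, g, sample_noise(g, 10, seed = 33))
  expect_lt(max(abs(unclass(map_path(z, qb, qb)) - unclass(z))), 1e-12)
  back <- map_path(map_path(z, qa, qb), qb, qa)
  expect_lt(max(abs(unclass(back) - unclass(z))), 1e-12)
  expect_error(map_path(z, process_spec(make_potential("zero"), 0.9), qb),
               "temperature")
})

test_that("exact OU step matches its closed form and stationary law", {
  expect_equal(ou_exact_step(1, A = 1, eps = 0.5, dt = log(2), xi = 0), 0.5)
  # small-step limit reduces to Euler-Maruyama at leading order
  dt <- 1e-6
  em <- 1 + sqrt(2 * 0.5 * dt) * 1.7
  expect_equal(ou_exact_step(1, 1, 0.5, dt, 1.7), em, tolerance = 1e-5)
  # stationary variance eps / A over many exact steps
  set.seed(41)
  x <- 0
  n <- 20000
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- ou_exact_step(x, A = 2, eps = 0.5, dt = 0.5, xi = rnorm(1))
    out[i] <- x
  }
  expect_lt(abs(var(out) - 0.25), 3 * 0.25 * sqrt(2 / n) * 2)
})

test_that("Euler-Maruyama converges to the exact OU law as dt shrinks", {
  # terminal second moment error at T = 1 halves (is O(dt)) as dt halves
  A <- 2; eps <- 0.5; n <- 40000
  exact <- (eps / A) * (1 - exp(-2 * A))
  err <- sapply(c(0.05, 0.025, 0.0125), function(dt) {
    g <- time_grid(dt, round(1 / dt))
    p <- propagate(proc_harmonic(A, eps), g, sample_noise(g, n, seed = 43))
    abs(mean(unclass(p)[g$n_steps + 1, ]^2) - exact)
  })
  # Euler at this step has bias ~ A dt * exact >> MC error (~3e-4)
  expect_gt(err[1], err[3])
  expect_lt(err[3], err[1] / 1.8 + 6e-4)
})

test_that("Brownian bridges pin endpoints and match the variance law", {
  g <- time_grid(1e-3, 1000)
  eps <- 0.5
  b <- sample_brownian_bridge(g, eps, x0 = 0.2, xT = -0.7,
                              n_paths = 200, seed = 51)
  expect_identical(unclass(b)[1, ], rep(0.2, 200))
  expect_identical(unclass(b)[1001, ], rep(-0.7, 200))

  b0 <- sample_brownian_bridge(g, eps, 0, 0, n_paths = 4000, seed = 52)
  mid <- unclass(b0)[501, ]   # t = 0.5
  v <- 2 * eps * 0.5 * (1 - 0.5)   # 0.25
  expect_lt(abs(var(mid) - v), 3 * v * sqrt(2 / length(mid)))
  expect_equal(var(unclass(b0)[1, ]), 0)
})

test_that("free Brownian terminal variance matches 2 eps t", {
  g <- time_grid(1e-3, 1000)
  eps <- 0.5
  p <- propagate(proc_zero(eps), g, sample_noise(g, 5000, seed = 53))
  xT <- unclass(p)[1001, ]
  v <- 2 * eps * g$duration
  expect_lt(abs(var(xT) - v), 3 * v * sqrt(2 / length(xT)))
})

test_that("OU bridges match the joint-Gaussian conditioning oracle", {
  A <- 2; eps <- 0.5
  g <- time_grid(5e-3, 200)
  ob <- sample_ou_bridge(g, eps, A, 0, 0, n_paths = 6000, seed = 61)
  expect_identical(unclass(ob)[1, ], rep(0, 6000))
  expect_identical(unclass(ob)[201, ], rep(0, 6000))

  # independent oracle: condition the OU joint Gaussian law on x_T.
  # Cov(x_s, x_t) = (eps/A) (e^{-A|t-s|} - e^{-A(t+s)}) for x_0 = 0.
  Tt <- g$duration
  cov_ou <- function(s, t) (eps / A) * (exp(-A * abs(t - s)) - exp(-A * (t + s)))
  for (tq in c(0.25, 0.5, 0.75) * Tt) {
    idx <- round(tq / g$dt) + 1
    v_cond <- cov_ou(tq, tq) - cov_ou(tq, Tt)^2 / cov_ou(Tt, Tt)
    samp <- unclass(ob)[idx, ]
    expect_lt(abs(var(samp) - v_cond), 3 * v_cond * sqrt(2 / length(samp)))
    expect_lt(abs(mean(samp)), 3 * sqrt(v_cond / length(samp)))
  }

  # continuity in A: a nearly-flat OU bridge reproduces the Brownian law
  ob2 <- sample_ou_bridge(g, eps, 1e-8, 0, 0, n_paths = 6000, seed = 62)
  mid <- unclass(ob2)[101, ]
  v_bb <- 2 * eps * (Tt / 2) * (1 - 0.5)
  expect_lt(abs(var(mid) - v_bb), 3 * v_bb * sqrt(2 / length(mid)))
})
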