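test_that("OM functional is half the summed squared noise", {
  g <- time_grid(0.01, 50)
  proc <- proc_harmonic(1.5)
  # noiseless propagation has zero OM action under its own process
  p0 <- propagate(proc, g, matrix(0, 50, 1), x0 = 0.8)
  expect_equal(om_functional(proc, p0), 0)

  # a path whose recovered noise is {1, -1, 1, -1, ...} has I = Nt/2
  xi <- matrix(rep(c(1, -1), 25), 50, 1)
  p1 <- propagate(proc, g, xi, x0 = 0)
  expect_equal(om_functional(proc, p1), 25, tolerance = 1e-10)

  # and in general I = sum(xi^2) / 2 for arbitrary noise, any process
  set.seed(71)
  for (proc in process_pool()) {
    xi <- sample_noise(g, 3)
    p <- propagate(proc, g, xi, x0 = 0.2)
    expect_equal(om_functional(proc, p), colSums(unclass(xi)^2) / 2,
                 tolerance = 1e-10)
  }
})

test_that("OM values over self-generated paths have mean and variance Nt/2", {
  nt <- 200; n <- 6000
  g <- time_grid(1e-3, nt)
  proc <- proc_harmonic(1)
  p <- propagate(proc, g, sample_noise(g, n, seed = 72))
  I <- om_functional(proc, p)
  expect_lt(abs(mean(I) - nt / 2), 3 * sd(I) / sqrt(n))
  expect_lt(abs(var(I) - nt / 2), 3 * var(I) * sqrt(2 / (n - 1)))
})

test_that("J vanishes for zero force and telescopes for constant drift", {
  g <- time_grid(0.02, 50)
  set.seed(73)
  p <- propagate(proc_harmonic(2), g, sample_noise(g, 4))
  expect_equal(j_functional(proc_zero(), p), rep(0, 4))
  expect_equal(j_continuous(proc_zero(), p), rep(0, 4))

  # linear(c): J = (1/2eps)(c^2 T / 2 - c (xT - x0)) exactly, via telescoping
  g1 <- time_grid(1 / 40, 40)
  sp <- straight_path(g1, 0, 1)   # x0 = 0, xT = 1, T = 1
  expect_equal(j_functional(proc_linear(1, 0.5), sp), -0.5)
  # continuous form agrees exactly when U'' = 0 (pure quadrature identity)
  expect_equal(j_continuous(proc_linear(1, 0.5), sp), -0.5)
  # and for any stochastic path with those endpoint statistics
  for (k in 1:3) {
    z <- propagate(proc_zero(), g1, sample_noise(g1, 1))
    lhs <- j_functional(proc_linear(1, 0.5), z)
    x0 <- unclass(z)[1, 1]; xT <- unclass(z)[41, 1]
    expect_equal(lhs, (0.5 * 1 - (xT - x0)) / (2 * 0.5), tolerance = 1e-10)
  }
})

test_that("I_a - I_b = J_a - J_b exactly on any common path", {
  g <- time_grid(0.005, 120)
  set.seed(74)
  pool <- process_pool()
  z <- propagate(proc_zero(), g, sample_noise(g, 6), x0 = 0.1)
  for (a in pool) for (b in pool) {
    di <- om_functional(a, z) - om_functional(b, z)
    dj <- j_functional(a, z) - j_functional(b, z)
    expect_lt(max(abs(di - dj) / pmax(abs(di), 1e-8)), 1e-10)
  }
})

test_that("continuous-time J converges to discrete J in the ensemble mean", {
  proc <- proc_harmonic(2)
  gap <- sapply(c(0.02, 0.005), function(dt) {
    g <- time_grid(dt, round(1 / dt))
    p <- propagate(proc, g, sample_noise(g, 4000, seed = 75))
    abs(mean(j_continuous(proc, p)) - mean(j_functional(proc, p)))
  })
  expect_lt(gap[2], gap[1])
  expect_lt(gap[2], 0.02)
})

test_that("path potential G follows its closed form", {
  expect_equal(path_potential_G(make_potential("zero"), 1, 2.5), 0)
  expect_equal(path_potential_G(make_potential("harmonic", list(A = 1)),
                                0.5, 0), -0.5)
  # linear(c): G is c^2/2 everywhere
  x <- c(-3, 0, 1, 7)
  expect_equal(path_potential_G(make_potential("linear", list(c = 2)), 0.7, x),
               rep(2, 4))
})

test_that("Ito-Girsanov action matches a brute-force two-term evaluation", {
  g <- time_grid(0.5, 2)
  proc <- proc_harmonic(1, eps = 0.5)
  sp <- straight_path(g, 0, 1)  # positions 0, 0.5, 1 over T = 1
  # independent hand evaluation of the Nt = 2 sum
  x <- c(0, 0.5, 1); dt <- 0.5; eps <- 0.5
  manual <- 0
  for (i in 1:2) {
    v <- (x[i + 1] - x[i]) / dt
    gx <- 0.5 * (-x[i])^2 - eps * 1
    manual <- manual + dt / (2 * eps) * (0.5 * v^2 + gx)
  }
  expect_equal(ig_action(proc, sp), manual)

  # zero force, constant path: action is exactly zero
  flat <- as_paths(rep(0, 3), g)
  expect_equal(ig_action(proc_zero(), flat), 0)

  # decomposition identity: kinetic term + G term, by definition
  set.seed(76)
  p <- propagate(proc, time_grid(0.01, 40), sample_noise(time_grid(0.01, 40), 3))
  dx <- diff(unclass(p))
  kin <- 0.01 / (2 * eps) * colSums(0.5 * (dx / 0.01)^2)
  gterm <- 0.01 / (2 * eps) *
    colSums(path_potential_G(proc$potential, eps, unclass(p)[1:40, ]))
  expect_equal(ig_action(proc, p), kin + gterm)
})

test_that("quadratic variation sums squared increments", {
  g <- time_grid(0.01, 100)
  expect_equal(quadratic_variation(straight_path(g, 0, 1)), 0.01)
  expect_equal(quadratic_variation(as_paths(rep(2, 101), g)), 0)
})

test_that("mean quadratic variation is drift-independent at small dt", {
  g <- time_grid(2e-4, 2500)
  n <- 2000
  q0 <- proc_zero(); qc <- proc_linear(2)
  qv0 <- quadratic_variation(propagate(q0, g, sample_noise(g, n, seed = 77)))
  qvc <- quadratic_variation(propagate(qc, g, sample_noise(g, n, seed = 78)))
  se <- sqrt(var(qv0) / n + var(qvc) / n)
  # drift adds c^2 dt T = 4e-4, below the MC resolution here
  expect_lt(abs(mean(qv0) - mean(qvc)), 3 * se + 4e-4)
})
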