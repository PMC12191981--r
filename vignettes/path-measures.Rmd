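---
title: "Path measures for discrete-time Brownian dynamics: model, conventions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path measures for discrete-time Brownian dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pathmeasure)
```

## The model

A particle at position $x$ moves in an external potential $U(x)$ at
reservoir temperature $\epsilon$ (energy units) under overdamped Langevin
dynamics,
$$dx_t = f(x_t)\,dt + \sqrt{2\epsilon}\,dW_t, \qquad f = -U'.$$
The package treats the *discrete-time* Euler–Maruyama realisation,
$$x_i = x_{i-1} + f(x_{i-1})\,\Delta t + \sqrt{2\epsilon\,\Delta t}\,\xi_i,$$
as the physical model rather than as an approximation: the noise history
$\{\xi_i\}$, $N_t$ iid standard normals, is a property of the thermal
reservoir, independent of the system it drives. Potentials are assumed
smooth and bounded below (Kato class), which all built-in families satisfy.

Everything is one-dimensional. The contracts of `bd_potential`
(energy/force/curvature triple), `bd_process` (potential + temperature) and
`bd_paths` (positions at $t = i\,\Delta t$, $i = 0..N_t$, one column per
path) are written so that a $d$-dimensional extension would generalise the
three callables without touching the callers.

## Two constructions for the change of measure

Given two processes $Q_1, Q_2$ sharing $T$, $\Delta t$ and $\epsilon$:

**Common noise.** Feeding the same noise history to both drifts defines a
bijective map $B$ between their path spaces (`map_path()`, built from
`recover_noise()` $\circ$ `propagate()`). The discrete path density is
determined by the noise alone, so the likelihood ratio between a path and
its image is exactly one and the KL divergence vanishes for *every*
$\Delta t > 0$. The package asserts this as an identity at $10^{-10}$
absolute, not as a Monte Carlo estimate.

**Common path.** Evaluating both densities on the same paths cancels the
kinetic (quadratic-variation) term of the Onsager–Machlup functional and
leaves the drift part
$$J = \frac{\Delta t}{2\epsilon}\sum_i \Big(\tfrac12 f^2(z_{i-1})
  - \frac{z_i - z_{i-1}}{\Delta t} f(z_{i-1})\Big),$$
whose Itô integration-by-parts limit is
$$J^{CT} = \frac{U(z_T)-U(z_0)}{2\epsilon}
 + \frac{1}{2\epsilon}\int_0^T\!\Big(\tfrac12 f^2 - \epsilon U''\Big)dt.$$

*Orientation convention.* The estimator is
$\tilde D(Q_a\Vert Q_b) = E_a[J_b - J_a]$: the expectation, under the
generating measure, of the log of its own density over the reference's.
This is the standard KL orientation and is the unique sign choice
consistent with all three closed forms the package tests against
(constant drift $c^2T/4\epsilon$; OU forward $A^2T^2/4$ and reverse
$(e^{-2AT}-1+2AT)/8$; bridge $(AT/12)(AT-6)$), each of which we re-derived
independently from the Gaussian moments $E_0[z_t^2] = 2\epsilon t$ and
$E_{OU}[z_t^2] = (\epsilon/A)(1-e^{-2At})$ before writing the estimators.
The OU-reverse test doubles as a dual-route check: `kl_ou_analytic()`
against direct quadrature of those moments.

## Numerical conventions

- **Left-point (Itô) sums everywhere.** The drift is evaluated at
  $x_{i-1}$ in propagation, in $J$, and in every time integral
  (`j_continuous`, `ig_action`). A trapezoid rule would implicitly add a
  Stratonovich correction and bias the comparisons the package exists to
  make.
- **Exact identities before statistics.** `propagate`/`recover_noise` are
  exact mutual inverses ($10^{-12}$), $I_a - I_b = J_a - J_b$ holds at
  $10^{-10}$ relative, and the common-noise log ratio is zero at
  $10^{-10}$; Monte Carlo comparisons are then judged at 3 standard errors
  of the mean (the estimands are means of light-tailed functionals).
- **Reproducibility.** One master integer seed initialises R's
  Mersenne-Twister; noise matrices are filled column-major so each path
  occupies a fixed contiguous block of the stream, making ensembles
  reproducible from `(seed, grid, n_paths)` and leaving earlier paths
  unchanged when `n_paths` grows. Seeds are recorded in path provenance
  and in serialised TSV headers.
- **Failure mode.** A non-finite position aborts propagation with the step
  index — stiff potentials with too large a $\Delta t$ must fail loudly,
  not produce quiet overflow.
- **Validation scales.** Monte Carlo validation defaults to
  $\Delta t = 10^{-3}$, $T = 1$ with $10^4$–$2\times10^4$ paths, which
  keeps the $O(\Delta t)$ discretisation bias of the discrete-$J$
  estimators below the Monte Carlo noise; the quadratic-variation check
  uses $\Delta t = 10^{-4}$ where the drift contribution
  $c^2\,\Delta t\,T$ is far below resolution.

## Bridge sampling

Both bridge laws are Gaussian, so both samplers are exact at any
$\Delta t$ — no Euler simulation plus rejection:

- Brownian bridges: a free Gaussian random walk plus the linear endpoint
  correction, which for iid Gaussian increments *is* the conditional law;
  marginal variance $2\epsilon t(1-t/T)$.
- OU bridges: sequential Gaussian conditioning using the exact OU
  transition kernel combined with the closed-form likelihood of the
  terminal pin (the Doob $h$-transform of a linear process). Tested
  against conditional variances computed independently from the joint OU
  covariance $\mathrm{Cov}(x_s,x_t) =
  (\epsilon/A)(e^{-A|t-s|} - e^{-A(t+s)})$.

Inside the bridge KL integrand, `J` uses the *unconditioned* forces (zero
for the Brownian bridge, $-Ax$ for the OU bridge); the conditioning drift
never enters. With both endpoints pinned at the origin the boundary term
of $J^{CT}$ vanishes, and the estimate reduces to the variance integral —
which is why $\epsilon$ cancels, a property the tests assert. The
zero-crossing of the bridge expression is located by root-finding on the
quadrature route (`kl_bridge_quadrature`), not on the factored closed
form, so the reported $AT = 6$ is a computation rather than an echo.

## The double well and free-energy recovery

The field's double-well examples contrast a narrow and a broad degenerate
well; no standard functional form exists, so the package uses a minimal
one: $U = h\,(1-(s/a)^2)^2$ with $s = x$ for $x \le 0$ and $s = x/w$ for
$x > 0$. Minima sit at $-a$ and $+aw$ at equal depth, the barrier height
is $h$ at $x = 0$, and substituting $x \to wx$ on the right branch shows
the partition-function ratio is exactly $w$, giving the closed-form
reference $F_B - F_A = -\epsilon\ln w$ against which both the quadrature
(`boltzmann_reference`) and the residence-time estimator are tested. The
blend is continuously differentiable but its curvature jumps at $x = 0$
when $w \ne 1$; finite-difference consistency probes therefore avoid an
$h$-neighbourhood of the origin, and the curvature at the blend point
itself is reported from the left branch.

Residence-time estimation (`residence_free_energy`) uses, as its study
conditions: $h = 1$, $a = 1$, $w = 2$, $\epsilon = 0.5$ (comparable to the
barrier, so crossings are frequent — a Kramers estimate gives a crossing
every $\sim$10 time units), $\Delta t = 2\times10^{-3}$, and 3000 time
units split over 16 chains started alternately in the two minima to
symmetrise initial-condition bias. Occupancy counts all $N_t+1$ samples
with full $\Delta t$ weight (endpoint half-weighting would change the
estimate by $O(\Delta t / T)$, negligible for long runs), ties at the
divider go to basin A, and the divider defaults to the numerically located
barrier top. The error bar is a block bootstrap with blocks of
$\sim$60 time units — well beyond the residence correlation time — because
occupancy indicators are strongly autocorrelated and a naive iid standard
error would be dishonestly small.

## Spectral drift-independence diagnostic

The claim under test is that path components above a finite frequency
cutoff are independent of the (smooth) drift. Naive mean-detrended DFT
power does *not* show this: the drift changes the endpoint displacement,
and the discontinuity of the periodic extension leaks $O(1)$
drift-dependent power into **every** frequency bin (measured: a flat
$\approx 2\times$ power ratio at all $k$ for $c = 1.5$). The package
therefore detrends by each path's endpoint chord, which isolates the
fluctuation spectrum:

- a constant drift lives entirely in the chord, so chord-detrended drifted
  and free ensembles agree in law at *all* frequencies (kept as an exact
  property test);
- a state-dependent force (OU, $A = 5$) suppresses low-frequency
  fluctuation power (Welch $z \approx 20$ at the lowest bins) while the
  band above the cutoff $N_t/10$ is statistically indistinguishable from
  free Brownian motion (max $|z| \approx 3$ over $\sim$100 bins, consistent
  with a null maximum).

The comparison statistic is a per-bin Welch $z$ on mean per-path power;
the pass rule (max $|z| < 5$ above the cutoff, $|z| > 5$ at bin 1) is a
plain multiple-comparison bound, not a fitted threshold.

## What the generators emulate — and what they do not

All tests run on synthetic ensembles from the package's own samplers:
exact iid Gaussian noise, perfectly known potentials, no measurement
error. That is precisely the setting in which the closed forms hold, so
passing tests establish the *internal* consistency of the constructions
and estimators — they do not establish that any laboratory time series is
Euler–Maruyama with Gaussian noise. Features of real data deliberately not
emulated: multiplicative or state-dependent noise, inertia (underdamped
dynamics), measurement noise on positions, and dimensionality beyond one.

## Known limitations

- One spatial dimension; no multidimensional potentials or channels.
- Explicit Euler–Maruyama only: no implicit, midpoint, or adaptive
  stepping; stiff potentials require a suitably small $\Delta t$ or the
  propagator aborts.
- Path files are plain TSV (17 significant digits, exact double
  round-trip); there is no binary container format.
- No action minimisation or most-probable-path machinery, by design: the
  package's own results show the discrete OM functional is a property of
  the noise, path-independent in law, so a "least thermodynamic action"
  principle has nothing physical to minimise.
- The common-path KL estimators assume the generating ensemble actually
  comes from `qa` on the stated grid; they do not detect mislabelled
  ensembles.
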