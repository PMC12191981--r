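# Shared fixtures: small processes and grids used across test files.

eps_default <- 0.5

proc_zero <- function(eps = eps_default)
  process_spec(make_potential("zero"), eps)

proc_linear <- function(c = 1, eps = eps_default)
  process_spec(make_potential("linear", list(c = c)), eps)

proc_harmonic <- function(A = 1, eps = eps_default)
  process_spec(make_potential("harmonic", list(A = A)), eps)

proc_double_well <- function(h = 1, a = 1, w = 2, eps = eps_default)
  process_spec(make_potential("double_well", list(h = h, a = a, w = w)), eps)

# a pool of structurally different processes sharing one temperature,
# used by the property-style bijection/identity loops
process_pool <- function(eps = eps_default) list(
  proc_zero(eps),
  proc_linear(1, eps),
  proc_linear(-0.5, eps),
  proc_harmonic(2, eps),
  proc_double_well(1, 1, 2, eps)
)

# deterministic straight-line path x_i = x0 + slope * t_i
straight_path <- function(grid, x0 = 0, slope = 1) {
  tt <- seq(0, grid$duration, length.out = grid$n_steps + 1L)
  as_paths(x0 + slope * tt, grid)
}
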