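# Shared fixtures: the standard study configuration (a0 = 0.5, eps = 0.01,
# x0 = 0.5, dt = 0.05, t_end = 40) and a per-session cache so expensive
# spectral solves are computed once and reused across test files.

.solve_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .solve_cache, inherits = FALSE))
    assign(key, expr, envir = .solve_cache)
  get(key, envir = .solve_cache, inherits = FALSE)
}

std_params <- function(lam = 0.01, a1 = 0, a0 = 0.5, x0 = 0.5, eps = 0.01)
  pop_params(a0 = a0, eps = eps, x0 = x0, lam = lam, a1 = a1)

std_grid <- function(dt = 0.05, t_end = 40) time_grid(dt = dt, t_end = t_end)

# second-order WHE solution at the standard configuration
whe_std <- function(lam)
  cached(sprintf("whe_%g", lam), whe_solve(std_params(lam = lam), std_grid()))

# coupled gPC-WHE solution at lam = 0.02 and the given growth-rate coefficient
gpc_std <- function(a1)
  cached(sprintf("gpc_%g", a1),
         gpc_whe_solve(std_params(lam = 0.02, a1 = a1), std_grid()))

# extinction-regime coupled run (a0 < lam^2/2); longer horizon, coarser step
extinction_fit <- function()
  cached("extinction",
         gpc_whe_solve(pop_params(a0 = 1e-4, eps = 0.01, x0 = 0.5, lam = 0.02,
                                  a1 = 4e-5),
                       time_grid(dt = 0.5, t_end = 200)))

# forward-Euler trajectory of the deterministic logistic ODE (the lam = 0
# limit of the kernel scheme)
euler_logistic <- function(params, grid) {
  x <- numeric(grid$n_steps + 1L)
  x[1L] <- params$x0
  for (i in seq_len(grid$n_steps))
    x[i + 1L] <- x[i] + grid$dt * (params$a0 * x[i] - params$eps * x[i]^2)
  x
}
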