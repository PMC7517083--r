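#' Monte Carlo configuration
#'
#' Settings for the sampling-based reference solvers. A seed is required
#' explicitly: the samplers never fall back on a silent default, so identical
#' `(seed, config)` pairs give bit-identical sample moments.
#'
#' @param n_paths Number of sample paths per (inner) run, >= 1.
#' @param seed Integer RNG seed (required).
#' @param dt_mc Simulation time step; need not equal the spectral solver's
#'   grid step.
#' @param scheme `"euler_maruyama"` or `"exact_path"`.
#' @param n_param_draws Outer-loop draws of the random growth rate for
#'   [nested_mc()].
#' @return Object of class `"mc_config"`.
#' @examples
#' mc_config(n_paths = 1000, seed = 42)
#' @export
mc_config <- function(n_paths, seed, dt_mc = 0.01,
                      scheme = c("euler_maruyama", "exact_path"),
                      n_param_draws = 1L) {
  scheme <- match.arg(scheme)
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("an explicit integer 'seed' is required")
  if (n_paths < 1) stop("'n_paths' must be >= 1")
  if (dt_mc <= 0) stop("'dt_mc' must be > 0")
  structure(list(n_paths = as.integer(n_paths), seed = as.integer(seed),
                 dt_mc = dt_mc, scheme = scheme,
                 n_param_draws = as.integer(n_param_draws)),
            class = "mc_config")
}

.mc_moment_row <- function(X) {
  n <- length(X)
  m <- mean(X)
  if (n < 2L)
    return(c(mean = m, variance = 0, se_mean = 0, se_var = 0))
  d <- X - m
  v <- sum(d * d) / (n - 1)
  m4 <- mean(d^4)
  c(mean = m, variance = v,
    se_mean = sqrt(v / n),
    se_var = sqrt(max(m4 - v^2, 0) / n))
}

.as_mc_moments <- function(tab, scheme, cfg) {
  structure(as.data.frame(tab), scheme = scheme, n_paths = cfg$n_paths,
            seed = cfg$seed, dt_mc = cfg$dt_mc,
            class = c("mc_moments", "data.frame"))
}

#' Euler-Maruyama sample moments for the stochastic logistic SDE
#'
#' Simulates `n_paths` trajectories of
#' \eqn{X_{i+1} = X_i + (a X_i - \epsilon X_i^2)\Delta t + \lambda X_i \Delta W_i},
#' \eqn{\Delta W_i \sim N(0, \Delta t)}, on the Monte Carlo grid
#' `dt_mc` up to the final time of `grid`, and returns per-time sample
#' moments with standard errors. Negative excursions are floored at zero
#' (absorbing); the positive exact pathwise sampler
#' [exact_path_samples()] is the unbiased reference when flooring matters.
#'
#' @param params A [pop_params()] with `a1 = 0` (random growth rates are
#'   handled by [nested_mc()]).
#' @param grid A [time_grid()]; only its final time is used (the simulation
#'   runs on `cfg$dt_mc`).
#' @param cfg An [mc_config()].
#' @return An object of class `"mc_moments"`: data.frame with columns `t`,
#'   `mean`, `variance`, `se_mean`, `se_var`.
#' @examples
#' p <- pop_params(0.5, 0.01, 0.5, lam = 0.01)
#' em <- em_paths(p, time_grid(0.05, t_end = 2), mc_config(500, seed = 1))
#' tail(em, 1)
#' @export
em_paths <- function(params, grid, cfg) {
  stopifnot(inherits(params, "pop_params"), inherits(grid, "time_grid"),
            inherits(cfg, "mc_config"))
  if (params$a1 != 0)
    stop("em_paths requires a1 = 0; use nested_mc() for a random growth rate")
  set.seed(cfg$seed)
  t_end <- grid$times[length(grid$times)]
  nst <- as.integer(round(t_end / cfg$dt_mc))
  dtm <- cfg$dt_mc
  sq <- sqrt(dtm)
  a <- params$a0; eps <- params$eps; lam <- params$lam
  X <- rep(params$x0, cfg$n_paths)
  out <- matrix(0, nst + 1L, 4L,
                dimnames = list(NULL, c("mean", "variance", "se_mean", "se_var")))
  out[1L, ] <- .mc_moment_row(X)
  for (i in seq_len(nst)) {
    dW <- rnorm(cfg$n_paths, sd = sq)
    X <- X + (a * X - eps * X * X) * dtm + lam * X * dW
    X <- pmax(X, 0)
    out[i + 1L, ] <- .mc_moment_row(X)
  }
  .as_mc_moments(cbind(t = seq(0, by = dtm, length.out = nst + 1L), out),
                 "euler_maruyama", cfg)
}

#' Sample moments from the exact pathwise solution
#'
#' Simulates Brownian paths \eqn{B(t)} and evaluates the exact solution of
#' the stochastic logistic SDE,
#' \deqn{X(t) = \frac{e^{(a - \lambda^2/2) t + \lambda B(t)}}
#'   {1/x_0 + \epsilon \int_0^t e^{(a - \lambda^2/2) s + \lambda B(s)} ds},}
#' which is positive by construction. The denominator integral is computed
#' cell-by-cell with the exponent interpolated linearly between grid nodes
#' and integrated in closed form (\eqn{\int e^{c + m s} ds}); this is exact
#' in the deterministic limit, so at `lam = 0` the sampler reproduces
#' [exact_logistic()] to machine precision.
#'
#' @inheritParams em_paths
#' @return An `"mc_moments"` data.frame as in [em_paths()].
#' @examples
#' p <- pop_params(0.5, 0.01, 0.5, lam = 0.01)
#' ex <- exact_path_samples(p, time_grid(0.05, t_end = 2), mc_config(500, seed = 1))
#' tail(ex, 1)
#' @export
exact_path_samples <- function(params, grid, cfg) {
  stopifnot(inherits(params, "pop_params"), inherits(grid, "time_grid"),
            inherits(cfg, "mc_config"))
  if (params$a1 != 0)
    stop("exact_path_samples requires a1 = 0")
  set.seed(cfg$seed)
  t_end <- grid$times[length(grid$times)]
  nst <- as.integer(round(t_end / cfg$dt_mc))
  dtm <- cfg$dt_mc
  sq <- sqrt(dtm)
  g <- params$a0 - params$lam^2 / 2
  lam <- params$lam; eps <- params$eps
  npa <- cfg$n_paths
  E <- rep(1, npa)                 # exp(g t + lam B) at the current node
  acc <- rep(0, npa)               # running denominator integral
  out <- matrix(0, nst + 1L, 4L,
                dimnames = list(NULL, c("mean", "variance", "se_mean", "se_var")))
  out[1L, ] <- .mc_moment_row(rep(params$x0, npa))
  inv_x0 <- 1 / params$x0
  for (i in seq_len(nst)) {
    dc <- g * dtm + lam * rnorm(npa, sd = sq)   # exponent increment per cell
    # exact integral of exp over the cell for a linear exponent: E * (e^dc - 1)/dc * dt
    phi <- ifelse(abs(dc) > 1e-8, expm1(dc) / dc, 1 + dc / 2 + dc * dc / 6)
    acc <- acc + dtm * E * phi
    E <- E * exp(dc)
    X <- E / (inv_x0 + eps * acc)
    out[i + 1L, ] <- .mc_moment_row(X)
  }
  .as_mc_moments(cbind(t = seq(0, by = dtm, length.out = nst + 1L), out),
                 "exact_path", cfg)
}

#' Nested parameter-plus-noise Monte Carlo
#'
#' Validation oracle for the coupled gPC-WHE solver: the outer loop draws the
#' growth rate from its uniform distribution (`n_param_draws` draws), the
#' inner loop runs Euler-Maruyama paths per draw, and the law of total
#' variance splits the result into a between-draw (parameter) component
#' (variance over draws of the inner means) and a within-draw (noise-like)
#' component (mean over draws of the inner variances).
#'
#' @inheritParams em_paths
#' @param params A [pop_params()] with `a1 > 0`.
#' @param a1_convention As in [gpc_whe_solve()]: `"coefficient"` (default,
#'   `a1` = sd of a, so a ~ U[a0 - sqrt(3) a1, a0 + sqrt(3) a1]) or
#'   `"half_width"` (a ~ U[a0 - a1, a0 + a1]).
#' @return An `"mc_moments"` data.frame with columns `t`, `mean`, `variance`
#'   (total, across all draws and paths), `se_mean`, `se_var`,
#'   `var_between` (parameter component), `var_within` (noise component).
#' @examples
#' p <- pop_params(0.5, 0.01, 0.5, lam = 0.02, a1 = 0.01)
#' nm <- nested_mc(p, time_grid(0.05, t_end = 1),
#'                 mc_config(100, seed = 1, dt_mc = 0.02, n_param_draws = 20))
#' tail(nm, 1)
#' @export
nested_mc <- function(params, grid, cfg,
                      a1_convention = c("coefficient", "half_width")) {
  stopifnot(inherits(params, "pop_params"), inherits(grid, "time_grid"),
            inherits(cfg, "mc_config"))
  a1_convention <- match.arg(a1_convention)
  if (params$a1 <= 0) stop("nested_mc requires a1 > 0")
  set.seed(cfg$seed)
  hw <- if (a1_convention == "coefficient") sqrt(3) * params$a1 else params$a1
  nd <- cfg$n_param_draws
  npa <- cfg$n_paths
  a_draws <- runif(nd, params$a0 - hw, params$a0 + hw)
  t_end <- grid$times[length(grid$times)]
  nst <- as.integer(round(t_end / cfg$dt_mc))
  dtm <- cfg$dt_mc
  sq <- sqrt(dtm)
  eps <- params$eps; lam <- params$lam
  A <- matrix(rep(a_draws, each = npa), npa, nd)
  X <- matrix(params$x0, npa, nd)
  N <- npa * nd
  out <- matrix(0, nst + 1L, 6L,
                dimnames = list(NULL, c("mean", "variance", "se_mean", "se_var",
                                        "var_between", "var_within")))
  split_row <- function(X) {
    base <- .mc_moment_row(as.vector(X))
    cm <- colMeans(X)
    within <- (colSums(X * X) - npa * cm * cm) / (npa - 1)
    c(base, var_between = stats::var(cm), var_within = mean(within))
  }
  out[1L, ] <- split_row(X)
  for (i in seq_len(nst)) {
    dW <- matrix(rnorm(N, sd = sq), npa, nd)
    X <- X + (A * X - eps * X * X) * dtm + lam * X * dW
    X[X < 0] <- 0
    out[i + 1L, ] <- split_row(X)
  }
  .as_mc_moments(cbind(t = seq(0, by = dtm, length.out = nst + 1L), out),
                 "nested_mc", cfg)
}

#' @export
print.mc_moments <- function(x, ...) {
  if (!all(c("t", "mean", "variance", "se_mean", "se_var") %in% names(x)) ||
      nrow(x) == 0L)
    return(NextMethod())
  cat(sprintf("Monte Carlo sample moments (%s): %d paths, dt = %g, seed = %d\n",
              attr(x, "scheme"), attr(x, "n_paths"), attr(x, "dt_mc"),
              attr(x, "seed")))
  fin <- x[nrow(x), ]
  cat(sprintf("  final t = %g: mean = %.5g (se %.2g), variance = %.5g (se %.2g)\n",
              fin$t, fin$mean, fin$se_mean, fin$variance, fin$se_var))
  invisible(x)
}
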