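#' Model parameters for the stochastic logistic population model
#'
#' Bundles the coefficients of the stochastic Verhulst SDE
#' \deqn{dX = (a X - \epsilon X^2)\,dt + \lambda X\,dW, \qquad X(0) = x_0,}
#' where the growth rate may itself be uncertain, \eqn{a(\omega) = a_0 + a_1
#' \psi_1(\zeta)} with \eqn{\psi_1} the orthonormal degree-1 Legendre
#' polynomial of a uniform random variable (see [legendre_orthonormal()]).
#' With this convention `a1` is the standard deviation of the growth rate and
#' `a` is uniform on \eqn{[a_0 - \sqrt{3} a_1,\; a_0 + \sqrt{3} a_1]}.
#'
#' @param a0 Mean growth rate (1/time). The deterministic growth rate when
#'   `a1 = 0`.
#' @param eps Nonlinear loss (crowding) coefficient \eqn{\epsilon} > 0
#'   (1/(time * population)). The carrying capacity is `L = a0/eps`.
#' @param x0 Initial population, > 0.
#' @param lam Diffusion coefficient \eqn{\lambda} >= 0 (1/sqrt(time));
#'   `lam = 0` recovers the deterministic model.
#' @param a1 Growth-rate uncertainty coefficient >= 0 (1/time); the
#'   coefficient of the orthonormal chaos polynomial \eqn{\psi_1}, equal to
#'   sd(a). `a1 = 0` means the growth rate is deterministic.
#'
#' @return An object of class `"pop_params"`: a list with fields `a0`, `eps`,
#'   `x0`, `lam`, `a1`.
#' @seealso [carrying_capacity()], [growth_regime()], [time_grid()]
#' @examples
#' p <- pop_params(a0 = 0.5, eps = 0.01, x0 = 0.5, lam = 0.01)
#' carrying_capacity(p)
#' growth_regime(p)
#' @export
pop_params <- function(a0, eps, x0, lam = 0, a1 = 0) {
  for (nm in c("a0", "eps", "x0", "lam", "a1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite numeric value", nm))
  }
  if (eps <= 0) stop("'eps' must be > 0")
  if (x0 <= 0) stop("'x0' must be > 0")
  if (lam < 0) stop("'lam' must be >= 0")
  if (a1 < 0) stop("'a1' must be >= 0")
  structure(list(a0 = a0, eps = eps, x0 = x0, lam = lam, a1 = a1),
            class = "pop_params")
}

#' Carrying capacity of the logistic model
#'
#' @param params A [pop_params()] object.
#' @return `a0/eps`, the saturation level L.
#' @export
carrying_capacity <- function(params) {
  stopifnot(inherits(params, "pop_params"))
  params$a0 / params$eps
}

#' Long-run regime of the stochastic logistic model
#'
#' The pathwise-exact solution is recurrent with a stationary gamma law when
#' `a0 > lam^2/2` ("persistent"), decays to zero almost surely when
#' `a0 < lam^2/2` ("extinction"), and sits on the noise-induced transition
#' point when equal. The comparison is exact (zero tolerance): the transition
#' case is measure-zero and only informational.
#'
#' @param params A [pop_params()] object.
#' @return One of `"persistent"`, `"extinction"`, `"transition"`.
#' @export
growth_regime <- function(params) {
  stopifnot(inherits(params, "pop_params"))
  thr <- params$lam^2 / 2
  if (params$a0 > thr) "persistent"
  else if (params$a0 < thr) "extinction"
  else "transition"
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Stochastic logistic model parameters\n")
  cat(sprintf("  growth rate a0 = %g, eps = %g (L = %g), lambda = %g, x0 = %g\n",
              x$a0, x$eps, x$a0 / x$eps, x$lam, x$x0))
  if (x$a1 > 0)
    cat(sprintf("  random growth rate: sd(a) = %g (a ~ U[%g, %g])\n",
                x$a1, x$a0 - sqrt(3) * x$a1, x$a0 + sqrt(3) * x$a1))
  cat(sprintf("  regime: %s (a0 vs lambda^2/2 = %g)\n",
              growth_regime(x), x$lam^2 / 2))
  invisible(x)
}

#' Uniform time grid
#'
#' The discretization used by the kernel finite-difference solvers. Nodes are
#' `t_i = i * dt`, `i = 0, ..., n_steps`. Kernel supports on the grid are
#' causal: any kernel value with `t1 > t` or `t2 > t` is identically zero.
#' The solver stability bound `dt < 1/a0` is checked at solver entry (see
#' [max_stable_dt()]), not here.
#'
#' @param dt Time step, > 0.
#' @param t_end Final time; used when `n_steps` is missing
#'   (`n_steps = round(t_end/dt)`).
#' @param n_steps Integer number of steps >= 1.
#' @return An object of class `"time_grid"`: list with `dt`, `n_steps`,
#'   `times` (length `n_steps + 1`).
#' @examples
#' g <- time_grid(dt = 0.05, t_end = 40)
#' g$n_steps
#' @export
time_grid <- function(dt, t_end = NULL, n_steps = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  if (is.null(n_steps)) {
    if (is.null(t_end)) stop("supply either 't_end' or 'n_steps'")
    n_steps <- as.integer(round(t_end / dt))
  }
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("'n_steps' must be >= 1")
  structure(list(dt = dt, n_steps = n_steps, times = seq(0, by = dt,
                                                         length.out = n_steps + 1L)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("Uniform time grid: dt = %g, %d steps, t in [0, %g]\n",
              x$dt, x$n_steps, x$times[length(x$times)]))
  invisible(x)
}
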