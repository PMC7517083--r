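#' Exact solution of the deterministic logistic (Verhulst) model
#'
#' Closed form for \eqn{dX/dt = a X - \epsilon X^2}, \eqn{X(0) = x_0}:
#' \deqn{X(t) = \frac{a x_0}{\epsilon x_0 + (a - \epsilon x_0) e^{-a t}}
#'            = \frac{L}{1 + (L/x_0 - 1) e^{-a t}},}
#' with carrying capacity \eqn{L = a/\epsilon}. For `a0 > 0` the solution is
#' the sigmoid approaching L; for `a0 < 0` it decays to zero (extinction).
#' Any noise or growth-rate uncertainty in `params` (`lam`, `a1`) is ignored.
#'
#' @param params A [pop_params()] object; `a0` must be nonzero.
#' @param t Time(s) >= 0 (vectorized).
#' @return Population value(s) X(t).
#' @examples
#' p <- pop_params(a0 = 0.5, eps = 0.01, x0 = 0.5)
#' exact_logistic(p, c(0, 10, 40))
#' @export
exact_logistic <- function(params, t) {
  stopifnot(inherits(params, "pop_params"))
  if (params$a0 == 0)
    stop("exact_logistic is degenerate for a0 = 0")
  if (any(t < 0)) stop("'t' must be >= 0")
  a <- params$a0; eps <- params$eps; x0 <- params$x0
  a * x0 / (eps * x0 + (a - eps * x0) * exp(-a * t))
}

#' Exact solution of the Richards growth model
#'
#' The Richards model generalizes the logistic with an allometric curvature
#' exponent `beta` (`beta = 2` is the Verhulst model). Two common
#' parameterizations are supported:
#' \describe{
#'   \item{`"capacity"`}{\eqn{dX/dt = a X [1 - (X/L)^{\beta-1}]} with
#'     \eqn{L = a_0/\epsilon}. The plateau is L for every `beta`, so the
#'     allometric exponent shapes the transient only.}
#'   \item{`"loss"`}{\eqn{dX/dt = a X - \epsilon X^\beta}. The plateau is
#'     \eqn{(a/\epsilon)^{1/(\beta-1)}} and coincides with L only at
#'     `beta = 2`.}
#' }
#' Both reduce exactly to [exact_logistic()] at `beta = 2`. The closed form is
#' obtained from the Bernoulli substitution \eqn{u = X^{1-\beta}}:
#' \deqn{X(t) = K\,[1 + ((K/x_0)^{\beta-1} - 1)\,e^{-(\beta-1) a t}]^{-1/(\beta-1)},}
#' where K is the plateau of the chosen parameterization.
#'
#' @inheritParams exact_logistic
#' @param beta Allometric exponent > 0, `beta != 1`.
#' @param parameterization `"capacity"` (default) or `"loss"`, see Details.
#' @return Population value(s) X(t).
#' @examples
#' p <- pop_params(a0 = 0.5, eps = 0.01, x0 = 0.5)
#' exact_richards(p, beta = 3, t = 10)
#' all.equal(exact_richards(p, 2, 7), exact_logistic(p, 7))
#' @export
exact_richards <- function(params, beta, t,
                           parameterization = c("capacity", "loss")) {
  stopifnot(inherits(params, "pop_params"))
  parameterization <- match.arg(parameterization)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a single positive number")
  if (beta == 1) stop("'beta' = 1 is degenerate (exponential model)")
  if (params$a0 == 0) stop("exact_richards is degenerate for a0 = 0")
  if (any(t < 0)) stop("'t' must be >= 0")
  a <- params$a0; x0 <- params$x0
  K <- switch(parameterization,
              capacity = params$a0 / params$eps,
              loss = (params$a0 / params$eps)^(1 / (beta - 1)))
  K * (1 + ((K / x0)^(beta - 1) - 1) * exp(-(beta - 1) * a * t))^(-1 / (beta - 1))
}

#' Moments of the stationary gamma distribution of the stochastic logistic model
#'
#' In the persistent regime `a0 > lam^2/2` (with deterministic growth rate,
#' `a1 = 0`) the stochastic logistic SDE converges to the stationary gamma
#' distribution with shape \eqn{2a/\lambda^2 - 1} and scale
#' \eqn{\lambda^2/(2\epsilon)}. This returns its mean and variance, used as
#' the small-noise steady-state oracle for the spectral solvers. Note
#' mean \eqn{= a_0/\epsilon - \lambda^2/(2\epsilon)}, slightly below the
#' carrying capacity, and variance \eqn{\to 0} as \eqn{\lambda \to 0}.
#'
#' @param params A [pop_params()] object with `a1 = 0` and
#'   `a0 > lam^2/2`.
#' @return Named list with `mean`, `variance`, `shape`, `scale`.
#' @examples
#' stationary_gamma_moments(pop_params(0.5, 0.01, 0.5, lam = 0.01))
#' @export
stationary_gamma_moments <- function(params) {
  stopifnot(inherits(params, "pop_params"))
  if (params$a1 != 0)
    stop("stationary gamma moments are defined for a deterministic growth rate (a1 = 0)")
  if (growth_regime(params) != "persistent")
    stop("no stationary gamma distribution in this regime (requires a0 > lam^2/2)")
  shape <- 2 * params$a0 / params$lam^2 - 1
  scale <- params$lam^2 / (2 * params$eps)
  list(mean = shape * scale, variance = shape * scale^2,
       shape = shape, scale = scale)
}

#' Exact moments of the linear stochastic transport model
#'
#' For the linear model \eqn{dX = a X\,dt + \lambda X\,dW} (geometric
#' Brownian motion) the exact moments are
#' \deqn{E[X(t)] = x_0 e^{a t}, \qquad
#'       Var[X(t)] = x_0^2 e^{2 a t} (e^{\lambda^2 t} - 1).}
#' To first order in \eqn{\lambda^2 t} the variance is
#' \eqn{\lambda^2 t\, x_0^2 e^{2 a t}}, which is what the first-order
#' Wiener-Hermite kernel \eqn{x^{(1)}(t, t_1) = \lambda x_0 e^{a t}}
#' integrates to. Used as the analytic oracle for the linear (`eps = 0`)
#' reduction of the kernel solver.
#'
#' @param a Growth rate.
#' @param lam Diffusion coefficient >= 0.
#' @param x0 Initial value.
#' @param t Time(s) >= 0 (vectorized).
#' @return List with vectors `mean` and `variance`.
#' @examples
#' linear_model_moments(a = 0.5, lam = 0.1, x0 = 1, t = 1)
#' @export
linear_model_moments <- function(a, lam, x0, t) {
  if (any(t < 0)) stop("'t' must be >= 0")
  m <- x0 * exp(a * t)
  v <- x0^2 * exp(2 * a * t) * expm1(lam^2 * t)
  list(mean = m, variance = v)
}
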