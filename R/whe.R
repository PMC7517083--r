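#' Stability bound for the explicit kernel finite-difference scheme
#'
#' The explicit first-order scheme for the Wiener-Hermite kernel system is
#' convergent for `dt < 1/a0` (obtained from the fixed-point contraction
#' condition after bounding the mean kernel by the carrying capacity). For
#' `a0 <= 0` the bound was derived for the growth regime and does not apply;
#' `+Inf` is returned with a note.
#'
#' @param params A [pop_params()] object.
#' @return The largest admissible time step `1/a0`, or `+Inf` when `a0 <= 0`.
#' @examples
#' max_stable_dt(pop_params(0.5, 0.01, 0.5))  # 2
#' @export
max_stable_dt <- function(params) {
  stopifnot(inherits(params, "pop_params"))
  if (params$a0 <= 0) {
    message("stability bound dt < 1/a0 derived for the growth regime (a0 > 0); ",
            "no finite bound returned for a0 <= 0")
    return(Inf)
  }
  1 / params$a0
}

# Convergence flag: relative change of a series over its last `frac` of steps.
.settled <- function(v, frac = 0.1, tol = 1e-5) {
  n <- length(v)
  i0 <- max(1L, n - as.integer(ceiling(frac * n)))
  ref <- abs(v[n])
  if (ref < .Machine$double.eps) ref <- 1
  max(abs(v[i0:n] - v[n])) / ref < tol
}

#' Second-order Wiener-Hermite expansion solver for the stochastic logistic SDE
#'
#' Solves the deterministic kernel system equivalent (to second WHE order) to
#' \deqn{dX = (a X - \epsilon X^2)\,dt + \lambda X\,dW}
#' for deterministic growth rate (`a1 = 0`), using an explicit first-order
#' finite-difference scheme on a uniform grid. The mean kernel
#' \eqn{x^{(0)}(t)}, Gaussian kernel \eqn{x^{(1)}(t,t_1)} and non-Gaussian
#' kernel \eqn{x^{(2)}(t,t_1,t_2)} obey
#' \deqn{\dot x^{(0)} = a x^{(0)} - \epsilon[(x^{(0)})^2 + I_1 + I_2],}
#' \deqn{\dot x^{(1)} = a x^{(1)} - 2\epsilon x^{(0)} x^{(1)}
#'   - 4\epsilon \int x^{(1)}(t_2) x^{(2)}(t_1,t_2)\,dt_2
#'   + \lambda \delta(t-t_1) x^{(0)},}
#' \deqn{\dot x^{(2)} = a x^{(2)} - 2\epsilon x^{(0)} x^{(2)}
#'   - \epsilon x^{(1)}(t_1) x^{(1)}(t_2) + \lambda \delta(t-t_2) x^{(1)}(t_1),}
#' with \eqn{I_1 = \int (x^{(1)})^2 dt_1} and
#' \eqn{I_2 = 2\int\!\!\int (x^{(2)})^2 dt_1 dt_2}. Kernel integrals use the
#' midpoint (cell-representative) rule on the causal support; the Dirac
#' forcing is realized as a step-independent Kronecker jump
#' \eqn{\lambda x^{(0)}_i} when the time index reaches the kernel argument
#' index, which reproduces the exact first-order kernel of the linear model.
#' The second-order kernel is symmetrized in \eqn{(t_1,t_2)} after every step.
#'
#' The moments are \eqn{E[X] = x^{(0)}} and, by the \eqn{k!}-weighted kernel
#' identity, \eqn{Var[X] = I_1 + 2\int\!\!\int (x^{(2)})^2 = I_1 + I_2}:
#' `var_gaussian` is \eqn{I_1} and `var_nongaussian` is \eqn{I_2}.
#'
#' @param params A [pop_params()] object with `a1 = 0` (use
#'   [gpc_whe_solve()] for a random growth rate).
#' @param grid A [time_grid()]; requires `grid$dt < max_stable_dt(params)`.
#' @param keep_kernels If `TRUE`, retain the full first-order kernel history
#'   `x1[i, j]` (time node i, argument node j) and the final-time second-order
#'   kernel matrix.
#' @return An object of class `"whe_fit"`: list with `moments` (data.frame
#'   `t`, `mean`, `var_total`, `var_gaussian`, `var_nongaussian`),
#'   `steady_state` (final-time values plus `converged` flag: relative change
#'   of mean and total variance below 1e-5 over the last 10% of steps),
#'   `params`, `grid`, and optionally `kernels`.
#' @examples
#' p <- pop_params(a0 = 0.5, eps = 0.01, x0 = 0.5, lam = 0.01)
#' fit <- whe_solve(p, time_grid(dt = 0.05, t_end = 10))
#' fit
#' @export
whe_solve <- function(params, grid, keep_kernels = FALSE) {
  stopifnot(inherits(params, "pop_params"), inherits(grid, "time_grid"))
  if (params$a1 != 0)
    stop("whe_solve requires a deterministic growth rate (a1 = 0); ",
         "use gpc_whe_solve() for a random growth rate")
  if (grid$dt >= max_stable_dt(params))
    stop(sprintf("dt = %g violates the stability bound dt < 1/a0 = %g",
                 grid$dt, 1 / params$a0))
  n <- grid$n_steps
  dt <- grid$dt
  a <- params$a0; eps <- params$eps; lam <- params$lam

  mean_v <- numeric(n + 1L)
  var_g <- numeric(n + 1L)
  var_ng <- numeric(n + 1L)
  mean_v[1L] <- params$x0

  x1 <- numeric(n)          # current slice x^(1)(t_i, t1_j), j = 1..n
  x2 <- matrix(0, n, n)     # current slice x^(2)(t_i, t1_j, t2_k)
  x1hist <- if (keep_kernels) matrix(0, n + 1L, n) else NULL

  for (m in seq_len(n)) {
    s <- seq_len(m - 1L)
    x0m <- mean_v[m]
    x1s <- x1[s]
    I1 <- dt * sum(x1s * x1s)
    if (m > 1L) {
      B <- x2[s, s, drop = FALSE]
      I2 <- 2 * dt^2 * sum(B * B)
    } else I2 <- 0
    if (!is.finite(x0m + I1 + I2))
      stop("FDM diverged; reduce dt")

    mean_v[m + 1L] <- x0m + dt * (a * x0m - eps * (x0m * x0m + I1 + I2))

    if (m > 1L) {
      I12 <- dt * drop(B %*% x1s)
      x1[s] <- x1s + dt * (a * x1s - eps * (2 * (x0m * x1s) + 4 * I12))
      Bn <- B + dt * (a * B - eps * (2 * (x0m * B) + tcrossprod(x1s)))
      blk <- matrix(0, m, m)
      blk[s, s] <- Bn
      blk[s, m] <- blk[s, m] + lam * x1s   # Kronecker jump at k = i
      blk <- (blk + t(blk)) / 2
      x2[seq_len(m), seq_len(m)] <- blk
      var_ng[m + 1L] <- 2 * dt^2 * sum(blk * blk)
    }
    x1[m] <- lam * x0m                      # Kronecker jump at j = i
    var_g[m + 1L] <- dt * sum(x1[seq_len(m)]^2)
    if (keep_kernels) x1hist[m + 1L, ] <- x1
  }

  var_tot <- var_g + var_ng
  moments <- data.frame(t = grid$times, mean = mean_v, var_total = var_tot,
                        var_gaussian = var_g, var_nongaussian = var_ng)
  converged <- .settled(mean_v) && .settled(var_tot)
  fit <- structure(list(
    params = params, grid = grid, moments = moments,
    steady_state = list(mean = mean_v[n + 1L], var_total = var_tot[n + 1L],
                        var_gaussian = var_g[n + 1L],
                        var_nongaussian = var_ng[n + 1L],
                        converged = converged),
    kernels = if (keep_kernels) list(x1 = x1hist, x2_final = x2) else NULL,
    call = match.call()), class = "whe_fit")
  fit
}

#' Non-Gaussian share of the total variance
#'
#' Ratio of the second-order (non-Gaussian) kernel variance component to the
#' total variance per time point; defined as 0 where the total variance is 0.
#'
#' @param fit A `"whe_fit"` or `"gpcwhe_fit"` object, or a moments data frame
#'   with columns `var_total` and `var_nongaussian`.
#' @return Numeric vector in `[0, 1]`, one value per time node.
#' @examples
#' p <- pop_params(0.5, 0.01, 0.5, lam = 0.01)
#' fr <- nongaussian_fraction(whe_solve(p, time_grid(0.05, t_end = 10)))
#' tail(fr, 1)
#' @export
nongaussian_fraction <- function(fit) {
  m <- if (is.data.frame(fit)) fit else fit$moments
  stopifnot(all(c("var_total", "var_nongaussian") %in% names(m)))
  ifelse(m$var_total > 0, m$var_nongaussian / m$var_total, 0)
}
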