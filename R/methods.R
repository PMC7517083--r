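#' @export
print.whe_fit <- function(x, ...) {
  ss <- x$steady_state
  lab <- if (inherits(x, "gpcwhe_fit")) "Coupled gPC-WHE" else "Second-order WHE"
  cat(sprintf("%s solution of the stochastic logistic model\n", lab))
  cat(sprintf("  a0 = %g, eps = %g, lambda = %g, x0 = %g",
              x$params$a0, x$params$eps, x$params$lam, x$params$x0))
  if (inherits(x, "gpcwhe_fit"))
    cat(sprintf(", a1 = %g (%s, P = %d)", x$a1_coefficient, x$system, x$P))
  cat("\n")
  cat(sprintf("  grid: dt = %g, %d steps (t_end = %g); %s\n", x$grid$dt,
              x$grid$n_steps, x$grid$times[length(x$grid$times)],
              if (ss$converged) "converged to steady state" else "NOT converged"))
  cat(sprintf("  final mean = %.6g, total variance = %.6g\n", ss$mean, ss$var_total))
  if (inherits(x, "gpcwhe_fit"))
    cat(sprintf("  variance split: par %.6g / noise %.6g / mix %.3g\n",
                ss$var_par, ss$var_noise, ss$var_mix))
  else
    cat(sprintf("  variance split: Gaussian %.6g / nonGaussian %.3g\n",
                ss$var_gaussian, ss$var_nongaussian))
  invisible(x)
}

#' Summary of a spectral solution
#'
#' @param object A `"whe_fit"` or `"gpcwhe_fit"`.
#' @param ... Unused.
#' @return The object's `steady_state` list, invisibly, after printing a
#'   steady-state report including the non-Gaussian variance share.
#' @export
summary.whe_fit <- function(object, ...) {
  print(object)
  ss <- object$steady_state
  fr <- nongaussian_fraction(object)
  cat(sprintf("  nonGaussian share of total variance at t_end: %.4g%%\n",
              100 * fr[length(fr)]))
  if (inherits(object, "gpcwhe_fit")) {
    si <- sensitivity_indices(decompose_variance(object))
    cat(sprintf("  sensitivity indices: S_noise = %.1f%%, S_par = %.1f%%, S_mix = %.2g%%\n",
                100 * si$s_noise, 100 * si$s_par, 100 * si$s_mix))
  }
  invisible(ss)
}

#' @export
as.data.frame.whe_fit <- function(x, ...) x$moments

#' Plot a spectral solution
#'
#' Two-panel base-graphics display: mean population and variance components
#' against time.
#'
#' @param x A `"whe_fit"` or `"gpcwhe_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.whe_fit <- function(x, ...) {
  m <- x$moments
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(m$t, m$mean, type = "l", xlab = "t", ylab = "mean population",
                 main = "Mean", ...)
  if (inherits(x, "gpcwhe_fit")) {
    graphics::matplot(m$t, cbind(m$var_total, m$var_par, m$var_noise, m$var_mix),
                      type = "l", lty = 1:4, col = 1:4, xlab = "t",
                      ylab = "variance", main = "Variance components")
    graphics::legend("topleft", c("total", "parameter", "noise", "mixed"),
                     lty = 1:4, col = 1:4, bty = "n", cex = 0.8)
  } else {
    graphics::matplot(m$t, cbind(m$var_total, m$var_gaussian, m$var_nongaussian),
                      type = "l", lty = 1:3, col = 1:3, xlab = "t",
                      ylab = "variance", main = "Variance components")
    graphics::legend("topleft", c("total", "Gaussian", "nonGaussian"),
                     lty = 1:3, col = 1:3, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Simulate sample paths at the fitted parameters
#'
#' Draws Monte Carlo sample moments at the parameters of a spectral fit:
#' Euler-Maruyama paths for a deterministic growth rate, nested
#' parameter-plus-noise sampling when the fit carries growth-rate
#' uncertainty. Intended as a quick consistency companion to the spectral
#' moments.
#'
#' @param object A `"whe_fit"` or `"gpcwhe_fit"`.
#' @param nsim Number of sample paths (inner paths for the nested sampler).
#' @param seed Integer RNG seed (required; no silent default).
#' @param ... Passed to [mc_config()] (e.g. `dt_mc`, `n_param_draws`).
#' @return An `"mc_moments"` data.frame.
#' @export
simulate.whe_fit <- function(object, nsim = 1000, seed, ...) {
  cfg <- mc_config(n_paths = nsim, seed = seed, ...)
  if (inherits(object, "gpcwhe_fit") && object$params$a1 > 0) {
    if (cfg$n_param_draws < 2L) cfg$n_param_draws <- 100L
    nested_mc(object$params, object$grid, cfg)
  } else {
    em_paths(object$params, object$grid, cfg)
  }
}
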