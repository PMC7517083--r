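#' Decompose the solution variance into parameter, noise and mixed components
#'
#' For a coupled gPC-WHE solution with kernels \eqn{x_k^{(j)}} (gPC index k,
#' Wiener-Hermite order j) the total variance splits exactly as
#' \deqn{Var[X] = Var_{par} + Var_{noise} + Var_{mix},}
#' \deqn{Var_{par} = \sum_{k \ge 1} [x_k^{(0)}]^2, \quad
#'       Var_{noise} = \sum_{j \ge 1} j! \int [x_0^{(j)}]^2 d\tau_j, \quad
#'       Var_{mix} = \sum_{k \ge 1}\sum_{j \ge 1} j! \int [x_k^{(j)}]^2 d\tau_j,}
#' using the same midpoint-rule kernel integrals as the solver. The
#' sensitivity index of a source is its variance share, e.g.
#' \eqn{S_{noise} = Var_{noise}/Var[X]}; indices are reported as fractions
#' and sum to 1 wherever the total variance is positive.
#'
#' @param fit A `"gpcwhe_fit"` from [gpc_whe_solve()] (a plain `"whe_fit"` is
#'   accepted and treated as having no parameter uncertainty).
#' @return An object of class `"variance_report"`: a data.frame with columns
#'   `t`, `var_total`, `var_par`, `var_noise`, `var_mix`, `s_noise`, `s_par`,
#'   `s_mix`, carrying attributes `steady_state` (final-time row) and
#'   `converged`. Indices are 0 (flagged degenerate) where `var_total = 0`.
#' @examples
#' p <- pop_params(0.5, 0.01, 0.5, lam = 0.02, a1 = 0.01)
#' rep <- decompose_variance(gpc_whe_solve(p, time_grid(0.05, t_end = 10)))
#' tail(rep, 2)
#' @export
decompose_variance <- function(fit) {
  stopifnot(inherits(fit, "whe_fit"))
  m <- fit$moments
  if (!"var_par" %in% names(m)) {        # pure WHE: all variance is noise
    m$var_par <- 0
    m$var_noise <- m$var_total
    m$var_mix <- 0
  }
  pos <- m$var_total > 0
  s_noise <- s_par <- s_mix <- numeric(nrow(m))
  s_noise[pos] <- m$var_noise[pos] / m$var_total[pos]
  s_par[pos] <- m$var_par[pos] / m$var_total[pos]
  s_mix[pos] <- m$var_mix[pos] / m$var_total[pos]
  out <- data.frame(t = m$t, var_total = m$var_total, var_par = m$var_par,
                    var_noise = m$var_noise, var_mix = m$var_mix,
                    s_noise = s_noise, s_par = s_par, s_mix = s_mix)
  structure(out,
            steady_state = out[nrow(out), , drop = FALSE],
            converged = isTRUE(fit$steady_state$converged),
            degenerate = !pos[length(pos)],
            class = c("variance_report", "data.frame"))
}

#' Variance-based sensitivity indices
#'
#' Extracts the sensitivity indices (variance shares) of the noise, the
#' random parameter, and their interaction at a given time or at steady state
#' (the final node of a converged run).
#'
#' @param report A `"variance_report"` from [decompose_variance()].
#' @param t Either `"steady_state"` (default: final time node) or a numeric
#'   time; the nearest grid node is used.
#' @return Named list `s_noise`, `s_par`, `s_mix` (fractions summing to 1),
#'   plus `degenerate = TRUE` with all-zero indices where the total variance
#'   is zero.
#' @examples
#' p <- pop_params(0.5, 0.01, 0.5, lam = 0.02, a1 = 0.01)
#' rep <- decompose_variance(gpc_whe_solve(p, time_grid(0.05, t_end = 10)))
#' sensitivity_indices(rep)
#' @export
sensitivity_indices <- function(report, t = "steady_state") {
  stopifnot(inherits(report, "variance_report"))
  row <- if (identical(t, "steady_state")) nrow(report)
         else which.min(abs(report$t - t))
  tot <- report$var_total[row]
  if (tot <= 0)
    return(list(s_noise = 0, s_par = 0, s_mix = 0, degenerate = TRUE))
  list(s_noise = report$s_noise[row], s_par = report$s_par[row],
       s_mix = report$s_mix[row], degenerate = FALSE)
}

#' @export
print.variance_report <- function(x, ...) {
  ss <- attr(x, "steady_state")
  cat("Variance decomposition (noise / parameter / mixed)\n")
  cat(sprintf("  %d time points, t in [%g, %g]%s\n", nrow(x), x$t[1],
              x$t[nrow(x)],
              if (isTRUE(attr(x, "converged"))) ", converged" else ""))
  cat(sprintf("  final: var_total = %.6g (par %.6g, noise %.6g, mix %.3g)\n",
              ss$var_total, ss$var_par, ss$var_noise, ss$var_mix))
  cat(sprintf("  indices: S_par = %.1f%%, S_noise = %.1f%%, S_mix = %.2g%%\n",
              100 * ss$s_par, 100 * ss$s_noise, 100 * ss$s_mix))
  invisible(x)
}
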