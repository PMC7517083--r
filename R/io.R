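# Flat key=value run configuration and CSV writers.

.rc_numeric <- c("a0", "eps", "x0", "lam", "a1", "dt", "t_end", "dt_mc")
.rc_integer <- c("P", "n_paths", "seed", "n_param_draws")
.rc_logical <- c("gaussian_only")
.rc_character <- c("solver", "system", "a1_convention", "output_dir", "preset")
.rc_solvers <- c("whe", "gpc_whe", "gpc_whe_gaussian_only", "em", "exact_path",
                 "nested_mc")

#' Run configuration
#'
#' A flat, fully expanded description of a single solver run, serializable to
#' and parseable from a plain `key = value` text file with a lossless
#' round-trip. Used by the command-line interface and the experiment presets.
#'
#' @param a0,eps,x0,lam,a1 Model parameters, see [pop_params()].
#' @param dt,t_end Grid settings, see [time_grid()].
#' @param solver One of `"whe"`, `"gpc_whe"`, `"gpc_whe_gaussian_only"`,
#'   `"em"`, `"exact_path"`, `"nested_mc"`.
#' @param P,system,a1_convention gPC settings, see [gpc_whe_solve()].
#' @param n_paths,seed,dt_mc,n_param_draws Monte Carlo settings, see
#'   [mc_config()]; `seed` is mandatory for the sampling solvers.
#' @param output_dir,preset Bookkeeping fields carried in manifests.
#' @return Object of class `"run_config"` (named list).
#' @examples
#' cfg <- run_config(a0 = 0.5, eps = 0.01, x0 = 0.5, lam = 0.01)
#' cfg$solver
#' @export
run_config <- function(a0 = 0.5, eps = 0.01, x0 = 0.5, lam = 0.01, a1 = 0,
                       dt = 0.05, t_end = 40, solver = "whe", P = 1L,
                       system = "reference", a1_convention = "coefficient",
                       n_paths = 10000L, seed = NA_integer_, dt_mc = 0.01,
                       n_param_draws = 200L, output_dir = ".",
                       preset = "") {
  solver <- match.arg(solver, .rc_solvers)
  structure(list(a0 = a0, eps = eps, x0 = x0, lam = lam, a1 = a1, dt = dt,
                 t_end = t_end, solver = solver, P = as.integer(P),
                 system = system, a1_convention = a1_convention,
                 n_paths = as.integer(n_paths), seed = as.integer(seed),
                 dt_mc = dt_mc, n_param_draws = as.integer(n_param_draws),
                 output_dir = output_dir, preset = preset),
            class = "run_config")
}

.fmt_val <- function(v) {
  if (is.numeric(v) && !is.integer(v)) sprintf("%.17g", v)
  else if (is.logical(v)) tolower(as.character(v))
  else as.character(v)
}

#' Write a run configuration as a flat key=value text file
#'
#' Numeric values are written with 17 significant digits so that
#' [read_run_config()] round-trips them exactly.
#'
#' @param cfg A [run_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- vapply(names(cfg), function(nm) paste(nm, "=", .fmt_val(cfg[[nm]])),
                  character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a run configuration from a flat key=value text file
#'
#' Lines starting with `#` and keys prefixed `meta.` (written into manifests)
#' are ignored.
#'
#' @param path File path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  cfg <- run_config()
  for (m in kv) {
    if (length(m) != 3L) next
    key <- m[2]; val <- m[3]
    if (startsWith(key, "meta.")) next
    if (!key %in% names(cfg)) stop(sprintf("unknown configuration key '%s'", key))
    cfg[[key]] <-
      if (key %in% .rc_numeric) {
        if (identical(val, "NA")) NA_real_ else as.numeric(val)
      } else if (key %in% .rc_integer) {
        if (identical(val, "NA")) NA_integer_ else as.integer(val)
      } else if (key %in% .rc_logical) identical(tolower(val), "true")
      else val
  }
  cfg$solver <- match.arg(cfg$solver, .rc_solvers)
  cfg
}

#' Write a moment/summary table as CSV
#'
#' Plain CSV with a header row, UTF-8, LF line endings, deterministic column
#' order, and floating-point columns formatted with 17 significant digits so
#' that read-back reproduces the in-memory doubles exactly.
#'
#' @param tab A data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_moments(data.frame(t = c(0, 0.1), mean = c(0.5, pi)), f)
#' read_moments(f)$mean[2] == pi
#' @export
write_moments <- function(tab, path) {
  stopifnot(is.data.frame(tab))
  cols <- lapply(tab, function(col) {
    if (is.numeric(col) && !is.integer(col)) sprintf("%.17g", col)
    else as.character(col)
  })
  header <- paste(names(tab), collapse = ",")
  body <- if (nrow(tab)) do.call(paste, c(cols, sep = ",")) else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read back a CSV written by [write_moments()]
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_moments <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

# Execute a single run described by a run_config; used by the CLI `solve` verb
# and by the presets.
.dispatch_run <- function(cfg) {
  params <- pop_params(a0 = cfg$a0, eps = cfg$eps, x0 = cfg$x0, lam = cfg$lam,
                       a1 = cfg$a1)
  grid <- time_grid(dt = cfg$dt, t_end = cfg$t_end)
  need_seed <- cfg$solver %in% c("em", "exact_path", "nested_mc")
  if (need_seed && is.na(cfg$seed))
    stop("this solver samples: an explicit 'seed' is required in the configuration")
  switch(cfg$solver,
    whe = whe_solve(params, grid),
    gpc_whe = gpc_whe_solve(params, grid, P = cfg$P, system = cfg$system,
                            a1_convention = cfg$a1_convention),
    gpc_whe_gaussian_only = gpc_whe_solve(params, grid, P = cfg$P,
                                          system = cfg$system,
                                          gaussian_only = TRUE,
                                          a1_convention = cfg$a1_convention),
    em = em_paths(params, grid,
                  mc_config(cfg$n_paths, seed = cfg$seed, dt_mc = cfg$dt_mc)),
    exact_path = exact_path_samples(params, grid,
                                    mc_config(cfg$n_paths, seed = cfg$seed,
                                              dt_mc = cfg$dt_mc,
                                              scheme = "exact_path")),
    nested_mc = nested_mc(params, grid,
                          mc_config(cfg$n_paths, seed = cfg$seed,
                                    dt_mc = cfg$dt_mc,
                                    n_param_draws = cfg$n_param_draws),
                          a1_convention = cfg$a1_convention))
}

.write_manifest <- function(cfg, path, elapsed = NA_real_) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- vapply(names(cfg), function(nm) paste(nm, "=", .fmt_val(cfg[[nm]])),
                  character(1))
  meta <- c(
    paste("meta.package_version =",
          as.character(utils::packageVersion("stochpop"))),
    paste("meta.r_version =", R.version.string),
    paste("meta.elapsed_sec =", .fmt_val(as.numeric(elapsed))))
  writeLines(c(lines, meta), path, useBytes = TRUE)
  invisible(path)
}

#' Execute a configured run and write its outputs
#'
#' Runs the solver described by `cfg`, writes `<tag>_moments.csv` (the full
#' moment table) and `<tag>_manifest.txt` (the expanded configuration plus
#' package/R versions and wall time; sufficient to reproduce the run exactly
#' via [read_run_config()]).
#'
#' @param cfg A [run_config()].
#' @param output_dir Output directory (created if missing).
#' @param tag File-name stem.
#' @return Invisibly, a list with `result` (the fit or moments object) and
#'   `files` (paths written).
#' @export
execute_run <- function(cfg, output_dir = cfg$output_dir, tag = "run") {
  t0 <- Sys.time()
  res <- .dispatch_run(cfg)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- if (inherits(res, "whe_fit")) res$moments else as.data.frame(res)
  csv <- file.path(output_dir, paste0(tag, "_moments.csv"))
  man <- file.path(output_dir, paste0(tag, "_manifest.txt"))
  write_moments(tab, csv)
  cfg$output_dir <- output_dir
  .write_manifest(cfg, man, elapsed = difftime(Sys.time(), t0, units = "secs"))
  invisible(list(result = res, files = c(moments = csv, manifest = man)))
}
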