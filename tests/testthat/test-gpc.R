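test_that("orthonormal Legendre basis: values and orthonormality by quadrature", {
  z <- c(-1, -0.3, 0, 0.5, 1)
  expect_equal(legendre_orthonormal(0, z), rep(1, 5))
  expect_equal(legendre_orthonormal(1, z), sqrt(3) * z)
  expect_equal(legendre_orthonormal(2, 1), sqrt(5))
  expect_equal(legendre_orthonormal(2, 0.5), sqrt(5) * (3 * 0.25 - 1) / 2)

  gq <- pracma::gaussLegendre(16, -1, 1)
  for (i in 0:3) for (j in 0:3) {
    inner <- sum(gq$w * legendre_orthonormal(i, gq$x) *
                   legendre_orthonormal(j, gq$x)) / 2
    expect_equal(inner, as.numeric(i == j), tolerance = 1e-12)
  }
  expect_error(legendre_orthonormal(1, 1.5), "\\[-1, 1\\]")
})

test_that("triple-product table: known entries, symmetry, orthonormality slice", {
  cc <- triple_product_table(3)
  expect_equal(cc[1, 2, 2], 1)                 # c_011 = 1
  expect_equal(cc[2, 2, 2], 0)                 # c_111 = 0 (odd symmetry)
  expect_equal(cc[2, 2, 3], 2 / sqrt(5))       # c_112
  # permutation symmetry
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expect_equal(cc[i, j, k], cc[j, i, k])
    expect_equal(cc[i, j, k], cc[k, j, i])
  }
  # c_0jk = delta_jk
  expect_equal(cc[1, , ], diag(4))
  b <- gpc_basis(2)
  expect_identical(b$order, 2L)
  expect_equal(b$triple_products, triple_product_table(2))
})

test_that("a deterministic growth rate decouples the coupled system to pure WHE", {
  w <- whe_std(0.02)
  g <- cached("gpc_0", gpc_whe_solve(std_params(lam = 0.02, a1 = 0), std_grid()))
  expect_lt(max(abs(w$moments$mean - g$moments$mean)), 1e-12)
  expect_lt(max(abs(w$moments$var_total - g$moments$var_total)), 1e-12)
  expect_identical(max(g$moments$var_par), 0)
  expect_identical(max(g$moments$var_mix), 0)
})

test_that("growth-rate representation has the stated mean and variance", {
  # a = a0 + a1 psi1(zeta), zeta ~ U(-1,1): E[a] = a0, Var[a] = a1^2,
  # i.e. a ~ U[a0 - sqrt(3) a1, a0 + sqrt(3) a1]
  set.seed(42)
  zeta <- runif(2e5, -1, 1)
  a <- 0.5 + 0.01 * legendre_orthonormal(1, zeta)
  expect_equal(mean(a), 0.5, tolerance = 1e-4)
  expect_equal(var(a), 0.01^2, tolerance = 0.02)
  expect_equal(range(a), c(0.5 - sqrt(3) * 0.01, 0.5 + sqrt(3) * 0.01),
               tolerance = 1e-3)
  # the half-width convention rescales the internal coefficient by 1/sqrt(3)
  p <- std_params(lam = 0.02, a1 = 0.01)
  g <- time_grid(0.05, t_end = 1)
  f1 <- gpc_whe_solve(p, g, a1_convention = "coefficient")
  f2 <- gpc_whe_solve(p, g, a1_convention = "half_width")
  expect_equal(f1$a1_coefficient, 0.01)
  expect_equal(f2$a1_coefficient, 0.01 / sqrt(3))
})

test_that("coupled solver agrees with nested Monte Carlo at steady state", {
  fit <- gpc_std(0.01)
  nm <- nested_mc(std_params(lam = 0.02, a1 = 0.01), std_grid(),
                  mc_config(500, seed = 11, dt_mc = 0.02, n_param_draws = 200))
  fin <- nm[nrow(nm), ]
  nd <- 200
  se_between <- fin$var_between * sqrt(2 / (nd - 1))
  se_within <- fin$var_within * sqrt(2 / (nd * 500))
  se_mean <- sqrt(fin$var_between / nd + fin$var_within / (nd * 500))
  expect_lt(abs(fit$steady_state$var_total - fin$variance),
            3 * (se_between + se_within))
  expect_lt(abs(fit$steady_state$mean - fin$mean), 4 * se_mean + 0.05)
  # law-of-total-variance split identifies the parameter component
  expect_lt(abs(fit$steady_state$var_par - fin$var_between), 3 * se_between)
})

test_that("gaussian-only flag drops second-order kernels and matches the reduced system", {
  p <- std_params(lam = 0.02, a1 = 0.01)
  g <- std_grid()
  fgo <- gpc_whe_solve(p, g, gaussian_only = TRUE, keep_kernels = TRUE)
  expect_null(fgo$kernels$x2_final)
  expect_identical(max(fgo$moments$var_nongaussian), 0)
  full <- gpc_std(0.01)
  # the nonGaussian contribution is small here, so the reduced system tracks
  # the full one closely
  expect_equal(fgo$steady_state$var_total, full$steady_state$var_total,
               tolerance = 0.01)
})

test_that("exact Galerkin assembly differs from the tabulated system by one damping term", {
  p <- std_params(lam = 0.02, a1 = 0.01)
  gal <- cached("gal_0.01", gpc_whe_solve(p, std_grid(), system = "galerkin"))
  ref <- gpc_std(0.01)
  # exact projection leaves the noise kernels undamped by the parameter
  # uncertainty: its noise component matches the deterministic-rate value
  noise0 <- whe_std(0.02)$steady_state$var_total
  expect_equal(gal$steady_state$var_noise, noise0, tolerance = 0.005)
  # the tabulated variant damps the noise component through 2 eps x1^(0)
  expect_lt(ref$steady_state$var_noise, gal$steady_state$var_noise)
  # both carry the same parameter component to first order
  expect_equal(ref$steady_state$var_par, gal$steady_state$var_par,
               tolerance = 0.01)
  expect_error(gpc_whe_solve(p, std_grid(), P = 2), "hard-coded P = 1")
})

test_that("generic Galerkin assembler runs at higher chaos order and decouples", {
  p <- std_params(lam = 0.02, a1 = 0.01)
  g <- time_grid(0.05, t_end = 5)
  f2 <- gpc_whe_solve(p, g, P = 2, system = "galerkin")
  expect_true(all(is.finite(f2$moments$var_total)))
  f1 <- gpc_whe_solve(p, g, P = 1, system = "galerkin")
  # the P = 2 correction to a uniformly distributed linear-in-zeta rate is small
  expect_equal(f2$moments$var_total, f1$moments$var_total, tolerance = 0.05)
  # with a1 = 0 every k >= 1 kernel stays exactly zero at any order
  f0 <- gpc_whe_solve(std_params(lam = 0.02, a1 = 0), g, P = 2,
                      system = "galerkin")
  expect_identical(max(f0$moments$var_par), 0)
  expect_identical(max(f0$moments$var_mix), 0)
})
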