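test_that("exact logistic solution: fixed point, limits, and closed form", {
  # starting at the carrying capacity the solution is constant
  p_at_L <- pop_params(a0 = 0.5, eps = 0.01, x0 = 50)
  expect_equal(exact_logistic(p_at_L, c(0, 1, 10, 100)), rep(50, 4))

  # sigmoid growth to L for a0 > 0, decay to 0 for a0 < 0
  p <- pop_params(a0 = 0.5, eps = 0.01, x0 = 0.5)
  expect_equal(exact_logistic(p, 0), 0.5)
  expect_equal(exact_logistic(p, 80), carrying_capacity(p), tolerance = 1e-12)
  pneg <- pop_params(a0 = -0.3, eps = 0.01, x0 = 5)
  expect_lt(exact_logistic(pneg, 60), 1e-6)

  expect_error(exact_logistic(pop_params(0, 0.01, 1), 1), "degenerate")
  expect_error(exact_logistic(p, -1), ">= 0")
})

test_that("exact logistic matches an adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  p <- pop_params(a0 = 0.5, eps = 0.01, x0 = 0.5)
  rhs <- function(t, y, parms) list(p$a0 * y - p$eps * y^2)
  sol <- deSolve::ode(y = p$x0, times = c(0, 5, 20), func = rhs, parms = NULL,
                      rtol = 1e-11, atol = 1e-12)
  expect_equal(exact_logistic(p, c(5, 20)), unname(sol[2:3, 2]),
               tolerance = 1e-8)
})

test_that("exact logistic is monotone on either side of the carrying capacity", {
  tt <- seq(0, 30, by = 0.5)
  for (a0 in c(0.2, 0.5, 1)) for (eps in c(0.005, 0.02)) {
    L <- a0 / eps
    below <- exact_logistic(pop_params(a0, eps, 0.1 * L), tt)
    above <- exact_logistic(pop_params(a0, eps, 3 * L), tt)
    expect_true(all(diff(below) > 0))
    expect_true(all(diff(above) < 0))
  }
})

test_that("exact logistic satisfies the ODE residual by finite differences", {
  p <- pop_params(a0 = 0.5, eps = 0.01, x0 = 0.5)
  h <- 1e-4
  tt <- seq(1, 30, by = 1)
  dX <- (exact_logistic(p, tt + h) - exact_logistic(p, tt - h)) / (2 * h)
  X <- exact_logistic(p, tt)
  expect_lt(max(abs(dX - p$a0 * X + p$eps * X^2)), 1e-8)
})

test_that("Richards model reduces to the logistic at beta = 2 and keeps its plateau", {
  p <- pop_params(a0 = 0.5, eps = 0.01, x0 = 0.5)
  tt <- c(0, 3, 10, 40)
  expect_equal(exact_richards(p, beta = 2, tt, "capacity"), exact_logistic(p, tt))
  expect_equal(exact_richards(p, beta = 2, tt, "loss"), exact_logistic(p, tt))
  # capacity parameterization: the allometric exponent shapes the transient
  # but leaves the steady state at L
  for (b in c(1.5, 3, 4))
    expect_equal(exact_richards(p, beta = b, 120, "capacity"),
                 carrying_capacity(p), tolerance = 1e-9)
  expect_error(exact_richards(p, beta = 1, 1), "degenerate")
})

test_that("Richards loss form matches numeric integration of dX/dt = aX - eps X^beta", {
  skip_if_not_installed("deSolve")
  p <- pop_params(a0 = 0.5, eps = 0.01, x0 = 0.5)
  for (b in c(1.5, 3)) {
    rhs <- function(t, y, parms) list(p$a0 * y - p$eps * y^b)
    sol <- deSolve::ode(y = p$x0, times = c(0, 10), func = rhs, parms = NULL,
                        rtol = 1e-11, atol = 1e-12)
    expect_equal(exact_richards(p, beta = b, 10, "loss"), unname(sol[2, 2]),
                 tolerance = 1e-8)
  }
})

test_that("stationary gamma moments match the closed form and its limits", {
  m1 <- stationary_gamma_moments(pop_params(0.5, 0.01, 0.5, lam = 0.01))
  expect_equal(m1$mean, 49.995)
  expect_equal(m1$variance, 0.249975)
  m2 <- stationary_gamma_moments(pop_params(0.5, 0.01, 0.5, lam = 0.02))
  expect_equal(m2$mean, 49.98)
  expect_equal(m2$variance, 0.9996)

  # deterministic limit: mean -> L, variance -> 0 (variance ~ a0 lam^2 / (2 eps^2))
  m3 <- stationary_gamma_moments(pop_params(0.5, 0.01, 0.5, lam = 1e-6))
  expect_equal(m3$mean, 50, tolerance = 1e-9)
  expect_lt(m3$variance, 1e-8)
  expect_equal(m3$variance, 0.5 * 1e-12 / (2 * 0.01^2), tolerance = 1e-5)

  # mean identity a0/eps - lam^2/(2 eps) over a parameter sweep
  for (a0 in c(0.3, 0.5, 1)) for (lam in c(0.01, 0.05)) for (eps in c(0.005, 0.02)) {
    m <- stationary_gamma_moments(pop_params(a0, eps, 1, lam = lam))
    expect_equal(m$mean, a0 / eps - lam^2 / (2 * eps), tolerance = 1e-12)
  }

  expect_error(stationary_gamma_moments(pop_params(1e-4, 0.01, 0.5, lam = 0.02)),
               "no stationary gamma")
  expect_error(stationary_gamma_moments(pop_params(0.5, 0.01, 0.5, lam = 0.01,
                                                   a1 = 0.01)),
               "a1 = 0")
})

test_that("regime classification compares a0 with lam^2/2 exactly", {
  expect_identical(growth_regime(pop_params(0.5, 0.01, 1, lam = 0.02)), "persistent")
  expect_identical(growth_regime(pop_params(1e-4, 0.01, 1, lam = 0.02)), "extinction")
  expect_identical(growth_regime(pop_params(2e-4, 0.01, 1, lam = 0.02)), "transition")
})

test_that("linear-model moments: exact GBM formulas and Monte Carlo oracle", {
  m0 <- linear_model_moments(a = 0.5, lam = 0, x0 = 1, t = 2)
  expect_equal(m0$mean, exp(1))
  expect_identical(m0$variance, 0)

  m1 <- linear_model_moments(a = 0.5, lam = 0.1, x0 = 1, t = 1)
  expect_equal(m1$mean, exp(0.5))

  # sample variance of exact GBM draws within 3 standard errors
  set.seed(202601)
  n <- 1e6
  x <- exp((0.5 - 0.1^2 / 2) + 0.1 * rnorm(n))
  v <- var(x)
  se <- sqrt((mean((x - mean(x))^4) - v^2) / n)
  expect_lt(abs(m1$variance - v), 3 * se)
})

test_that("linear-model variance follows the lam^2 t series in the small-noise limit", {
  for (a in c(0.2, 0.5)) for (lam in c(0.005, 0.01)) for (t in c(1, 4, 8)) {
    l2t <- lam^2 * t
    if (l2t >= 1e-3) next
    v <- linear_model_moments(a, lam, 2, t)$variance
    series <- l2t * 4 * exp(2 * a * t)
    expect_lt(abs(v - series) / v, l2t)
  }
})

test_that("parameter container validates its invariants", {
  expect_error(pop_params(0.5, 0, 1), "eps")
  expect_error(pop_params(0.5, 0.01, -1), "x0")
  expect_error(pop_params(0.5, 0.01, 1, lam = -0.1), "lam")
  expect_error(pop_params(0.5, 0.01, 1, a1 = -0.1), "a1")
  expect_equal(carrying_capacity(pop_params(0.5, 0.01, 1)), 50)
})
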