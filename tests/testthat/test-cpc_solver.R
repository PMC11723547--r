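test_that("NSFD denominator satisfies its contract", {
  expect_equal(nsfd_denominator(0.01, "plain"), 0.01)
  expect_equal(nsfd_denominator(0.01, "expm1"), 1 - exp(-0.01))
  expect_equal(nsfd_denominator(0.01, "expm1"), 0.00995017, tolerance = 1e-6)
  expect_error(nsfd_denominator(1, "plain"), class = "pwfrac_contract_violation")
  expect_error(nsfd_denominator(-0.1, "plain"), class = "pwfrac_domain_error")
  # Pi(dt) = dt + O(dt^2): relative deviation vanishes with dt
  for (kind in c("plain", "expm1")) {
    dt <- 1e-6
    expect_lt(abs(nsfd_denominator(dt, kind) - dt) / dt, 1e-5)
  }
})

test_that("CPC kernels reduce to the classical derivative at theta = 1, Q = 1", {
  k <- cpc_kernels(1, 1)
  expect_identical(k$V0, 1)
  expect_identical(k$V1, 0)
  k <- cpc_kernels(0.5, 2)
  expect_equal(k$V0, 0.5 * 2^0.5)
  expect_equal(k$V1, 0.5 * 2^0.5)
  expect_error(cpc_kernels(1.5), class = "pwfrac_domain_error")
})

test_that("theta = 1 scalar solve is bit-identical to explicit Euler", {
  dt <- 0.01
  N <- 100
  tr <- solve_cpc_scalar(-1, 1, t_end = 1, dt = dt, theta = 1)
  expect_identical(tr$x, euler_relax(-1, 1, dt, N))
})

test_that("classical-limit error against exp(-t) decays at first order", {
  errs <- sapply(c(0.01, 0.005, 0.0025), function(dt) {
    tr <- solve_cpc_scalar(-1, 1, t_end = 1, dt = dt, theta = 1)
    abs(tr$x[nrow(tr)] - exp(-1))
  })
  order_emp <- -coef(lm(log(errs) ~ log(1 / c(0.01, 0.005, 0.0025))))[2]
  expect_true(abs(order_emp - 1) < 0.15)
})

test_that("one-step update matches the hand-expanded n = 0 formula", {
  th <- 0.7; Q <- 1.3; lam <- 1.1; dt <- 0.01; x0 <- 2; nu <- -0.8
  Pi <- dt
  V0 <- th * Q^(1 - th); V1 <- (1 - th) * Q^th
  vp1 <- 1 - th                    # varpi_1
  kp1 <- th                        # kappa_1
  r1 <- 1 / gamma(1 - th)          # r_1
  f0 <- nu * x0
  x1_hand <- (lam^(1 - th) * Pi^th * f0 - V1 * Pi * vp1 * x0 +
                V0 * (kp1 * x0 + r1 * x0)) / (V1 * Pi + V0)
  w <- gl_weights(th, 5)
  expect_equal(cpc_step(x0, w, th, Pi, f0, Q, lam), x1_hand,
               tolerance = 1e-14)
  tr <- solve_cpc_scalar(nu, x0, t_end = 0.05, dt = dt, theta = th,
                         Q = Q, lambda = lam)
  expect_equal(tr$x[2], x1_hand, tolerance = 1e-14)
})

test_that("scalar fractional relaxation is positive and non-increasing", {
  for (th in c(0.5, 0.9, 0.99)) {
    tr <- solve_cpc_scalar(-1, 1, t_end = 5, dt = 0.01, theta = th)
    expect_true(all(tr$x > 0))
    expect_true(all(diff(tr$x) <= 0))
  }
})

test_that("constant order-function solve reproduces the constant-order solve", {
  p <- table1_params
  tr_c <- solve_constant_order(p, y0_bench, 0, 2, 0.01, theta = 0.9)
  tr_v <- solve_variable_order(p, y0_bench, 0, 2, 0.01,
                               theta_fn = function(t) rep(0.9, length(t)),
                               drift_eval = "explicit")
  expect_equal(as.matrix(tr_v[, c("X", "B", "C", "R", "E")]),
               as.matrix(tr_c[, c("X", "B", "C", "R", "E")]),
               tolerance = 1e-12)
})

test_that("deterministic solves are bit-reproducible", {
  p <- table1_params
  a <- solve_constant_order(p, y0_bench, 0, 1, 0.01, theta = 0.95)
  b <- solve_constant_order(p, y0_bench, 0, 1, 0.01, theta = 0.95)
  expect_identical(a, b)
  thf <- order_function("0.01 - 0.001*cos(t)")
  a <- solve_variable_order(p, y0_bench, 0, 1, 0.01, thf)
  b <- solve_variable_order(p, y0_bench, 0, 1, 0.01, thf)
  expect_identical(a, b)
})

test_that("restarting from a truncated history reproduces the continuation", {
  p <- table1_params
  A <- drift_matrix(p); b <- inflow_vector(p)
  full <- pwfrac:::.cpc_engine(A, b, y0_bench, 0, 1, 0.01, 0.9)
  k <- 40
  restart <- pwfrac:::.cpc_engine(A, b, y0_bench, 0, 1, 0.01, 0.9,
                                  history = full$states[, 1:(k + 1)])
  expect_identical(restart$states, full$states)
})

test_that("theta = 1 five-compartment solve converges to the classical solution", {
  skip_if_not_installed("deSolve")
  p <- table1_params
  A <- drift_matrix(p); b <- inflow_vector(p)
  ref <- deSolve::ode(y = y0_bench, times = c(0, 1),
                      func = function(t, y, parms) list(drop(b + A %*% y)),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-8)
  yref <- ref[2, 1 + 1:5]
  errs <- sapply(c(0.02, 0.01, 0.005), function(dt) {
    tr <- solve_constant_order(p, y0_bench, 0, 1, dt, theta = 1)
    max(abs(unlist(tr[nrow(tr), c("X", "B", "C", "R", "E")]) - yref))
  })
  # halving dt roughly halves the error (first-order scheme)
  expect_true(all(errs[-3] / errs[-1] > 1.6 & errs[-3] / errs[-1] < 2.4))
})

test_that("explicit drift evaluation diverges for tiny variable orders", {
  # the integral-dominated regime amplifies the drift by ~ Pi^theta/(V1 Pi + V0);
  # this documents why the variable-order default is implicit
  p <- table1_params
  expect_error(
    solve_variable_order(p, y0_bench, 30, 60, 0.01,
                         theta_fn = order_function("0.01 - 0.001*cos(t)"),
                         drift_eval = "explicit"),
    class = "pwfrac_divergence")
})

test_that("order functions leaving (0,1) are rejected with the offending time", {
  p <- table1_params
  expect_error(
    solve_variable_order(p, y0_bench, 0, 2, 0.01,
                         theta_fn = function(t) 1.5 - t),
    regexp = "t = ", class = "pwfrac_domain_error")
})

test_that("order-function expressions parse and carry their spec", {
  f <- order_function("0.01 - 0.001*cos(t)")
  expect_equal(f(0), 0.009)
  expect_equal(f(pi), 0.011)
  expect_identical(attr(f, "spec"), "0.01 - 0.001*cos(t)")
})
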