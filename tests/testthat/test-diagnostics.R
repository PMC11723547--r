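test_that("Lipschitz matrix matches the printed rate sums entrywise", {
  Th <- lipschitz_matrix(table1_params)
  hand <- rbind(
    c(0.03 + 0.01, 0, 0, 0, 0),                       # gamma1 + mu1 (as printed)
    c(0.01, 0.03 + 0.01 + 0.03 + 0.0256, 0, 0.03, 0),
    c(0, 0.01, 0.03 + 0.4 + 0.0256, 0.3, 0),
    c(0.03, 0.03, 0.03, 0.03 + 0.3 + 0.0256, 0),      # sigma3 (as printed)
    c(0, 0.03, 0.4, 0.01, 0.0256))
  expect_equal(unname(Th), hand)
  expect_equal(Th["B", "X"], 0.01)
  expect_equal(Th["R", "R"], 0.3556)
  expect_equal(unname(Th[1, 2:5]), rep(0, 4))
})

test_that("zero parameters give the zero matrix and zero bound", {
  p0 <- bc_params(omega1 = 0, omega2 = 0, omega3 = 0, gamma1 = 0,
                  gamma2 = 0, gamma3 = 0, mu1 = 0, mu2 = 0, alpha1 = 0,
                  alpha2 = 0, phi1 = 0, phi2 = 0, phi3 = 0, sigma1 = 0,
                  sigma2 = 0, sigma3 = 0)
  expect_equal(unname(lipschitz_matrix(p0)), matrix(0, 5, 5))
  expect_equal(lyapunov_bound(p0, rep(0, 5)), 0)
  expect_equal(as.numeric(contraction_factor(p0, 0.9)), 0)
})

test_that("Lipschitz matrix is entrywise monotone in each parameter", {
  base <- lipschitz_matrix(table1_params)
  for (nm in names(table1_params)) {
    p <- table1_params
    p[[nm]] <- p[[nm]] + 0.1
    expect_true(all(lipschitz_matrix(p) >= base - 1e-15), label = nm)
  }
})

test_that("Lyapunov bound matches the hand sum", {
  expect_equal(lyapunov_bound(table1_params, rep(0.1, 5)), 14160.9768,
               tolerance = 1e-9)
  # the printed bound uses four noise channels; the fifth is optional
  expect_equal(lyapunov_bound(table1_params, rep(0.1, 5), five_term = TRUE),
               14160.9768 + 0.005, tolerance = 1e-9)
  # state-independence is structural: no state argument exists
  expect_gte(lyapunov_bound(table1_params), 0)
})

test_that("contraction factor agrees with a power-iteration oracle", {
  Th <- lipschitz_matrix(table1_params)
  for (th in c(0.3, 0.9)) {
    V0 <- cpc_kernels(th)$V0
    got <- contraction_factor(Th, th, gamma_mode = "unit")
    expect_equal(as.numeric(got), power_iteration_rho(Th) / abs(V0),
                 tolerance = 1e-9)
  }
  set.seed(8)
  for (k in 1:5) {
    M <- matrix(runif(25), 5, 5)
    got <- contraction_factor(M, 0.8, gamma_mode = "unit")
    expect_equal(as.numeric(got),
                 power_iteration_rho(M) / abs(cpc_kernels(0.8)$V0),
                 tolerance = 1e-9)
  }
})

test_that("contraction factor is linear in the bound constants", {
  Th <- lipschitz_matrix(table1_params)
  a <- as.numeric(contraction_factor(Th, 0.9, psi_max = 1))
  b <- as.numeric(contraction_factor(Th, 0.9, psi_max = 2))
  expect_equal(b, 2 * a, tolerance = 1e-12)
})

test_that("the gamma factor uses |Gamma(theta - 1)|", {
  Th <- lipschitz_matrix(table1_params)
  th <- 0.9
  a <- as.numeric(contraction_factor(Th, th, gamma_mode = "abs"))
  b <- as.numeric(contraction_factor(Th, th, gamma_mode = "unit"))
  expect_equal(a / b, abs(gamma(th - 1)), tolerance = 1e-12)
  expect_gt(a, 0)
})

test_that("diagnostics report assembles all certificates", {
  rep_ <- diagnostics_report(table1_params, theta = 0.99)
  expect_s3_class(rep_, "pwfrac_diagnostics")
  expect_equal(rep_$lyapunov_bound, 14160.9768, tolerance = 1e-9)
  expect_equal(rep_$lipschitz_matrix, lipschitz_matrix(table1_params))
  expect_output(print(rep_), "Lyapunov")
})
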