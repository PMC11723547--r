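# Independent oracles used across the suite.  All are deliberately naive:
# direct gamma-function evaluations, power iteration, explicit loops.

# GL binomial weights of order theta-1 via gamma functions:
# varpi_i = (-1)^i * C(theta - 1, i)
varpi_gamma_oracle <- function(theta, i) {
  (-1)^i * gamma(theta) / (gamma(i + 1) * gamma(theta - i))
}

# Signed binomial of order theta: kappa_i = (-1)^(i-1) * C(theta, i)
kappa_gamma_oracle <- function(theta, i) {
  (-1)^(i - 1) * gamma(theta + 1) / (gamma(i + 1) * gamma(theta - i + 1))
}

# Spectral radius of a nonnegative matrix by power iteration.
power_iteration_rho <- function(M, iters = 2000, tol = 1e-14) {
  v <- rep(1, nrow(M))
  rho <- 0
  for (k in seq_len(iters)) {
    w <- M %*% v
    nr <- sqrt(sum(w^2))
    if (nr == 0) return(0)
    v_new <- w / nr
    if (max(abs(v_new - v)) < tol && k > 5) {
      v <- v_new
      break
    }
    v <- v_new
  }
  drop(crossprod(v, M %*% v)) / drop(crossprod(v, v))
}

# Explicit Euler on the scalar relaxation dx/dt = nu * x.
euler_relax <- function(nu, x0, dt, N) {
  x <- numeric(N + 1)
  x[1] <- x0
  for (n in seq_len(N)) x[n + 1] <- x[n] + dt * (nu * x[n])
  x
}

# Explicit Euler on the 5-compartment model.
euler_model <- function(params, y0, dt, N) {
  A <- drift_matrix(params)
  b <- inflow_vector(params)
  S <- matrix(0, 5, N + 1)
  S[, 1] <- y0
  for (n in seq_len(N)) {
    x <- S[, n]
    S[, n + 1] <- x + dt * drop(b + A %*% x)
  }
  S
}

table1_params <- bc_params()
y0_bench <- c(X = 30000, B = 12300, C = 738, R = 334, E = 10)
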