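#' Lipschitz matrix of the model operator
#'
#' The componentwise Lipschitz bound of the drift operator, as a 5x5
#' nonnegative matrix of rate sums.  The matrix is reproduced verbatim
#' from the source analysis, including its two entries that differ from
#' the dynamics of the model equations: the (1,1) entry is
#' `gamma1 + mu1` (the `X` equation itself carries `gamma1 + mu2`) and the
#' (4,4) entry is `alpha1 + alpha2 + sigma3` (the `R` equation carries
#' `alpha1 + alpha2 + phi3`).  Both discrepancies are kept as printed so
#' the certificate matches the published bound; they are documented here
#' and in the methods vignette.
#'
#' @param params A [bc_params()] object.
#' @return A 5x5 nonnegative matrix with `X,B,C,R,E` dimnames.
#' @export
lipschitz_matrix <- function(params) {
  p <- params
  Theta <- matrix(0, 5, 5, dimnames = list(compartments, compartments))
  Theta[1, 1] <- p$gamma1 + p$mu1
  Theta[2, ] <- c(p$mu2, p$gamma2 + p$mu1 + p$phi1 + p$sigma1, 0, p$alpha1, 0)
  Theta[3, ] <- c(0, p$mu1, p$gamma3 + p$phi2 + p$sigma2, p$alpha2, 0)
  Theta[4, ] <- c(p$gamma1, p$gamma2, p$gamma3,
                  p$alpha1 + p$alpha2 + p$sigma3, 0)
  Theta[5, ] <- c(0, p$phi1, p$phi2, p$phi3, p$sigma3)
  Theta
}

#' Contraction factor of the fixed-point certificate
#'
#' Computes the spectral radius of the scaled Lipschitz matrix
#' `lambda^{1-theta} Psi_max Phi_max |Gamma(theta - 1)| / |V0(theta)| *
#' Theta`.  The unique-solution certificate holds when the returned value
#' is below one.  Conventions: `Gamma(theta - 1)` is negative for `theta`
#' in `(0, 1)`, so its absolute value is used (a contraction scale must be
#' nonnegative); `Psi_max` and `Phi_max` are bound constants left
#' unspecified by the source analysis and default to one.
#'
#' @param Theta A 5x5 Lipschitz matrix (from [lipschitz_matrix()]) or a
#'   [bc_params()] object (converted automatically).
#' @param theta Fractional order in `(0, 1)`.
#' @param lambda,Q CPC prefactor and kernel constant.
#' @param psi_max,phi_max Bound constants of the certificate (default 1).
#' @param gamma_mode `"abs"` uses `|Gamma(theta - 1)|`; `"unit"` suppresses
#'   the gamma factor (prefactor `1/|V0|` at unit constants).
#' @return The spectral radius of the scaled matrix, with the scalar
#'   prefactor in attribute `"prefactor"` and the certificate verdict in
#'   attribute `"contractive"`.
#' @export
contraction_factor <- function(Theta, theta, lambda = 1, Q = 1,
                               psi_max = 1, phi_max = 1,
                               gamma_mode = c("abs", "unit")) {
  gamma_mode <- match.arg(gamma_mode)
  if (inherits(Theta, "bc_params")) Theta <- lipschitz_matrix(Theta)
  check_scalar(theta, "theta", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  V0 <- cpc_kernels(theta, Q)$V0
  gam <- if (gamma_mode == "abs") abs(gamma(theta - 1)) else 1
  if (!is.finite(gam))
    stop_pwfrac("gamma factor undefined for this order", "pwfrac_domain_error")
  pref <- lambda^(1 - theta) * psi_max * phi_max * gam / abs(V0)
  rho <- max(abs(eigen(Theta, only.values = TRUE)$values))
  structure(pref * rho, prefactor = pref, contractive = (pref * rho) < 1)
}

#' Lyapunov drift bound of the stochastic system
#'
#' The state-independent constant bounding the generator of the stochastic
#' system's log-Lyapunov function: the sum of all sixteen model rates plus
#' half the sum of squared noise intensities.  As printed, the bound's
#' noise sum covers only the first four channels; `five_term = TRUE`
#' includes the fifth.
#'
#' @param params A [bc_params()] object.
#' @param intensities Numeric length-5 noise intensities.
#' @param five_term Include the fifth noise channel in the quadratic sum.
#' @return The nonnegative bound.
#' @export
#' @examples
#' lyapunov_bound(bc_params(), rep(0.1, 5))  # 14160.9768
lyapunov_bound <- function(params, intensities = rep(0.1, 5),
                           five_term = FALSE) {
  p <- params
  rates <- p$omega1 + p$omega2 + p$omega3 +
    p$gamma1 + p$gamma2 + p$gamma3 +
    p$mu1 + p$mu2 +
    p$phi1 + p$phi2 + p$phi3 +
    p$sigma1 + p$sigma2 + p$sigma3 +
    p$alpha1 + p$alpha2
  k <- if (five_term) 5L else 4L
  rates + sum(intensities[seq_len(k)]^2) / 2
}

#' Analytic-certificate report
#'
#' Collects the Lipschitz matrix, the contraction factor at a given order,
#' and the stochastic Lyapunov bound into one structured report.
#'
#' @inheritParams contraction_factor
#' @param params A [bc_params()] object.
#' @param intensities Noise intensities for the Lyapunov bound.
#' @return A list of class `pwfrac_diagnostics` with elements
#'   `lipschitz_matrix`, `spectral_radius`, `contraction_factor`,
#'   `contractive`, `lyapunov_bound`, plus the conventions used.
#' @export
diagnostics_report <- function(params, theta = 0.99,
                               intensities = rep(0.1, 5),
                               lambda = 1, Q = 1,
                               psi_max = 1, phi_max = 1,
                               gamma_mode = "abs") {
  Theta <- lipschitz_matrix(params)
  cf <- contraction_factor(Theta, theta, lambda, Q, psi_max, phi_max,
                           gamma_mode)
  structure(list(
    lipschitz_matrix = Theta,
    spectral_radius = max(abs(eigen(Theta, only.values = TRUE)$values)),
    prefactor = attr(cf, "prefactor"),
    contraction_factor = as.numeric(cf),
    contractive = attr(cf, "contractive"),
    lyapunov_bound = lyapunov_bound(params, intensities),
    theta = theta,
    notes = c(
      "gamma factor |Gamma(theta-1)| used (absolute-value convention)",
      "Psi_max and Phi_max are unspecified bound constants, defaulting to 1",
      "Lyapunov noise sum uses the four-channel form as printed"
    )), class = "pwfrac_diagnostics")
}

#' @export
print.pwfrac_diagnostics <- function(x, ...) {
  cat("<pwfrac_diagnostics>\n")
  cat("Lipschitz matrix Theta:\n")
  print(x$lipschitz_matrix)
  cat(sprintf("spectral radius rho(Theta)   : %.6g\n", x$spectral_radius))
  cat(sprintf("prefactor (theta = %g)       : %.6g\n", x$theta, x$prefactor))
  cat(sprintf("contraction factor           : %.6g  (%s)\n",
              x$contraction_factor,
              if (x$contractive) "certificate holds" else "not contractive"))
  cat(sprintf("Lyapunov bound V-bar         : %.6f\n", x$lyapunov_bound))
  for (nt in x$notes) cat(" note:", nt, "\n")
  invisible(x)
}
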