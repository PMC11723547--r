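#' Model parameters for the five-compartment progression model
#'
#' Constructs the full rate-constant set of the compartmental model
#' \deqn{dX/dt = \omega_1 - (\gamma_1+\mu_2) X}
#' \deqn{dB/dt = \omega_2 + \mu_2 X + \alpha_1 R - (\gamma_2+\mu_1+\phi_1+\sigma_1) B}
#' \deqn{dC/dt = \omega_3 + \mu_1 B + \alpha_2 R - (\gamma_3+\phi_2+\sigma_2) C}
#' \deqn{dR/dt = \gamma_1 X + \gamma_2 B + \gamma_3 C - (\alpha_1+\alpha_2+\phi_3) R}
#' \deqn{dE/dt = \phi_3 R + \phi_2 C + \phi_1 B - \sigma_3 E}
#' where `X` counts hospitalised stage 1-2 patients, `B` stage 3A/3B, `C`
#' stage 4, `R` disease-free after chemotherapy, and `E` patients with
#' chemotherapy-induced cardiotoxicity.
#'
#' @param omega1,omega2,omega3 Recruitment inflows into `X`, `B`, `C`
#'   (persons per time unit).
#' @param gamma1,gamma2,gamma3 Transfer rates `X`,`B`,`C` into `R`
#'   (per time unit).
#' @param mu1,mu2 Stage-progression rates `B -> C` and `X -> B`.
#' @param alpha1,alpha2 Relapse rates `R -> B` and `R -> C`.
#' @param phi1,phi2,phi3 Chemotherapy-associated transfer rates of `B`, `C`,
#'   `R` into the cardiotoxic class `E`.
#' @param sigma1,sigma2,sigma3 Mortality rates of `B`, `C`, `E`.
#'
#' Defaults are the published benchmark parameter table (see
#' [table1_values()] and [map_table1()]).
#'
#' @return An object of class `bc_params`: a named list of the 16 rates.
#' @seealso [drift()], [map_table1()], [x_equilibrium()]
#' @export
#' @examples
#' p <- bc_params()
#' drift(c(X = 30000, B = 12300, C = 738, R = 334, E = 10), p)
bc_params <- function(omega1 = 14000, omega2 = 80, omega3 = 80,
                      gamma1 = 0.03, gamma2 = 0.03, gamma3 = 0.03,
                      mu1 = 0.01, mu2 = 0.01,
                      alpha1 = 0.03, alpha2 = 0.3,
                      phi1 = 0.03, phi2 = 0.4, phi3 = 0.01,
                      sigma1 = 0.0256, sigma2 = 0.0256, sigma3 = 0.0256) {
  p <- list(omega1 = omega1, omega2 = omega2, omega3 = omega3,
            gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
            mu1 = mu1, mu2 = mu2,
            alpha1 = alpha1, alpha2 = alpha2,
            phi1 = phi1, phi2 = phi2, phi3 = phi3,
            sigma1 = sigma1, sigma2 = sigma2, sigma3 = sigma3)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop_pwfrac(sprintf("parameter '%s' must be a finite non-negative scalar", nm),
                  "pwfrac_invalid_input")
  }
  structure(p, class = "bc_params")
}

#' @export
print.bc_params <- function(x, ...) {
  cat("<bc_params> five-compartment progression model rates\n")
  print(unlist(x), ...)
  invisible(x)
}

#' Published benchmark parameter table
#'
#' The parameter table of the source benchmark, in its original symbols:
#' inflows `Lambda1..Lambda3`, chemotherapy recovery rates `phi1..phi3`,
#' stage-transmission rates `beta1`, `beta2`, cardiotoxicity rates
#' `gamma1..gamma3`, mortalities `mu1..mu3` and relapse rates `psi1`,
#' `psi2`.  Feed this to [map_table1()] to obtain the model's canonical
#' [bc_params()] rate names.
#'
#' @return A named numeric vector of the 16 table entries.
#' @export
table1_values <- function() {
  c(Lambda1 = 14000, Lambda2 = 80, Lambda3 = 80,
    phi1 = 0.03, phi2 = 0.4, phi3 = 0.01,
    beta1 = 0.01, beta2 = 0.01,
    gamma1 = 0.03, gamma2 = 0.03, gamma3 = 0.03,
    mu1 = 0.0256, mu2 = 0.0256, mu3 = 0.0256,
    psi1 = 0.03, psi2 = 0.3)
}

#' Map the published parameter table onto model rate names
#'
#' The benchmark table and the model equations use different symbol
#' families.  The canonical reconciliation is: `Lambda_i -> omega_i`
#' (inflows), `beta1 -> mu1` (progression `B -> C`), `beta2 -> mu2`
#' (progression `X -> B`), the table's mortalities `mu1..mu3 ->
#' sigma1..sigma3`, and the relapse rates `psi1 -> alpha1`, `psi2 ->
#' alpha2`.  The `gamma` and `phi` names coincide.
#'
#' @param tab Named numeric vector or list providing the 16 entries named as
#'   in [table1_values()].
#' @return A [bc_params()] object.
#' @export
#' @examples
#' identical(map_table1(table1_values()), bc_params())
map_table1 <- function(tab) {
  tab <- unlist(tab)
  needed <- names(table1_values())
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop_pwfrac(sprintf("parameter table is missing entries: %s",
                        paste(missing, collapse = ", ")),
                "pwfrac_config_error")
  bc_params(
    omega1 = tab[["Lambda1"]], omega2 = tab[["Lambda2"]], omega3 = tab[["Lambda3"]],
    phi1 = tab[["phi1"]], phi2 = tab[["phi2"]], phi3 = tab[["phi3"]],
    mu1 = tab[["beta1"]], mu2 = tab[["beta2"]],
    gamma1 = tab[["gamma1"]], gamma2 = tab[["gamma2"]], gamma3 = tab[["gamma3"]],
    sigma1 = tab[["mu1"]], sigma2 = tab[["mu2"]], sigma3 = tab[["mu3"]],
    alpha1 = tab[["psi1"]], alpha2 = tab[["psi2"]]
  )
}

compartments <- c("X", "B", "C", "R", "E")

#' Linear-system representation of the model drift
#'
#' The model is affine in the state: `f(y) = b + A y`.  `drift_matrix`
#' returns the 5x5 rate matrix `A`; `inflow_vector` the constant inflow `b`.
#'
#' @param params A [bc_params()] object.
#' @return `drift_matrix`: a 5x5 matrix with rows/columns named
#'   `X,B,C,R,E`; `inflow_vector`: a named length-5 vector.
#' @export
drift_matrix <- function(params) {
  p <- params
  A <- matrix(0, 5, 5, dimnames = list(compartments, compartments))
  A["X", "X"] <- -(p$gamma1 + p$mu2)
  A["B", "X"] <- p$mu2
  A["B", "B"] <- -(p$gamma2 + p$mu1 + p$phi1 + p$sigma1)
  A["B", "R"] <- p$alpha1
  A["C", "B"] <- p$mu1
  A["C", "C"] <- -(p$gamma3 + p$phi2 + p$sigma2)
  A["C", "R"] <- p$alpha2
  A["R", "X"] <- p$gamma1
  A["R", "B"] <- p$gamma2
  A["R", "C"] <- p$gamma3
  A["R", "R"] <- -(p$alpha1 + p$alpha2 + p$phi3)
  A["E", "B"] <- p$phi1
  A["E", "C"] <- p$phi2
  A["E", "R"] <- p$phi3
  A["E", "E"] <- -p$sigma3
  A
}

#' @rdname drift_matrix
#' @export
inflow_vector <- function(params) {
  c(X = params$omega1, B = params$omega2, C = params$omega3, R = 0, E = 0)
}

#' Deterministic drift of the five-compartment model
#'
#' Evaluates the right-hand side of the compartmental system at a state.
#'
#' @param state Numeric length-5 state `(X, B, C, R, E)` (persons).
#' @param params A [bc_params()] object.
#' @return Named numeric length-5 rate vector (persons per time unit).
#' @export
drift <- function(state, params) {
  if (!is.numeric(state) || length(state) != 5L || any(!is.finite(state)))
    stop_pwfrac("'state' must be a finite numeric vector of length 5",
                "pwfrac_invalid_input")
  setNames(drop(inflow_vector(params) + drift_matrix(params) %*% state),
           compartments)
}

#' Steady state of the decoupled X equation
#'
#' The `X` compartment obeys `dX/dt = omega1 - (gamma1 + mu2) X` on its own,
#' so it relaxes exponentially towards `omega1 / (gamma1 + mu2)`.
#'
#' @param params A [bc_params()] object.
#' @return The fixed point `omega1 / (gamma1 + mu2)`.
#' @export
#' @examples
#' x_equilibrium(bc_params())  # 350000
x_equilibrium <- function(params) {
  k <- params$gamma1 + params$mu2
  if (k <= 0)
    stop_pwfrac("gamma1 + mu2 must be positive for an X equilibrium",
                "pwfrac_degenerate_parameter")
  params$omega1 / k
}
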