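#' Grunwald-Letnikov weight sequences
#'
#' The nonstandard finite-difference scheme for the CPC operator expands the
#' Riemann-Liouville integral of order `1 - theta` and the Caputo derivative
#' of order `theta` into discrete convolutions over the full solution
#' history.  Three weight sequences appear:
#'
#' * `varpi`: GL binomial coefficients of order `theta - 1`,
#'   `varpi_0 = 1`, `varpi_i = (1 - theta/i) varpi_{i-1}` (all positive;
#'   these weight the history sum of the integral part);
#' * `kappa`: signed binomials of order `theta`,
#'   `kappa_1 = theta`, `kappa_{i+1} = kappa_i (i - theta)/(i + 1)`
#'   (positive, strictly decreasing for `theta` in (0,1));
#' * `r`: initial-value correction weights `r_i = i^{-theta} / Gamma(1 -
#'   theta)` that turn the Riemann-Liouville difference into a Caputo one.
#'
#' For a time-varying order, `theta` may be a numeric vector giving the
#' order at each grid index `i = 1..N`; the recurrences then use
#' `theta(t_i)` at index `i`, so a constant vector reproduces the
#' constant-order sequences bit for bit.
#'
#' @param theta Constant fractional order in `(0, 1]` (`gl_r` requires
#'   `(0, 1)`), or a numeric vector of length `N` of per-index orders.
#' @param N Number of weights (history length).
#' @return `gl_varpi`: numeric vector of length `N + 1` (`varpi_0 ..
#'   varpi_N`); `gl_kappa`, `gl_r`: numeric vectors of length `N`
#'   (`i = 1..N`).
#' @seealso [gl_weights()] for all three at once.
#' @export
#' @examples
#' gl_varpi(0.5, 2)   # 1, 0.5, 0.375
#' gl_kappa(0.5, 2)   # 0.5, 0.125
#' gl_r(0.5, 1)       # 1/sqrt(pi)
gl_varpi <- function(theta, N) {
  th <- check_order_vector(theta, N, upper_closed = TRUE)
  if (N < 0) stop_pwfrac("'N' must be >= 0", "pwfrac_invalid_input")
  vp <- numeric(N + 1)
  vp[1] <- 1
  if (N >= 1) for (i in seq_len(N)) vp[i + 1] <- (1 - th[i] / i) * vp[i]
  vp
}

#' @rdname gl_varpi
#' @export
gl_kappa <- function(theta, N) {
  th <- check_order_vector(theta, N, upper_closed = TRUE)
  if (N < 1) stop_pwfrac("'N' must be >= 1", "pwfrac_invalid_input")
  kp <- numeric(N)
  kp[1] <- th[1]
  if (N >= 2) for (i in seq_len(N - 1)) kp[i + 1] <- kp[i] * (i - th[i + 1]) / (i + 1)
  kp
}

#' @rdname gl_varpi
#' @export
gl_r <- function(theta, N) {
  th <- check_order_vector(theta, N, upper_closed = FALSE)
  if (N < 1) stop_pwfrac("'N' must be >= 1", "pwfrac_invalid_input")
  i <- seq_len(N)
  i^(-th) / gamma(1 - th)
}

check_order_vector <- function(theta, N, upper_closed) {
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop_pwfrac("fractional order must be finite numeric", "pwfrac_invalid_input")
  if (!(length(theta) %in% c(1L, max(N, 1L))))
    stop_pwfrac("order vector length must be 1 or N", "pwfrac_invalid_input")
  hi_ok <- if (upper_closed) all(theta <= 1) else all(theta < 1)
  if (!all(theta > 0) || !hi_ok)
    stop_pwfrac(sprintf("fractional order must lie in (0, 1%s)",
                        if (upper_closed) "]" else ")"),
                "pwfrac_domain_error")
  rep_len(theta, max(N, 1L))
}

#' Full Grunwald-Letnikov weight table
#'
#' Computes all three weight sequences used by the CPC solver.  At the
#' classical limit `theta = 1` the `r` weights are identically zero (the
#' initial-value correction vanishes in the limit, avoiding the
#' `Gamma(0)` pole), matching the scheme's reduction to explicit Euler.
#'
#' @inheritParams gl_varpi
#' @return A list of class `gl_weights` with elements `varpi` (length
#'   `N + 1`), `kappa`, `r` (length `N`), `theta`, `N`.
#' @export
gl_weights <- function(theta, N) {
  th <- check_order_vector(theta, N, upper_closed = TRUE)
  r <- numeric(N)
  frac <- th < 1
  if (any(frac)) {
    i <- seq_len(N)
    r[frac] <- (i[frac])^(-th[frac]) / gamma(1 - th[frac])
  }
  structure(list(varpi = gl_varpi(th, N), kappa = gl_kappa(th, N),
                 r = r, theta = th, N = N),
            class = "gl_weights")
}

#' @export
print.gl_weights <- function(x, ...) {
  cat(sprintf("<gl_weights> N = %d, order %s\n", x$N,
              if (length(unique(x$theta)) == 1L)
                sprintf("theta = %g", x$theta[1]) else "theta(t) variable"))
  invisible(x)
}

#' @export
as.data.frame.gl_weights <- function(x, ...) {
  data.frame(i = seq_len(x$N), varpi = x$varpi[-1], kappa = x$kappa, r = x$r)
}
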