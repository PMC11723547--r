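#' Fractional Gaussian noise / fBm increments
#'
#' Generates `n` increments of fractional Brownian motion with Hurst index
#' `H` over steps of length `dt`: a stationary Gaussian sequence with mean
#' zero, variance `dt^{2H}`, and lag-k autocorrelation
#' `0.5 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})` (so `2^{2H-1} - 1` at lag
#' one).  Sampling uses circulant embedding of the exact covariance
#' (Davies-Harte): the embedding of the fGn autocovariance is nonnegative
#' definite for all `H` in `(0, 1)`, giving an exact O(n log n) method.
#'
#' @param H Hurst index in `(0, 1)`.  `H = 0.5` gives ordinary white
#'   Brownian increments.
#' @param n Number of increments (`>= 1`).
#' @param dt Step length.
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched and the output is reproducible.
#' @return Numeric vector of length `n` with attributes `H` and `dt`.
#' @export
#' @examples
#' x <- fbm_increments(0.75, 1000, 0.01, seed = 1)
#' mean(x^2)           # ~ 0.01^1.5
fbm_increments <- function(H, n, dt = 1, seed = NULL) {
  check_scalar(H, "H", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_pwfrac("'n' must be a positive count", "pwfrac_invalid_input")
  n <- as.integer(n)
  check_scalar(dt, "dt", lower = 0, open_lower = TRUE)
  x <- with_seed(seed, .fgn_unit(H, n))
  structure(x * dt^H, H = H, dt = dt)
}

# Unit-variance fGn of length n via circulant embedding.
.fgn_unit <- function(H, n) {
  if (n == 1L) return(rnorm(1))
  k <- 0:n
  acov <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(acov, acov[n:2])                 # length 2n, circulant first row
  lam <- Re(fft(circ))
  if (min(lam) < -1e-8 * max(lam))
    stop_pwfrac("circulant embedding produced a negative eigenvalue",
                "pwfrac_solver_error")
  lam[lam < 0] <- 0
  m <- 2L * n
  z <- complex(m)
  z[1L] <- sqrt(lam[1L]) * rnorm(1)
  z[n + 1L] <- sqrt(lam[n + 1L]) * rnorm(1)
  u <- rnorm(n - 1L)
  v <- rnorm(n - 1L)
  z[2:n] <- sqrt(lam[2:n] / 2) * complex(real = u, imaginary = v)
  z[m:(n + 2L)] <- Conj(z[2:n])
  Re(fft(z))[1:n] / sqrt(m)
}
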