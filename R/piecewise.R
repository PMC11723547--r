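#' Three-regime schedule
#'
#' Defines the partition of the horizon into the constant-order regime
#' `[0, T1)`, the variable-order regime `[T1, T2)` and the stochastic
#' regime `[T2, Tf]`, together with the step size and the order
#' specification of each deterministic regime.  Breakpoints are snapped to
#' the step grid; a warning is issued if snapping moves one by more than
#' `dt/2`.
#'
#' @param T1,T2,Tf Regime breakpoints, `0 < T1 < T2 < Tf`.
#' @param dt Step size, shared by all regimes.
#' @param theta1 Constant order of the first regime.
#' @param theta_fn Order function of the second regime (function of `t` or
#'   character expression; see [order_function()]).
#' @return A list of class `piecewise_schedule`.
#' @export
piecewise_schedule <- function(T1 = 30, T2 = 60, Tf = 100, dt = 0.01,
                               theta1 = 0.99,
                               theta_fn = "0.01 - 0.001*cos(t)") {
  check_scalar(dt, "dt", lower = 0, open_lower = TRUE)
  if (!(0 < T1 && T1 < T2 && T2 < Tf))
    stop_pwfrac("breakpoints must satisfy 0 < T1 < T2 < Tf",
                "pwfrac_config_error")
  snap <- function(x, nm) {
    s <- round(x / dt) * dt
    if (abs(s - x) > dt / 2 + 1e-12)
      warning(sprintf("breakpoint %s snapped from %g to %g", nm, x, s))
    s
  }
  structure(list(T1 = snap(T1, "T1"), T2 = snap(T2, "T2"),
                 Tf = snap(Tf, "Tf"), dt = dt, theta1 = theta1,
                 theta_fn = if (is.function(theta_fn))
                   theta_fn else order_function(theta_fn)),
            class = "piecewise_schedule")
}

#' Scenario configuration
#'
#' Bundles everything a piecewise run needs: model parameters, initial
#' state, schedule, stochastic configuration, CPC constants and numerical
#' options.  Serialisable to YAML via [write_scenario()] when the order
#' function is given as a character expression.
#'
#' @param params [bc_params()] model rates.
#' @param y0 Initial state `(X, B, C, R, E)`.
#' @param schedule [piecewise_schedule()].
#' @param noise [stochastic_config()] for the third regime.
#' @param Q,lambda CPC kernel constant and drift prefactor.
#' @param denom_kind NSFD denominator kind.
#' @param drift_eval_constant,drift_eval_variable Drift evaluation per
#'   deterministic regime (see [solve_variable_order()] for why the
#'   variable-order default is implicit).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(params = bc_params(),
                            y0 = c(X = 30000, B = 12300, C = 738,
                                   R = 334, E = 10),
                            schedule = piecewise_schedule(),
                            noise = stochastic_config(),
                            Q = 1, lambda = 1, denom_kind = "plain",
                            drift_eval_constant = "explicit",
                            drift_eval_variable = "implicit") {
  structure(list(params = params, y0 = check_state(y0),
                 schedule = schedule, noise = noise, Q = Q,
                 lambda = lambda, denom_kind = denom_kind,
                 drift_eval_constant = drift_eval_constant,
                 drift_eval_variable = drift_eval_variable),
            class = "scenario_config")
}

#' Benchmark scenario presets
#'
#' * `"figs1_5"`: constant order 0.99, horizon `[0,30)/[30,60)/[60,100]`,
#'   step 0.01, noise intensities all 0.1 — the headline scenario.
#' * `"figs6_10"`: as above with constant order 0.9 (order-sweep setting).
#' * `"fig11_shape"`: the incidence-comparison run structure — horizon
#'   `[0,3)/[3,5)/[5,12]`, order 0.9 (the underlying registry series is
#'   not published, so only the run structure is reproduced).
#'
#' All presets use the variable order `0.01 - 0.001 cos(t)` in the second
#' regime, the only order function published for it.
#'
#' @param name Preset name.
#' @param seed Master seed for the stochastic regime.
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name = c("figs1_5", "figs6_10", "fig11_shape"),
                            seed = 1L) {
  name <- match.arg(name)
  noise <- stochastic_config(seed = seed)
  switch(name,
    figs1_5 = scenario_config(schedule = piecewise_schedule(theta1 = 0.99),
                              noise = noise),
    figs6_10 = scenario_config(schedule = piecewise_schedule(theta1 = 0.9),
                               noise = noise),
    fig11_shape = scenario_config(
      schedule = piecewise_schedule(T1 = 3, T2 = 5, Tf = 12, theta1 = 0.9),
      noise = noise))
}

#' Run the full three-regime piecewise simulation
#'
#' Integrates the constant-order CPC regime on `[0, T1)`, hands its final
#' state to the variable-order regime on `[T1, T2)` (whose history sums
#' restart from the handoff), and hands that regime's final state to the
#' stochastic regime on `[T2, Tf]`.  Handoff states are equal across
#' boundaries by construction; the combined trajectory lives on a single
#' uniform grid with each point labelled by its regime.
#'
#' @param config A [scenario_config()] (or preset from
#'   [scenario_preset()]).
#' @return A `pw_trajectory` data frame with attribute `"handoffs"` (the
#'   states at `T1` and `T2`).
#' @export
#' @examples
#' \donttest{
#' tr <- run_piecewise(scenario_preset("figs1_5"))
#' tail(tr)
#' }
run_piecewise <- function(config) {
  s <- config$schedule
  tr1 <- solve_constant_order(config$params, config$y0, 0, s$T1, s$dt,
                              s$theta1, config$Q, config$lambda,
                              config$denom_kind,
                              config$drift_eval_constant)
  y1 <- unlist(tr1[nrow(tr1), compartments])
  tr2 <- solve_variable_order(config$params, y1, s$T1, s$T2, s$dt,
                              s$theta_fn, config$Q, config$lambda,
                              config$denom_kind,
                              config$drift_eval_variable)
  y2 <- unlist(tr2[nrow(tr2), compartments])
  tr3 <- solve_stochastic(config$params, y2, s$T2, s$Tf, s$dt,
                          config$noise, config$denom_kind)
  out <- rbind(tr1[-nrow(tr1), ], tr2[-nrow(tr2), ], tr3)
  rownames(out) <- NULL
  class(out) <- c("pw_trajectory", "data.frame")
  attr(out, "handoffs") <- list(T1 = y1, T2 = y2)
  out
}

#' Parameter sweep
#'
#' Re-runs a scenario for each value of one model rate, all else (including
#' the stochastic seed) held fixed.
#'
#' @param config A [scenario_config()].
#' @param name Name of a [bc_params()] field.
#' @param values Numeric vector of values to sweep.
#' @param horizon `"full"` runs all three regimes; `"deterministic"` stops
#'   at `T2` (regimes 1 and 2); `"constant"` stops at `T1`.  Pointwise
#'   cross-trajectory comparisons are meaningful on the constant-order
#'   regime; see the methods vignette.
#' @return Named list of `pw_trajectory` objects (names are the values).
#' @export
sweep_parameter <- function(config, name, values,
                            horizon = c("full", "deterministic",
                                        "constant")) {
  horizon <- match.arg(horizon)
  if (!name %in% names(config$params))
    stop_pwfrac(sprintf("unknown model parameter '%s'", name),
                "pwfrac_config_error")
  s <- config$schedule
  out <- lapply(values, function(v) {
    cfg <- config
    cfg$params[[name]] <- v
    switch(horizon,
      full = run_piecewise(cfg),
      deterministic = {
        tr1 <- solve_constant_order(cfg$params, cfg$y0, 0, s$T1, s$dt,
                                    s$theta1, cfg$Q, cfg$lambda,
                                    cfg$denom_kind, cfg$drift_eval_constant)
        y1 <- unlist(tr1[nrow(tr1), compartments])
        tr2 <- solve_variable_order(cfg$params, y1, s$T1, s$T2, s$dt,
                                    s$theta_fn, cfg$Q, cfg$lambda,
                                    cfg$denom_kind, cfg$drift_eval_variable)
        out <- rbind(tr1[-nrow(tr1), ], tr2)
        rownames(out) <- NULL
        class(out) <- c("pw_trajectory", "data.frame")
        out
      },
      constant = solve_constant_order(cfg$params, cfg$y0, 0, s$T1, s$dt,
                                      s$theta1, cfg$Q, cfg$lambda,
                                      cfg$denom_kind,
                                      cfg$drift_eval_constant))
  })
  names(out) <- as.character(values)
  out
}

#' Combine sweep results into long format
#'
#' @param sweeps Result of [sweep_parameter()].
#' @param name The swept parameter's name.
#' @return A long-format data frame adding `parameter` and `value` columns.
#' @export
sweep_long <- function(sweeps, name) {
  do.call(rbind, lapply(names(sweeps), function(v) {
    cbind(sweeps[[v]], parameter = name, value = as.numeric(v))
  }))
}

#' Write a deterministic reference run and its digest
#'
#' Runs the scenario, writes the trajectory CSV, and returns the file's
#' MD5 digest for regression testing: re-running with the same
#' configuration and seed must reproduce the digest exactly.
#'
#' @param config A [scenario_config()].
#' @param path Output CSV path.
#' @return Invisibly, `list(path, digest)`.
#' @export
generate_fixture <- function(config, path) {
  tr <- run_piecewise(config)
  write_trajectory(tr, path)
  dig <- unname(tools::md5sum(path))
  invisible(list(path = path, digest = dig))
}

#' @export
print.pw_trajectory <- function(x, ...) {
  cat(sprintf("<pw_trajectory> %d points, t in [%g, %g], regimes: %s\n",
              nrow(x), min(x$t), max(x$t),
              paste(unique(x$regime), collapse = ", ")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Plot a piecewise trajectory
#'
#' Simple line chart of all five compartments with regime boundaries
#' marked.
#'
#' @param x A `pw_trajectory`.
#' @param log_y Plot on a log scale.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.pw_trajectory <- function(x, log_y = FALSE, ...) {
  Y <- as.matrix(x[, compartments])
  graphics::matplot(x$t, Y, type = "l", lty = 1, col = seq_len(5),
                    xlab = "time", ylab = "population",
                    log = if (log_y) "y" else "", ...)
  bounds <- x$t[which(diff(as.integer(factor(x$regime))) != 0) + 1]
  graphics::abline(v = bounds, lty = 3, col = "grey40")
  graphics::legend("topleft", compartments, lty = 1, col = seq_len(5),
                   bty = "n")
  invisible(x)
}
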