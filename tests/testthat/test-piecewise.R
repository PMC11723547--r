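# A short schedule keeps the O(N^2) history sums cheap in unit tests;
# the full benchmark horizon is exercised in the acceptance suite.
short_config <- function(seed = 1) {
  scenario_config(
    schedule = piecewise_schedule(T1 = 2, T2 = 4, Tf = 6, dt = 0.01,
                                  theta1 = 0.95),
    noise = stochastic_config(seed = seed))
}

test_that("regime handoffs are exactly continuous", {
  tr <- run_piecewise(short_config())
  h <- attr(tr, "handoffs")
  at <- function(tt) unlist(tr[abs(tr$t - tt) < 1e-9,
                               c("X", "B", "C", "R", "E")])
  expect_identical(unname(at(2)), unname(h$T1))
  expect_identical(unname(at(4)), unname(h$T2))
  expect_identical(tr$regime[abs(tr$t - 2) < 1e-9], "cpc-variable")
  expect_identical(tr$regime[abs(tr$t - 4) < 1e-9], "stochastic")
  # single uniform grid, strictly increasing
  expect_equal(diff(tr$t), rep(0.01, nrow(tr) - 1), tolerance = 1e-9)
})

test_that("the incidence-comparison preset produces the expected grid", {
  cfg <- scenario_preset("fig11_shape")
  expect_equal(cfg$schedule$T1, 3)
  expect_equal(cfg$schedule$T2, 5)
  expect_equal(cfg$schedule$Tf, 12)
  tr <- run_piecewise(cfg)
  expect_equal(nrow(tr), 1201)
  expect_true(all(is.finite(as.matrix(tr[, c("X", "B", "C", "R", "E")]))))
})

test_that("different seeds differ only in the stochastic segment", {
  a <- run_piecewise(short_config(seed = 1))
  b <- run_piecewise(short_config(seed = 2))
  det <- a$t < 4 - 1e-9
  expect_identical(a[det, ], b[det, ])
  expect_false(identical(a[!det, ], b[!det, ]))
})

test_that("fixture generation is digest-stable", {
  cfg <- short_config(seed = 42)
  f1 <- file.path(tempdir(), "fix1.csv")
  f2 <- file.path(tempdir(), "fix2.csv")
  d1 <- generate_fixture(cfg, f1)
  d2 <- generate_fixture(cfg, f2)
  expect_true(file.exists(f1))
  expect_identical(d1$digest, d2$digest)
  rt <- read_trajectory(f1)
  tr <- run_piecewise(cfg)
  expect_equal(rt$X, tr$X, tolerance = 1e-15)
  unlink(c(f1, f2))
})

test_that("sweeps reject unknown parameter names", {
  expect_error(sweep_parameter(short_config(), "not_a_rate", c(1, 2)),
               class = "pwfrac_config_error")
})

test_that("sweep results vary the named parameter only", {
  sw <- sweep_parameter(short_config(), "phi1", c(0.03, 0.06),
                        horizon = "constant")
  expect_named(sw, c("0.03", "0.06"))
  # X is decoupled from phi1: identical trajectories
  expect_identical(sw[["0.03"]]$X, sw[["0.06"]]$X)
  # B responds
  expect_false(identical(sw[["0.03"]]$B, sw[["0.06"]]$B))
  lg <- sweep_long(sw, "phi1")
  expect_true(all(c("parameter", "value") %in% names(lg)))
  expect_equal(sort(unique(lg$value)), c(0.03, 0.06))
})

test_that("schedule validation and snapping behave", {
  expect_error(piecewise_schedule(T1 = 5, T2 = 3, Tf = 10),
               class = "pwfrac_config_error")
  # breakpoints snap to the nearest grid point
  s <- piecewise_schedule(T1 = 2.004, T2 = 4, Tf = 6, dt = 0.01)
  expect_equal(s$T1, 2)
  s <- piecewise_schedule(T1 = 2.007, T2 = 4, Tf = 6, dt = 0.01)
  expect_equal(s$T1, 2.01)
})

test_that("scenario configurations round-trip through YAML", {
  cfg <- short_config(seed = 7)
  f <- file.path(tempdir(), "scenario.yaml")
  write_scenario(cfg, f)
  back <- read_scenario(f)
  expect_equal(unclass(back$params), unclass(cfg$params))
  expect_equal(back$y0, cfg$y0)
  expect_equal(back$schedule$T1, cfg$schedule$T1)
  expect_equal(back$schedule$theta1, cfg$schedule$theta1)
  expect_identical(attr(back$schedule$theta_fn, "spec"),
                   attr(cfg$schedule$theta_fn, "spec"))
  expect_equal(back$noise$intensities, cfg$noise$intensities)
  expect_equal(back$noise$seed, cfg$noise$seed)
  # a run from the round-tripped config is identical
  expect_identical(as.data.frame(run_piecewise(back)),
                   as.data.frame(run_piecewise(cfg)))
  unlink(f)
})

test_that("trajectory CSV round-trips numeric values exactly", {
  tr <- solve_constant_order(table1_params, y0_bench, 0, 0.5, 0.01, 0.9)
  f <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_identical(back$X, tr$X)
  expect_identical(back$regime, tr$regime)
  unlink(f)
})
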