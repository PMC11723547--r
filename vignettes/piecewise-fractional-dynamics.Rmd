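---
title: "Piecewise fractional-stochastic dynamics of cancer progression: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise fractional-stochastic dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwfrac)
```

## The model

`pwfrac` simulates a five-compartment model of breast cancer progression
under chemotherapy.  The compartments are hospitalised stage 1-2 patients
$X$, stage 3A/3B patients $B$, stage 4 patients $C$, disease-free patients
after chemotherapy $R$, and patients with chemotherapy-induced
cardiotoxicity $E$.  The deterministic drift is the linear system

$$
\begin{aligned}
X' &= \omega_1 - (\gamma_1+\mu_2)X\\
B' &= \omega_2 + \mu_2 X + \alpha_1 R - (\gamma_2+\mu_1+\phi_1+\sigma_1)B\\
C' &= \omega_3 + \mu_1 B + \alpha_2 R - (\gamma_3+\phi_2+\sigma_2)C\\
R' &= \gamma_1 X + \gamma_2 B + \gamma_3 C - (\alpha_1+\alpha_2+\phi_3)R\\
E' &= \phi_3 R + \phi_2 C + \phi_1 B - \sigma_3 E,
\end{aligned}
$$

with inflows $\omega_i$ (persons/time), transfers into the disease-free
class $\gamma_i$, stage progression $\mu_1$ ($B\to C$) and $\mu_2$
($X\to B$), relapse $\alpha_1,\alpha_2$, chemotherapy-associated flows
into the cardiotoxic class $\phi_i$, and mortalities $\sigma_i$ (all
per time unit).  The benchmark parameter table ships as
`table1_values()`; its original symbols (inflows $\Lambda_i$,
transmissions $\beta_i$, mortalities named $\mu_i$, relapses $\psi_i$)
are reconciled onto the model's names by `map_table1()`.  One entry of
that reconciliation deserves a note: the model's $\mu_2$ is the $X \to B$
transfer, whose tabulated value is $\beta_2 = 0.01$; the table's own
$\mu_1..\mu_3 = 0.0256$ are mortalities and map to $\sigma_1..\sigma_3$.
Consequently the decoupled $X$ equation has equilibrium
$\omega_1/(\gamma_1+\mu_2) = 14000/0.04 = 350000$.

The full horizon $[0, T_f]$ is partitioned into three regimes that
capture crossover behaviour:

1. $[0, T_1)$: constant-order Caputo-proportional-constant (CPC)
   fractional dynamics,
2. $[T_1, T_2)$: variable-order CPC dynamics,
3. $[T_2, T_f]$: a stochastic system driven by fractional Brownian
   motion.

The benchmark uses $T_1 = 30$, $T_2 = 60$, $T_f = 100$, step
$\Delta t = 0.01$, initial state $(30000, 12300, 738, 334, 10)$ and noise
intensities $\varsigma_i = 0.1$; these are the defaults of
`scenario_preset("figs1_5")`.

## The CPC operator and its discretisation

The CPC operator of order $\theta \in (0,1]$ is
$D^{CPC,\theta} = V_1(\theta)\, I^{1-\theta} + V_0(\theta)\, D^{\theta}_C$,
a Riemann-Liouville integral of order $1-\theta$ plus a Caputo
derivative of order $\theta$, with kernels $V_0 = \theta Q^{1-\theta}$,
$V_1 = (1-\theta)Q^{\theta}$ and a positive constant $Q$ (default 1).
The model drift enters scaled by $\lambda^{1-\theta}$ (default
$\lambda = 1$).  At $\theta = 1$, $Q = 1$ the operator is the classical
derivative.

Both parts are discretised by Grunwald-Letnikov convolutions over the
full solution history, with a nonstandard finite-difference (NSFD)
denominator $\Pi(\Delta t) = \Delta t + O(\Delta t^2)$ in place of the
raw step (`"plain"`: $\Pi = \Delta t$, the default at
$\Delta t = 0.01$; `"expm1"`: $\Pi = 1 - e^{-\Delta t}$).  The weights
are

* $\varpi_0 = 1,\ \varpi_i = (1 - \theta/i)\varpi_{i-1}$ — binomial
  coefficients of order $\theta - 1$ (integral part),
* $\kappa_1 = \theta,\ \kappa_{i+1} = \kappa_i (i-\theta)/(i+1)$ —
  signed binomials of order $\theta$ (derivative part),
* $r_i = i^{-\theta}/\Gamma(1-\theta)$ — the initial-value correction
  that turns the Riemann-Liouville difference into a Caputo one.

Both weight families satisfy the scheme's ordering assumptions
($0 < \kappa_{i+1} < \kappa_i < \kappa_1 = \theta < 1$, and likewise for
$r_i$); the test suite pins the recurrences against direct
gamma-function binomials to $10^{-10}$.

**Exponent placement.** The update is implemented as

$$
\Big[\tfrac{V_1}{\Pi^{\theta-1}} + \tfrac{V_0}{\Pi^{\theta}}\Big] x_{n+1}
= \lambda^{1-\theta} f_n
- \tfrac{V_1}{\Pi^{\theta-1}} \sum_{i=1}^{n+1} \varpi_i\, x_{n+1-i}
+ \tfrac{V_0}{\Pi^{\theta}} \Big(\sum_{i=1}^{n+1} \kappa_i\, x_{n+1-i}
 + r_{n+1} x_0\Big),
$$

i.e. with $\Pi^{1-\theta}$ multiplying the integral part and
$\Pi^{-\theta}$ the derivative part.  This is the only reading that is
dimensionally consistent with a GL approximation of $I^{1-\theta}$ and
$D^\theta$ and that recovers explicit Euler exactly in the
$\theta = 1$, $\Pi = \Delta t$ limit; the code multiplies the equation
through by $\Pi^{\theta}$ so the pivot $V_1 \Pi + V_0$ is well scaled
for all orders and equals exactly 1 in the classical limit (making the
$\theta = 1$ trajectory bit-identical to explicit Euler, which the test
suite asserts).

**Drift evaluation and stability.** The scheme's derivation evaluates
the drift at $t_n$ (explicit), and the constant-order solver keeps that
default.  For the variable-order regime the published order function is
$\theta(t) = 0.01 - 0.001\cos t$, and for such tiny orders the CPC
equation is dominated by its integral part: the equation behaves like a
Volterra constraint $V_1 \int_0^t x + V_0 x \approx f$ rather than an
evolution equation.  The explicit update then multiplies the drift by
$\Pi^\theta / (V_1 \Pi + V_0) \approx 48$ at $\Delta t = 0.01$, and the
iteration diverges within a few hundred steps — this is reproducible
with `drift_eval = "explicit"` and is asserted as a divergence error in
the tests.  `solve_variable_order()` therefore defaults to
`drift_eval = "implicit"`: drift at $t_{n+1}$, a single $5\times 5$
linear solve per step (exact, the model being linear; no nonlinear
iteration).  With it the regime completes with finite states.  The
continuous small-order problem itself is singular at the regime start:
the handoff state does not satisfy the integral constraint, so the
solution passes through a boundary layer in which all compartments
collapse from $\sim 10^5$ to $O(10)$ with damped oscillation and
transient negative values.  Negative transients are reported, not
clipped (an optional clip-at-zero mode exists for the stochastic
phase).

**Variable order.**  Per-index weights use $\theta(t_i)$ at index $i$
in the recurrences above ($\kappa$ uses the analogous per-index
recurrence, so a constant order function reproduces the constant-order
tables bit for bit), and the kernels and pivot exponent at step $n$ use
$\theta(t_{n+1})$.  The history restarts at each regime boundary: the
variable-order solve treats its handoff state as $x_0$ and its GL sums
start fresh.  Order functions are given as character expressions in `t`
(e.g. `"0.01 - 0.001*cos(t)"`) so configurations stay serialisable.

No short-memory truncation is applied: every step sums the full
history, so a regime of $N$ steps costs $O(N^2)$ ($N = 3000$ per
deterministic benchmark regime; well under a second in practice).

## The stochastic regime

On $[T_2, T_f]$ each equation carries multiplicative noise
$\varsigma_k x_k\, dM_k^{H^*}$ with five independent fractional
Brownian drivers of common Hurst index $H^* > 0.5$.  (As printed, three
of the five noise terms pair mismatched states and letters; the
implementation follows the scalar template — each equation's own state
multiplies its own driver — and documents the literal reading as a
typographic slip.)  The Euler-Maruyama update is

$$
x_{n+1} = x_n + f_n \Pi + \varsigma\, x_n \Delta B_n + c,
$$

with a Hurst correction $c$ in three conventions:
`"paper-literal"` $c = 0.5\, x_n \Pi^{2H^*}$ (the printed form, the
default), `"sigma-squared"` $c = 0.5\, \varsigma^2 x_n \Pi^{2H^*}$ (the
standard Ito-type correction, vanishing with the noise) and `"off"`.
Note the paper-literal correction does not vanish at zero noise and
acts as a systematic relative inflation of $\approx e^{0.5\Pi^{2H^*} N}$
over $N$ steps; tests that compare against deterministic Euler therefore
use a mode whose correction vanishes.  The exponent is read as
$\Pi^{2H^*}$ (the fBm increment-variance scaling), consistent with the
printed condition $H^* > 0.5$.

No Hurst value is published for the benchmark; the package default is
$H^* = 0.75$, the midpoint of the admissible interval $(0.5, 1)$.
$H = 0.5$ is accepted only by the low-level test harnesses (classical
Brownian oracles), not by `stochastic_config()`.

**fGn generation.** `fbm_increments()` uses circulant embedding
(Davies-Harte) of the exact fGn autocovariance
$\rho(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})$, which is
nonnegative definite for all $H \in (0,1)$: an exact $O(n\log n)$
sampler.  The five driver streams are seeded by splitting one master
seed, so a path is fully reproducible from `(config, seed)`.

**A statistical note on testing fGn.**  For $H$ close to 1 the
time-average variance of a single stream converges at rate
$n^{H-1}$, not $n^{-1/2}$: at $H = 0.9$ one stream of $10^5$ increments
estimates its own variance with a sampling error of roughly 13%, so no
single-stream test can reliably verify the variance to 5%.  The
statistics tests therefore use an ensemble of 1000 independent streams
of 100 increments ($10^5$ in total), whose pooled second moment
concentrates to well under 1%.

**Strong convergence.** `em_strong_error()` measures RMS endpoint error
on the scalar geometric SDE with a shared Brownian path across a step
ladder.  The closed-form endpoint is matched to the correction mode:
with the sigma-squared correction the scheme is consistent with drift
$\nu + \varsigma^2/2$, whose solution is
$x_0\exp(\nu T + \varsigma B_T)$; with the correction off it is the Ito
solution $x_0\exp((\nu - \varsigma^2/2)T + \varsigma B_T)$.  The
empirical order lands near the theoretical $1/2$.

## Analytic certificates

`lipschitz_matrix()` returns the componentwise Lipschitz bound
$\Theta$ of the drift operator exactly as published, including two
entries that differ from the dynamics ($\Theta_{11} = \gamma_1+\mu_1$
where the $X$ equation carries $\gamma_1+\mu_2$, and
$\Theta_{44} = \alpha_1+\alpha_2+\sigma_3$ where the $R$ equation
carries $\phi_3$); the discrepancy is kept so the certificate matches
the published bound, and is flagged in the documentation.
`contraction_factor()` scales $\rho(\Theta)$ by
$\lambda^{1-\theta}\Psi_{\max}\Phi_{\max}|\Gamma(\theta-1)|/|V_0(\theta)|$.
Conventions: $\Gamma(\theta-1)$ is negative on $(0,1)$, so its absolute
value is used (a contraction scale must be nonnegative), and
$\Psi_{\max},\Phi_{\max}$ are bound constants the source analysis never
defines — they are exposed as configuration scalars defaulting to 1,
with the caveat printed in the report.  At the benchmark parameters the
factor exceeds one for all orders of interest (the gamma factor alone is
$\sim 100$ at $\theta = 0.99$), so the certificate verdict is "not
contractive" there; the quantity is reported as a diagnostic, not a
guarantee.  `lyapunov_bound()` returns the state-independent constant
$\bar V$ bounding the stochastic generator — the sum of all sixteen
rates plus half the squared intensities, covering four noise channels
as printed (a five-channel variant sits behind `five_term = TRUE`).

## Parameter sweeps and what the model can and cannot reproduce

`sweep_parameter()` re-runs a scenario across values of one rate with
everything else (including the noise seed) fixed.  Pointwise
cross-trajectory comparisons are made on the constant-order regime
after a one-unit transient: on the variable-order regime the boundary
layer collapses all trajectories to near-zero oscillating values where
ordering is numerically meaningless, and on the stochastic regime
pointwise comparisons are noise-flaky (path means over many seeds are
the right tool there).

Two published narrative claims are structurally incompatible with the
model equations themselves, and the package reproduces the equations,
not the narrative:

* $\phi_3$ (chemotherapy at stage 4) appears only as the outflow
  $-\phi_3 R$ of the disease-free class (feeding $E$), so increasing
  $\phi_3$ *decreases* $R$ — it cannot increase it.
* $\gamma_2$ moves $B$ into $R$, and $R$ feeds $C$ through the dominant
  relapse rate $\alpha_2 = 0.3 \gg \mu_1 = 0.01$, so increasing
  $\gamma_2$ *increases* $C$ over the benchmark horizon.

The directions that do follow from the equations — $\phi_1$ decreasing
$B$ (and leaving the decoupled $X$ unchanged), $\phi_3$ decreasing $B$,
$\gamma_2$ increasing $E$ — are verified in the test suite.

## Problem sizes and numerical conventions

Default test and acceptance runs use the benchmark grid
($\Delta t = 0.01$; deterministic regimes of 3000 steps each, a
stochastic regime of 4000 steps, 100-path ensembles for trend
statistics, 500 paths for the strong-order ladder, $10^5$ increments
for fGn statistics).  Unit tests use shorter horizons of the same
structure.  Other conventions: states are real-valued (mean-field
model, no rounding); the pivot $V_1\Pi + V_0 > 0$ is asserted at every
step; breakpoints snap to the step grid; divergence raises a classed
error carrying the step index; deterministic segments are
bit-reproducible and the stochastic segment is reproducible given the
seed.

## Known limitations

* The variable-order regime inherits the singular boundary layer of the
  tiny published order function; its trajectories should be read as the
  scheme's faithful output for that regime, not as biologically
  meaningful population counts.
* No adaptive stepping, no fast-convolution acceleration of the GL
  sums, no short-memory truncation, and no Milstein or higher-order
  stochastic schemes.
* The contraction certificate depends on two unspecified bound
  constants; with their default of 1 it is a relative diagnostic only.
* The synthetic scenarios emulate the published settings; the real
  incidence-registry series behind the original comparison is not
  published, so only the run structure (`"fig11_shape"`) is
  reproduced, and nothing here validates the model against real data.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_preset("figs1_5", seed = 1)
tr <- run_piecewise(cfg)
plot(tr, log_y = TRUE)
diagnostics_report(bc_params(), theta = 0.99)
```
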