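---
title: "Phosphate kinetics in single- and multi-pass hemodialysis: models, solvers and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphate kinetics in single- and multi-pass hemodialysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoskin)
```

## The models and their assumptions

Phosphate is predominantly intracellular; only a small, rapidly mixed serum +
extracellular pool (volume $V_{b0}$, concentration $x(t)$) is accessible to
the dialyzer. The intracellular pool is treated as an inexhaustible source at
constant concentration $C_s$ feeding the accessible pool at transfer rate
$K_s$ (L/h). The dialyzer clears phosphate by diffusion at rate $K_b$ (L/h)
and, when ultrafiltration is active, convectively at flow $Q$ (L/h), which
shrinks the patient-side volume as $V_b(t) = V_{b0} - Qt$. Units are fixed
package-wide: hours, litres, mmol/L, L/h; there is no conversion layer.

**Single pass (SP).** Dialysate is used once, so its phosphate level is a
small constant $C_{d0}$:
$$(V_{b0}-Qt)\,x' = K_sC_s - (K_s+K_b)\,x + K_bC_{d0}.$$
This has the exact solution implemented in `sp_concentration()`: a power law
$(1-Qt/V_{b0})^{(K_s+K_b)/Q}$ around the plateau
$x^{*} = (K_sC_s+K_bC_{d0})/(K_s+K_b)$, collapsing to an exponential when
$Q=0$. The solution is only defined for $t < V_{b0}/Q$ (complete volume
depletion); the package raises an error there rather than clamping.

**Multi pass (MP).** A transportable dialysis unit recirculates a small
dialysate volume $V_d(t)=V_{d0}+Qt$, whose concentration $y(t)$ rises during
treatment:
$$(V_{b0}-Qt)\,x' = K_sC_s-(K_s+K_b)x+K_by, \qquad
  (V_{d0}+Qt)\,y' = (K_b+Q)(x-y).$$

**Assumptions inherited by everything downstream:** constant $C_s$ during a
session (justified by the size of the intracellular pool), a well-mixed
accessible pool in equilibrium with the blood passing the filter, constant
$Q$, and no intake or binder kinetics during the session.

## The certified series solution

The MP system is linear with polynomially time-varying coefficients, so
$x, y$ admit power series $\sum\alpha_k t^k, \sum\beta_k t^k$ whose
coefficients follow a two-term matrix recursion
(`series_coefficients()`). The recursion matrices converge as
$k \to \infty$, which bounds the coefficient growth and proves uniform
convergence for $t < \min(V_{b0},V_{d0})/Q$ — exactly until a compartment
would be depleted; `series_eval()` refuses evaluation beyond this horizon.

The practical payoff is an *a-priori* error certificate that numerical
integrators cannot give: truncating after order $N$ commits an error of at
most $|\alpha_{N+1}|t^{N+1}$ (and $|\beta_{N+1}|t^{N+1}$ for the dialysate),
the Lagrange remainder exposed by `truncation_bound()`.
`terms_for_tolerance()` inverts it for the reference 8-hour session:

```{r}
p <- mp_params(Ks = 2.6, Kb = 6.9, Q = 0.23, Cs = 2.9, Vb0 = 10,
               Vd0 = 25, x0 = 2.9, y0 = 0)
terms_for_tolerance(p, t_max = 8, tol = 0.01)   # order certifying 0.01 mmol/L
```

Two numerical caveats, both deliberate choices:

* Coefficients are stored once and partial sums use Horner's scheme, which
  avoids forming $t^k$ at large $N$.
* The certificate bounds *truncation*, not floating-point rounding. The
  alternating sums reach magnitude $\sim e^{|\lambda_2| t}$ before
  cancelling, so in double precision the achievable accuracy degrades once
  $|\lambda_2|\,t \gtrsim 25$ ($\lambda_2$ the fast eigenvalue below). All
  ten published patient-level estimates stay well inside this regime on an
  8-hour grid, but independently drawn rate/volume combinations near the
  box-constraint corners do not; the test suite therefore always compares
  the series against other solvers *within its certified bound*, which is
  the contract the series actually makes.

## The closed form for negligible ultrafiltration

Ultrafiltration contributes little to phosphate transport, and with $Q=0$
the MP system is autonomous: $\dot{\mathbf x} = A\mathbf x + \mathbf b$ with
constant $A$. Both eigenvalues of $A$ are real and negative
(`eigenvalues_A()`), and the solution is a bi-exponential relaxation of both
compartments toward $C_s$, implemented in `closed_form_Q0()` from the
eigendecomposition $A = PDP^{-1}$. Any consistent eigenvector normalization
gives the same trajectory; the package tests the explicit formula against a
unit-column normalization and against adaptive integration. Degenerate
eigenvalues cannot occur for $K_b > 0$ but are guarded
($|\lambda_1-\lambda_2| < 10^{-12}$ raises).

`Q`-dispatch: every solver treats $Q < 10^{-10}$ L/h as exactly zero. The
finite-$Q$ SP exponent $(K_s+K_b)/Q$ overflows as $Q\to 0$ while the limit
is exact, so dispatching preserves numerical continuity; the threshold is
shared across modules.

## Reference integrator

`reference_integrate()` is an adaptive Dormand–Prince RK45 at local
tolerance $10^{-10}$, implemented in the package (no ODE-solver dependency
is assumed) and kept free of shared code with the analytic solvers — it is
the independent oracle every one of them is tested against, including a
step-halving self-consistency check.

## Rebound after a session

Disconnecting the dialyzer leaves pure source diffusion,
$V_{b0}x' = K_s(C_s - x)$, so the serum level relaxes from its end-of-session
value $x_T$ back to $C_s$ at rate $K_s/V_{b0}$ (`rebound_concentration()`,
absolute time). The percentage rebound
$(x(t{+}T)-x(T))/x(T)\cdot 100\%$ has the explicit form
$$\mathrm{rebound}(t)=\frac{C_s-x_T}{x_T}\bigl(1-e^{-K_st/V_{b0}}\bigr)\cdot100\%$$
(`rebound_percent()`, time measured *since the end* of the session — the two
conventions are exposed by separate functions precisely to prevent
off-by-$T$ mistakes). If the session ran long enough that $x_T$ reached the
SP plateau with phosphate-free dialysate, $C_s$ cancels:
$\mathrm{rebound}(t) = (K_b/K_s)(1-e^{-K_st/V_{b0}})\cdot100\%$
(`plateau_rebound_percent()`), which is why 2 h, 4 h and 8 h sessions show
the same rebound curve. Plateau attainment depends on the rates, so the
"session at least 2 h" precondition is advisory — a warning, not an error.

## Parameter estimation

Fitting assumes $Q=0$ throughout and minimizes the root-mean-square residual
pooled over all series of the chosen mode ($d=1$ SP, $2$ MP, $3$ coupled).
The published objective assumes equal series lengths; the package divides by
the *total* residual count, which reduces to the $1/(dn)$ form when lengths
agree and handles a 5-point SP series alongside two 9-point MP series.

Free parameters by mode (initial concentrations are parameters because the
baseline sample carries the same noise as any other):

| mode | free | fixed / implied |
|------|------|-----------------|
| SP | $K_s, K_b, z_0$ | $V_{b0}$ at the clinical value; $C_s=z_0$ |
| MP | $K_s, K_b, V_{b0}, x_0$ | $C_s=x_0$; $y_0=0$ |
| CP | $K_s, K_b, V_{b0}, z_0, x_0$ | $C_s=\max(z_0,x_0)$; $y_0=0$ |

$y_0$ is pinned to zero: freeing it (as a stand-in for a spatial average
over the filter channels) does not change fits materially. The CP
$\max$-rule is kept exact — no smoothing — so the objective has a kink on
the $z_0=x_0$ ridge; see "optimizer" below.

**Stage 1, linear pre-estimate.** With volumes, $C_s$ and initial conditions
held fixed the equations are linear in $(K_s, K_b)$; each consecutive
sampling interval is discretized by the trapezoidal rule and the stacked
system is solved by global least squares (`linear_preestimate()`). The
scheme is second order: its bias scales as $((K_s{+}K_b)\Delta t/V_{b0})^2$,
a few percent for typical patients on hourly samples but up to ~15 % for
the fastest, which is why it seeds — never replaces — the nonlinear stage.
A rank-deficient design (e.g. all samples at steady state) raises an error
rather than returning an arbitrary solution.

**Stage 2, bounded nonlinear least squares.** `nlminb` (bounded
quasi-Newton) started from the pre-estimated rates, first measurements and
the clinical volume, inside the physiological box
$K_s,K_b\in[0,30]$ L/h, $V_{b0}\in[0,60]$ L, $z_0,x_0\in[0,5]$ mmol/L.
Convergence tolerances are $10^{-10}$ (objective) and $10^{-8}$
(parameters). Two polish passes follow: a restart at the optimum, then a
short Nelder–Mead pass, which is derivative-free and therefore safe on the
CP kink where finite-difference gradients stall. Points where the model is
unevaluable (optimizer probing $K_b=0$) receive a large finite penalty.
Non-convergence is reported in the result, not raised.

**Uncertainty.** 95% half-widths come from the finite-difference Hessian
$H$ of the residual sum of squares at the optimum, covariance
$2s^2H^{-1}$ with $s^2 = \mathrm{RSS}/(n-p)$ — the Gauss–Markov
linearization ($H \approx 2J^TJ$ for small residuals, recovering the
familiar $s^2(J^TJ)^{-1}$). The source analysis cites a textbook without
fixing the scaling; this choice is documented here so an alternative can be
swapped in one place. A singular or indefinite Hessian yields `Inf`
half-widths with a warning — this is exactly what happens when $V_{b0}$ is
freed on SP-only data, reproducing its practical non-identifiability and the
motivation for coupled fitting, where the shared $V_{b0}$ becomes
identifiable through the dialysate mass balance.

**Robustness.** `multistart_robustness()` reruns the fit from uniform draws
inside the bounds (the first start is the deterministic two-stage start, so
one start equals a plain fit) and clusters optima at relative tolerance
$10^{-4}$; well-conditioned synthetic patients collapse to a single cluster.

## The synthetic cohort: what it does and does not establish

No patient-level measurements are distributed, so every end-to-end test runs
on synthetic cohorts (`cohort_design()`, `generate_cohort()`) emulating the
clinical study design: 10 patients, SP sampled at baseline plus hourly to
4 h (blood), MP at baseline plus hourly to 8 h (blood and dialysate), both
modalities generated from the *same* physiological parameters per patient —
the premise that makes coupled fitting meaningful.

Stated-world choices, fixed once:

* Parameter ranges are the spans of the published per-patient estimates:
  $K_s\in[2.4,11]$, $K_b\in[3.9,17.4]$ L/h, $V_{b0}\in[8,23]$ L,
  $C_s\in[1.0,2.9]$, $C_{d0}\in[0.09,0.21]$ mmol/L,
  $V_{d0}\in[14.24,31.93]$ L; draws are independent uniforms (no
  correlation structure is claimed by the source analysis, though real
  patients plainly correlate rates with volumes).
* The measurement-noise model is unstated in the source; the package uses
  additive Gaussian noise, $\sigma = 0.05$ mmol/L by default — consistent
  with published fit RMSEs of 0.01–0.08 — truncated at zero (negligible at
  clinical concentrations). Whether real assay error scales with
  concentration cannot be decided from the published material.
* Truth trajectories use $Q=0$ forward models to match the estimation
  assumption; a design option injects $Q\in[0.1,0.3]$ L/h truth to study
  the (argued negligible) misspecification, routed through the numerical
  integrator.

A green recovery test therefore establishes that *the pipeline inverts its
own forward model under the stated noise* — it does not validate the
two-compartment physiology, the constant-$C_s$ assumption, or the noise
model against real patients.

## Numerical choices and degenerate inputs, collected

* $Q$-zero dispatch threshold $10^{-10}$ L/h, shared by all solvers.
* Series validity horizon enforced strictly; reported
  $\tilde\lambda$ adds $\varepsilon = 10^{-6}$ 1/h to the limiting
  eigenvalue bound.
* The reference session figure does not print $C_{d0}$ or $V_{d0}$; the
  package adopts $C_{d0}=0$ (high-flow dialysate is effectively
  phosphate-free at the membrane) and $V_{d0}=25$ L, with sensitivity
  recorded at the observed extremes 14.24 L (order rises to 30) and
  31.93 L (falls to 22).
* Reduction-ratio formulas (`sp_reduction_ratio()`) enforce the
  steady-start, $C_{d0}=0$, $Q=0$ convention they were derived under
  instead of silently generalizing.
* CSV dialect: comma separator, UTF-8, period decimal, mandatory header;
  one unambiguous dialect, validated with row-level error messages.
* All stochastic behaviour (cohorts, noise, multistart) is seeded;
  identical seeds give byte-identical CLI outputs.

## Known limitations

* One accessible compartment: no early-session flattening, no delayed
  rebound; such effects require additional states or delays and are out of
  scope.
* The fitted $C_s$ leans on the steady-state-at-baseline assumption; a
  noisy baseline propagates into it (relapse measurements would decouple
  this, and rebound-based estimation of $K_s$ is supported only on
  synthetic data).
* Confidence intervals are linearization-based; they inherit the usual
  optimism near bounds and say nothing about multimodality (the multistart
  report addresses the latter empirically).
* The series solver's floating-point ceiling discussed above; for stiff
  parameter corners prefer `closed_form_Q0()` ($Q=0$) or
  `reference_integrate()`.
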