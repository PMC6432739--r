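---
title: "The chemovirotherapy model: dynamics, steady states, and delay-induced stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The chemovirotherapy model: dynamics, steady states, and delay-induced stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoviro)
```

## The model

`chemoviro` simulates and analyses a four-compartment model of
combination cancer therapy: an oncolytic virus that infects and lyses
tumor cells, administered together with a chemotherapeutic drug. The
dimensional state is the uninfected tumor cell concentration $U$,
virus-infected tumor cells $I$, free virions $V$, and drug
concentration $C$ in an avascular tumor nodule. Uninfected cells grow
logistically at rate $\alpha$ toward a shared carrying capacity $K$;
infection transfers mass from $U$ to $I$ at rate $\beta UV$; infected
cells lyse at rate $\delta$, each releasing $b$ virions; virions clear
at rate $\gamma$; the drug kills uninfected and infected cells at
rates $\delta_0 UC$ and $\delta_1 IC$, is infused at a scheduled rate
$g(t)$, and decays at rate $\lambda$.

Rescaling time by the infected-cell lysis rate ($\bar t = \delta t$)
and concentrations by their characteristic scales gives the
dimensionless system that every function in the package works with:

$$
\begin{aligned}
U' &= \alpha U(1-U-I) - \beta UV - \delta_0 UC,\\
I' &= \beta UV - I - \delta_1 IC,\\
V' &= bI - \beta UV - \gamma V,\\
C' &= \xi(t) - \psi C,
\end{aligned}
$$

where all symbols now denote their dimensionless counterparts,
$\psi = \lambda/\delta$ and $\xi(t)$ is one of three infusion
schedules: constant $\phi$ (protracted intravenous infusion),
exponential $\phi e^{-at}$ (single bolus), or sinusoidal
$\phi\sin^2(at)$ (periodic clinic visits). Dropping compartments
yields the chemotherapy-only planar system (logistic bracket $1-U$),
the virotherapy-only system, and the untreated logistic equation with
closed form $U(t) = U_0/((1-U_0)e^{-\alpha t}+U_0)$.

Two transcription repairs were needed to make the published system
self-consistent, and both are applied throughout: the logistic bracket
is $1-(U+I)/K$ (one printing garbles the $I$), and the infected-cell
loss term in the dimensionless system is $-I$ (the rescaled
$-\delta I$).

## Parameters, scales, and two deliberate conventions

The reference dimensional values ship as `table1_params()`:
$K=10^6$ cells, $\alpha=0.206$, $\beta=0.001$, $\delta=0.5115$,
$\gamma=0.001$, $b=10$, $q=5$, $\lambda=4.16$, $\delta_0=0.005$,
$\delta_1=0.006$ (rates per day). One nondimensional time unit is
$1/\delta \approx 1.955$ days; metrics use the exact conversion and
"about 2 days" only as a label.

```{r}
p <- nondimensionalize(table1_params())
p
```

Two scale choices are genuinely underdetermined and are therefore
explicit knobs:

* **Drug scale.** The rescaling defines $\phi = q/(\delta C_0)$
  against a characteristic drug concentration $C_0$ that is never
  fixed anywhere in the source analysis. The default `drug_scale = 1`
  gives $\phi = q/\delta \approx 9.78$. Usefully, the products that
  control the drug's dynamical effect, $\bar\delta_0\phi =
  \delta_0 q/\delta^2$ and $\bar\delta_1\phi$, are invariant to this
  choice, so every stability verdict that depends on the drug only
  through $\delta_0\phi$ is scale-independent.
* **Replication-rate convention.** $\beta$ carries the unit "per day
  per $10^6$ cells or virions". Under the default
  `beta_convention = "per-1e6-cells"`, state variables are measured in
  units of $10^6$ cells and $\bar\beta = \beta/\delta \approx 0.002$.
  The literal per-cell rescaling ($\bar\beta = \beta K/\delta$) is the
  convention under which the dimensional replication rates quoted for
  the virotherapy experiments ($10^{-6}$, $10^{-3}$) actually clear
  the tumor on the reported ten-day time scale, so the figure
  scenarios use `"per-cell"`. Both interpretations are runnable
  everywhere.

Because of these two ambiguities the published eigenvalue lists for
the drug-bearing interior states cannot be reproduced exactly at any
single configuration; the package instead verifies every catalogued
equilibrium by residual and every verdict by perturbation simulation,
and reports its own computed spectra. The one spectrum entry that is
convention-independent, the decoupled drug eigenvalue
$-\psi = -8.13$, is reproduced exactly.

## Drug pharmacokinetics in closed form

The drug equation is linear, so each schedule has an exact solution
(`drug_solution()`), used as an oracle for the integrator and for the
long-time behaviour (`drug_limit()`): the constant schedule converges
monotonically to $\phi/\psi$; the bolus decays to zero (with the
degenerate closed form $(C_0+\phi t)e^{-\psi t}$ handled explicitly
when $a = \psi$); the sinusoidal schedule converges to a *periodic
attractor* with mean $\phi/(2\psi)$, amplitude
$\phi/(2\sqrt{\psi^2+4a^2})$, and period $\pi/a$. The source analysis
asserts a constant limit for the sinusoidal case; the pointwise limit
does not exist, so the package reports the orbit-level description,
which is what its tests can and do verify. The printed sinusoidal
closed form is typeset-damaged; the implementation derives the
particular solution directly and validates it against quadrature
rather than transcribing it.

## Integration

All reference trajectories use the classical fixed-step RK4 scheme
(`integrate_model()`), the method used for the model's published
simulations. The default step $h = 0.001$ resolves the stiffest
default rate ($\psi \approx 8$, so $\psi h \ll 1$); the tests verify
fourth-order convergence against the logistic closed form. State
components are concentrations, so the integrator clips negative
excursions below $10^{-12}$ in magnitude and aborts on anything
larger or non-finite, reporting the last valid time.

The delayed model (virus-infection delay $\tau_1$ on the infection
terms, drug-response delay $\tau_2$ on the drug-kill terms) is
integrated by the method of steps (`integrate_dde()`): RK4 stages
evaluate delayed states by cubic Hermite interpolation of the stored
node values and node derivatives, which preserves fourth-order
accuracy; the step is capped at half the smallest positive delay so a
stage never needs the solution inside the step being computed.
Histories are constant and equal to the initial state, matching the
reference simulation setup; general history functions would be a
straightforward extension. With both delays zero the delayed path
reproduces the ODE path exactly, and on the scalar test problem
$x'(t) = -x(t-\tau)$ the integrator is verified against the exact
piecewise-polynomial solution with clean $16\times$ error contraction
per halving of $h$.

## Steady states and local stability

`equilibria_*()` catalogue the closed-form steady states of each
variant: tumor-free, infected-tumor-free (carrying capacity), and
tumor-dormant families, with their existence conditions. Design
choices worth recording:

* The published constant-infusion dormant state carries $C=0$, which
  cannot be stationary when $\phi>0$; the catalogued state uses
  $C^*=\phi/\psi$ (the published $U$-coordinate is recovered). The
  analogous sinusoidal states printed with a nonzero drug level at
  $W=0$ are corrected to $C^*=0$, with a note in the state's
  condition string.
* The published interior dormant coordinates are sprawling rational
  expressions with visible typesetting damage; the package re-derives
  them from the stationarity conditions (for effective drug level
  $C_e$: $U^* = \gamma(1+\delta_1 C_e)/(\beta(b-1-\delta_1 C_e))$,
  then $I^*$ and $V^*$ linearly) and always passes candidates through
  `refine_steady_state()`, a damped Newton polish that errors if a
  candidate moves more than 10% — the guard that would catch a wrong
  closed form. Refined coordinates are authoritative; residuals are
  below $10^{-9}$ across random admissible parameter draws.
* The exponential schedule is autonomized exactly via
  $W = \phi e^{-at}$, $W' = -aW$ (adding a stable $-a$ eigenvalue).
  The sinusoidal substitution $W = \phi\sin^2(at)$ is non-smooth and
  non-unique at $W \in \{0, \phi\}$, so it is used only to catalogue
  equilibria: $W$ enters as a frozen forcing level, stability is
  assessed on the drug-bearing core at that level, and the simulator
  always integrates the nonautonomous $\xi(t)$ directly.

`classify()` computes the numeric Jacobian spectrum (analytic
Jacobians, cross-checked against central differences in the tests)
and reports stable/unstable/marginal with a $10^{-9}$ marginality
band; printed closed-form conditions (e.g. $\delta_0\phi > \alpha\psi$
for the tumor-free state, the Routh–Hurwitz inequalities
$a_0,a_1,a_2>0$, $a_1a_2>a_0$ for cubics) are evaluated alongside the
spectrum, never in place of it, because several printed conditions
contain evident typos (one states $\beta+\gamma > \beta\gamma$ where
the adjacent algebra requires $b\beta$). `verify_by_simulation()`
closes the loop: stable verdicts must contract random perturbations,
unstable ones must expel a perturbation along the unstable
eigendirection (random directions can land on invariant boundary
faces), with the asymptotic trend fitted over the second half of the
horizon to be robust to non-normal transient amplification.
`dulac_divergence()` implements the weighted-divergence exclusion of
periodic orbits for the planar chemotherapy system
($g = 1/(UC)$ gives $-\alpha/C - \phi/(UC^2) < 0$).

## Delay-induced stability loss

Linearizing the delayed chemotherapy system about its tumor-free
state gives the transcendental characteristic function
$f(\lambda) = (\lambda+\psi)(\lambda-\alpha+e^{-\lambda\tau_2}
\delta_0\phi/\psi)$. Purely imaginary roots $\pm i\omega$ exist iff
$\delta_0\phi/\psi > \alpha$, with
$\omega = \sqrt{(\delta_0\phi/\psi)^2-\alpha^2}$ and critical delays
$\tau_{2k} = (\arccos(\alpha\psi/(\delta_0\phi)) + 2k\pi)/\omega$.
The published critical-delay formula has the form $1/\omega +
\arccos(\cdot)$, which fails direct substitution into the real and
imaginary part equations; the crossing form above passes it to
$10^{-9}$ and is what `hopf_frequency()` returns. Likewise the
published existence condition is stated with the inequality reversed
relative to its own derivation; the implementation follows the
algebra ($\delta_0\phi/\psi > \alpha$). The degenerate pair
($\tau_2 = \psi/(\delta_0\phi)$ with equality) produces a double zero
root and is flagged as a boundary case rather than labelled stable.

`rightmost_root_scan()` locates characteristic roots in a complex
window by the argument principle with adaptive phase tracking along
the contour, bisection until a sub-box isolates one root, and complex
Newton polish; contours passing near a root are jittered with a
notice. The tests verify that the rightmost root of the reduced
factor crosses zero within $10^{-3}$ of $\tau_{2,0}$.

## Scenarios, metrics, and the packaged experiments

`run_scenario()` reproduces the reference experiment configurations:
chemotherapy alone under the three schedules (initial state $U_0=0.8$,
$C_0=0.2$), virotherapy alone across $\beta \in \{10^{-6},10^{-3}\}$
and $b \in \{10,100\}$, the combination under each schedule (the
figure caption and the accompanying text disagree on the burst sizes,
so both parameterizations ship, as `fig3-caption-*` with
$b\in\{2,5\}$ and `fig3-text-*` with $b\in\{15,25\}$), and the
delayed combination across $\tau_1 \in \{0.001,0.01\}$,
$\tau_2 \in \{0.001,0.1,0.3\}$. Default initial concentrations are
$U_0=1$, $I_0=0$, $V_0=0.1$, $C_0=0.1$. Everything is deterministic;
repeated runs are byte-identical.

The headline metric is the **clearance time**: the first grid time at
which the tumor burden $U+I$ falls below a threshold *and stays
below it* (the persistence requirement keeps transient dips from
counting). The threshold default, $10^{-3}$ of carrying capacity
($10^3$ cells), operationalizes "reduced to zero", which the source
never defines; it is an exposed knob. `compare_infusions()` runs the
three schedules at equal $\phi$ and ranks them by terminal tumor
burden; under the reference conditions the single bolus ranks worst,
in line with the qualitative claim that constant and periodic
delivery outperform a single injection — while administering a small
fraction of the drug.

## What the tests do and do not show

The test suite verifies the machinery against independent oracles
(closed forms, an LSODA reference integrator, eigen-decompositions,
finite differences, the argument principle) and the model-level
claims under the reference conditions: chemotherapy alone never
clears the reference tumor; clearance accelerates with burst size and
replication rate; the combination clears faster than virotherapy
alone; clearance time grows with the virus-infection delay $\tau_1$.

One published claim does **not** reproduce and its check is left
failing by design: that clearance time also grows with the
drug-response delay $\tau_2$ over $[0.001, 0.3]$. In every
Table-consistent regime in which the tumor is cleared at all, the
virus does the clearing, and delaying the drug-response terms delays
the $\delta_1 IC$ kill of infected cells — leaving more virus
factories alive and *slightly speeding* clearance (about 0.03 time
units over the whole $\tau_2$ range). Because
$\bar\delta_0\phi/\psi = \delta_0 q/(\delta\lambda) \approx 0.012 \ll
\alpha$ regardless of the unknown drug scale, no admissible scale
choice makes the drug strong enough to flip this sign.

Other limitations to keep in mind: the model is well-mixed and
avascular (no spatial structure, no immune response, no resistance);
the infusion schedules are idealized; parameter values are fitted
murine values plus two estimated drug-kill rates; positivity and
boundedness are enforced and tested numerically rather than proved;
and the simulated clearance of a tumor within days is, as the source
itself concedes, optimistic relative to clinical experience. Problem
sizes in the shipped tests (horizons of 5–30 time units, steps of
$10^{-3}$–$2\times10^{-2}$, 6–20 random parameter draws per property)
were chosen to exercise every code path at comfortable numerical
margins.
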