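---
title: "Models and methods in myoperf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in myoperf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`myoperf` personalizes a multiscale model of coronary and myocardial blood
flow against two kinds of clinical information: cardiac-function
measurements (cuff pressures, stroke volume, ejection fraction) and the
*relative* distribution of myocardial blood flow (MBF) across
vessel-specific perfusion territories, of the kind produced by dynamic CT
perfusion imaging. The package works at desk scale: every 3D flow problem
the original workflow solved with a finite-element Navier–Stokes code is
represented here by its 0D (lumped-parameter) surrogate, which is also the
model the personalization loops themselves operate on. A seed-reproducible
synthetic-patient generator replaces clinical imaging so that the entire
pipeline is testable without data downloads.

# The closed-loop 0D circulation

The circulation is a circuit: node pressures $P$ (dyn/cm$^2$), element
flows $Q$ (mL/s), chamber volumes $V$ (mL). Vessel segments carry a
Poiseuille resistance $R = 8\mu l/(\pi r^4)$, an inertance
$L = \rho l/(\pi r^2)$ and a wall compliance
$C = 3\pi r^3 l/(2Eh)$, with blood viscosity $\mu = 0.04$ P and density
$\rho = 1.06$ g/cm$^3$. The four heart chambers are time-varying elastance
elements $P = E(t)\,(V - V_0)$ with a raised-cosine activation between
$E_{\min}$ and $E_{\max}$; valves are smooth diodes (open resistance,
large leak resistance, sigmoid blending over ~20 dyn/cm$^2$) so the system
stays $C^1$ and plain Newton iteration converges. Each coronary outlet
carries the standard three-resistor boundary block
$R_a$–$R_\mu$–$R_v$ with a grounded capacitance $C_a$ at the
microvascular node and an intramyocardial capacitance $C_{im}$ referenced
to a scaled chamber pressure. The microvascular pressure observable is
$P_\mu = P - Q R_a$.

Two numerical paths solve this network:

* `simulate_lpn()` integrates the full DAE with backward Euler (Newton per
  step, step halving on divergence; C++ core) to periodic convergence —
  default `dt = T/2000`, periodicity tolerance $10^{-3}$, at most 20
  cycles. Halving the default step moves systolic pressure by < 0.2 mmHg.
* `steady_solve()` solves the resistive skeleton (capacitors open,
  inductors short) exactly; it reproduces cycle averages of the pulsatile
  solve within ~3% on coronary blocks and is the fast inner model of the
  flow-tuning loops.

**Intramyocardial pressure.** The reference is a fixed scaled chamber
pressure — left-tree outlets $1.0\,P_{LV}$, right-tree $0.5\,P_{LV}$ —
rather than a `max()` of chamber pressures, keeping the mass matrix
constant. With the canonical total coronary distal capacitance of
$10^{-6}$ cm$^5$/dyn the resulting phase shift of coronary inflow is weak;
strong diastolic dominance requires a larger intramyocardial compliance
than that total allows. We keep the canonical constant as the default and
note this as a known limitation of the 0D surrogate at that setting.

# Perfusion territories and flow targets

Every LV mesh node is assigned to the nearest coronary outlet point
(Euclidean distance, ties to the lowest outlet id); an alternative
centerline-distance metric is available. Integrals over territories use
node-centered control volumes (one quarter of each adjacent tetrahedron),
which makes volume and flow conservation exact by construction. Nodal MBF
in mL/min per 100 mL converts to absolute flow as
$\sum_i \mathrm{mbf}_i\, cv_i / 100 / 60$.

Flow targets are *fractions* of total LV flow — perfusion CT is trusted
for the distribution but not the absolute flow. The total itself comes
from the morphometric rule $Q_{LV} = 3.41\,V_{LV}^{0.75}$ mL/min, with a
20% supplement for branches not perfusing the LV. Murray-law targets
split flow as diameter$^{2.6}$ and serve as the conventional baseline.

# Darcy perfusion model

Myocardial perfusion is a single-compartment porous medium:
$-\nabla\cdot(k\nabla p) + (\beta_{src}+\beta_{snk})\,p =
\beta_{src}\,p_{src} + \beta_{snk}\,p_{snk}$, solved with linear
tetrahedral finite elements, consistent mass matrices, and natural
zero-flux boundaries ($k = 2\times10^{-5}$ cm$^2$Pa$^{-1}$s$^{-1}$,
$p_{cap} = 15$ mmHg, $p_{snk} = 0$). The conductances follow
$\beta_{src} = Q_{LV}/(V_{LV}(\bar p_{src}-p_{cap}))$,
$\beta_{snk} = Q_{LV}/(V_{LV}(p_{cap}-p_{snk}))$. Substituting a uniform
$p_{src} = \bar p_{src}$ gives the closed form $p \equiv p_{cap}$ and
total MBF $= Q_{LV}$ exactly — preserved to machine precision because the
mass terms are assembled consistently, and used as an exact acceptance
test. The problem is linear, so the "iterate to steady state" of the
original workflow is a single SPD solve here. The solver converges at
second order against a manufactured solution.

Because the diffusion length $\sqrt{k/(\beta_{src}+\beta_{snk})}$ is about
0.9 cm at these parameters, MBF leaks across territory boundaries; with
strongly dispersed synthetic truth this pulls simulated MBF fractions
toward volume-proportional values, and per-territory MBF errors are
accordingly larger than the per-outlet flow errors. The imaging-informed
vs diameter-law *ordering* is unaffected.

# Synthetic vascular trees

Constrained constructive optimization grows one independent binary tree
per LV territory, totalling 500 terminals allocated to territories by
volume (largest-remainder rounding, at least one per territory). Each new
terminal must keep a distance $0.5\,(V/n)^{1/3}$ from the existing tree
(relaxed by 0.9 per failed round of 10 attempts) and is connected at the
volume-minimizing bifurcation point among its 5 nearest segments
(Nelder–Mead over the 3D position; the optimized connection never costs
more than the naive midpoint connection, which is asserted in tests).
Terminal flows are equal within a territory, so radii follow
$r = r_{root}(Q/Q_{root})^{1/3}$ — Murray's bifurcation law with
$\gamma = 3$ holds exactly at every junction until the 300 µm radius
floor clamps. Each tree is seeded independently (`seed + outlet index`).

Radius personalization propagates per-outlet scale factors rootward as the
maximum over daughters, capped by the (already updated) parent radius;
image-based geometry is never rescaled and caps the synthetic roots.

# Two-stage personalization

**Stage 1 (cardiac function).** Restarted Nelder–Mead (tolerance 0.1 on
the percent objective spread, 200 iterations per restart, simplex step 0.1
of each range, up to 50 restarts with seeded jitter) minimizes the mean
relative error over systolic/diastolic pressure, stroke volume and
ejection fraction. The parameter specification is data-driven
(`default_stage1_spec()`, shipped as JSON): chamber elastances, LV
unstressed volume, activation duration, systemic resistance and
compliances, pulmonary resistance, venous filling pressure, total coronary
resistance — faithful in role to the published 36-parameter set, collapsed
to what four targets can identify. Three deliberate engineering choices:
evaluations run on a lumped coronary equivalent (cardiac metrics are
insensitive to the coronary split); every evaluation is a cold start,
because in a closed loop the initial state fixes the conserved blood
volume and warm starts would disconnect the filling parameter from the
objective; and the restart loop exits early when restarts stop improving
the objective by more than the stated tolerance. Tuning integrates at
`dt = T/500`; the returned error is re-verified at `T/1500`.

**Stage 2 without trees.** Per-outlet resistance scale factors in
$[0.5, 2.0]$, renormalized at every evaluation to preserve the total
parallel outlet resistance, are optimized against the imaged flow
fractions on the hyperemic steady surrogate (distal resistances scaled by
0.24). Then the split $R_a/R_\mu$ (initially 0.38, venous share fixed at
16%) is updated twice directly from pulsatile simulations:
$R_a = (\bar P - p_{src})/\bar Q$, holding each outlet's total fixed,
where $p_{src} = \mathrm{MBF}_{V_i}/(\beta_{src}V_i) + p_{cap}$ inverts
the perfusion integral.

**Stage 2 with trees.** With 500 outlets the scale-factor search is
intractable, so the loop alternates analytic updates on the steady
surrogate: (1) set each distal resistance to
$R_{tot}Q_{LV}/Q_{reqd} - R_{path}$, dilating synthetic paths by
$\alpha = (R_{path,syn}/\tilde R_{path,syn})^{1/4}$ wherever that value
would fall below a floor of 5% of the mean outlet resistance, until the
mean flow error is below 5%; (2) compare outlet pressures with
$P_{reqd} = p_{src} + Q_{reqd}R_a$ and dilate/constrict all trees toward
the required path resistances; repeat until both errors are below 5%.
$R_{tot}$ is referenced to the model's own hyperemic total
($R_{tot} = P_{aorta}/Q_{LV}$, $P_{aorta}$ = measured mean arterial
pressure), which makes the update formula an exact fixed point when flows
match. Convergence is typically ~10 outer iterations; the pressure error
decays geometrically because parent-radius caps limit each dilation step.

# The synthetic patient (what a green test establishes)

The generator emulates the *processed outputs* of the imaging pipeline,
not the imaging itself: a truncated prolate-spheroid LV shell (~90 mL
wall volume) meshed by structured parametric subdivision into conforming
tetrahedra; an epicardial tree with 16 LV-perfusing outlets on the
epicardial surface plus 2 proximal right-coronary branches that do not
perfuse the LV, radii by Murray splitting of the left/right mains; ground
truth per-outlet flows that are Murray shares perturbed by lognormal
multipliers with $\sigma = 0.4$ — reproducing the central clinical
phenomenon that true flow distributions deviate unpredictably from any
diameter law; and a nodal MBF field that integrates exactly to those
flows per territory, with multiplicative lognormal noise (CV 0.2)
renormalized territory-by-territory. Cardiac targets default to a
measured reference row (137/73 mmHg, SV 40.4 mL, EF 0.65) at 70 bpm (heart
rate is not part of the printed table; chosen once as typical).

What the generator does *not* emulate: stenosed lumens (all FFR values on
synthetic patients are near 1), image noise and segmentation variability,
fiber-oriented anisotropic perfusion, scar. A green pipeline test
therefore establishes that the estimation machinery recovers dispersed
flow distributions that diameter-based rules cannot — it does not validate
against real hemodynamic waveform morphology or ischemia detection.

# Numerical choices and degenerate inputs

* One unit system internally (CGS); clinical units convert exactly once at
  interfaces, with 1 mmHg = 1333.22 dyn/cm$^2$ (the constant used across
  closed-loop hemodynamics codes).
* Backward Euler was chosen over higher-order schemes for robustness of
  the valve-switching DAE; the periodicity check is blockwise-relative on
  pressures, flows and volumes.
* Voronoi ties break to the lowest outlet id; territory integrals use
  exactly conservative control volumes.
* Degenerate CCO connections (any new segment under 1 µm) are rejected
  with a finite penalty; spacing relaxations are logged.
* The with-trees loop raises an explicit infeasibility error naming the
  outlet if the epicardial path alone already exceeds the admissible path
  resistance.

# Known limitations

* The 0D surrogate cannot represent stenosis-specific or junction losses
  (an optional quadratic stenosis element exists but is off by default),
  so FFR along unstenosed synthetic anatomy is a smooth mild decline.
* The coronary flow waveform is only weakly out of phase at the canonical
  coronary capacitance (see above).
* MBF-fraction errors are dominated by Darcy inter-territory diffusion at
  the published permeability.
* One-way coupling only: perfusion does not feed back on the coronary
  network.
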