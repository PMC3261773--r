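---
title: "Pseudo-plateau bursting as a canard-induced mixed mode oscillation"
author: "lactoburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-plateau bursting as a canard-induced mixed mode oscillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactoburst)
```

## The model

Pituitary lactotrophs fire short bursts of small spikes riding on a
depolarized plateau ("pseudo-plateau bursting").  The model behind this
package is a minimal conductance-based description with three state
variables: the membrane potential $V$ (mV), the delayed-rectifier K$^+$
activation $n$, and the cytosolic Ca$^{2+}$ concentration $c$ (µM):

$$
C_m \frac{dV}{dt} = -\left(I_{Ca} + I_K + I_{K(Ca)} + I_{BK}\right),\qquad
\frac{dn}{dt} = \frac{n_\infty(V) - n}{\tau_n},\qquad
\frac{dc}{dt} = -f_c\left(\alpha I_{Ca} + k_c c\right),
$$

with $I_{Ca} = g_{Ca} m_\infty(V)(V - V_{Ca})$,
$I_K = g_K n (V - V_K)$,
$I_{K(Ca)} = g_{K(Ca)} s_\infty(c)(V - V_K)$ and
$I_{BK} = g_{BK} b_\infty(V)(V - V_K)$.  The voltage-dependent gates
$m_\infty, n_\infty, b_\infty$ are Boltzmann functions; SK-channel
activation $s_\infty(c) = c^2/(c^2 + K_d^2)$ is a Hill function of
order 2.  Units are fixed throughout to mV, ms, pF, nS, pA and µM, so
that nS·mV = pA and pF/nS = ms and no hidden scaling is required
anywhere.  `lacto_pars()` carries the standard parameter values of the
lactotroph model; every scan works on immutable modified copies
(`set_pars()`), which rules out aliasing bugs in grid sweeps.

The three variables are fast ($V$, $\tau_V = C_m/g_{Total} \sim$ a few
ms), intermediate ($n$, 43 ms) and slow ($c$, $1/(f_c k_c) = 625$ ms).
The package treats $C_m$ as the singular-perturbation dial: sending
$C_m \to 0$ makes $V$ infinitely fast and exposes the geometry that
organises the bursting.

## One fast, two slow: the critical manifold

With $f(V,c,n) = -(I_{Ca}+I_K+I_{K(Ca)}+I_{BK})$, the critical manifold
$f = 0$ is an explicit graph $n = n(c,V)$ (`n_of()`).  It is folded:
two fold curves $L^\pm$ (where $\partial f/\partial V = 0$) separate
attracting upper/lower sheets from a repelling middle sheet.
Eliminating the lumped linear conductance between $f = 0$ and
$\partial f/\partial V = 0$ leaves one scalar equation in $V$ alone, so
the folds sit at two constant voltages independent of both $c$ and
$g_K$ — a structural fact the test suite checks directly.
`fold_voltages()` locates them by a dense sign scan on
$[-75, 50]$ mV followed by bisection; with the default conductances
they sit near $-61.0$ and $-22.8$ mV.

The reduced flow on the manifold is singular on the folds.  Rescaling
time by $-(\partial f/\partial V)^{-1}$ yields the desingularized
system in $(V, c)$ (`desing_rhs()`), smooth everywhere, with time
reversed on the repelling sheet.  Its equilibria are of two kinds:

* **ordinary singularities** — true equilibria of the full model, on
  the Ca$^{2+}$ balance curve CN1 ($c = -\alpha I_{Ca}/k_c$);
* **folded singularities** — points on $L^\pm$ where the flow crosses
  the fold with zero desingularized velocity; they are not equilibria
  of the full model but organise how trajectories traverse the fold.

Both are classified spectrally from an analytic $2\times 2$ Jacobian
(`desing_jacobian()`), obtained by hand differentiation and validated
against central finite differences in the tests.  The analytic route
matters because the folded-node eigenvalue ratio
$\mu = \lambda_{weak}/\lambda_{strong}$ never exceeds about 0.07 here:
classification near the folded saddle-node boundaries needs more
accuracy than finite differences of a stiff expression reliably give.

A folded **node** on $L^+$ is the engine of the small spikes: for
$C_m > 0$ every trajectory entering its singular funnel makes up to
$S_{max} = \lfloor (\mu+1)/(2\mu) \rfloor$ rotations while crossing the
fold.  `mu_profile()` traces $\mu$ and $S_{max}$ across the
folded-node window.

## Singular orbits and the funnel distance delta

`build_singular_orbit()` concatenates desingularized flow on the
attracting sheets with vertical (fast-fibre) jumps at the folds and
iterates the resulting one-dimensional return map in the Ca$^{2+}$
coordinate of the jump-down point.  The map contracts slowly near the
spiking/bursting boundary (ratios around 0.8 per cycle), so plain
iteration is Aitken-accelerated; convergence is declared at
$10^{-8}$ µM.  When the upper-sheet segment enters the funnel the
integration is stopped within $10^{-4}$ state units of the folded node
and the jump is taken from the node itself, which is where the orbit
leaves in the singular limit.

The **strong canard** — the unique trajectory entering the folded node
along its strong eigendirection — is computed by backward integration
from a displacement of $10^{-4}$ along that eigenvector
(`strong_canard()`; both signs are tried and the branch that stays on
the upper sheet is kept).  Together with $L^+$ it bounds the singular
funnel.

The discriminating quantity is the funnel-entry distance $\delta$
(`delta_of()`): the position of the orbit's landing point on the
projection $P(L^-)$ relative to the strong canard.  Since $P(L^-)$ is a
graph over $c$, $\delta$ is measured as a *signed Ca$^{2+}$
difference*, not an arc length; the zero set — all the theory uses —
is identical, and the sign convention ($\delta > 0$ inside the funnel)
is fixed dynamically by testing which side of the canard actually
funnels into the node.  $\delta > 0$ predicts mixed mode oscillations
(bursting), $\delta < 0$ relaxation oscillation (spiking); the package
verifies this prediction against full-system simulations at
$C_m = 0.5$ pF in its test suite.

## Bifurcation scanning

All two-parameter structure in $(g_K, g_{BK})$ is traced by per-slice
bisection of scalar test functions; no continuation machinery is used,
because every boundary here is the zero of a smooth scalar that is
monotone near its zero, and bisection is robust through the folded
saddle-node degeneracies:

* `find_TR()` — type II folded saddle-node (transcritical): the
  ordinary singularity crosses a fold; test function is its distance
  to the fold voltage.
* `find_SN()` — type I folded saddle-node: a folded node and folded
  saddle coalesce; test function is the root count of $F$ along the
  fold line.
* `find_focus_node()` — discriminant of the desingularized Jacobian at
  a tracked folded singularity.
* `find_fold_merge()` — double root of the fold-voltage equation
  (independent of $g_K$), where the manifold loses its fold entirely.
* `find_codim2_on_merge_line()` — the point on the merged fold line
  beyond which it carries no folded singularities.
* `trace_delta_zero()` — the $\delta = 0$ boundary, by bisecting
  $\delta$ in $g_K$ inside the folded-node window per $g_{BK}$ slice.

With the default parameter set these give, at $g_{BK} = 0.4$ nS, the
ordering TR1 $<$ SN1 $<$ focus–node $<$ TR2 $<$ SN2
(≈ 0.513, 7.59, 43.1, 129, 137 nS).  The folded-singularity searches
use a Ca$^{2+}$ window of $[0, 1.4]$ µM plus an extended negative
window $[-1, 0)$ whose hits are flagged nonphysical: the folded-saddle
partner of the physical folded node sits at negative $c$ over part of
parameter space, and the type I coalescence happens there, so the
negative window is needed to detect SN1/SN2 at all even though no
trajectory with $c \ge 0$ ever visits those points.

`build_region_map()` labels a parameter grid by its fold and
folded-singularity inventory (depolarized steady / folded node on
$L^+$ / folded singularities on $L^-$ / hyperpolarized steady / no
folds), which reconstructs the qualitative two-parameter diagram.

## Full-system simulation and burst features

`simulate_lacto()` integrates the full model with `deSolve::lsoda` and
a compiled right-hand side (rtol $10^{-8}$, atol $10^{-10}$ by
default; 60 s of model time with a 20 s discarded transient, doubled
automatically when fewer than three cycles are found).
`full_hopf_slice()` finds the Hopf bifurcation of the full system by
bisecting the leading eigenvalue real part of the analytic Jacobian at
the depolarized equilibrium; as $C_m \to 0$ this Hopf collapses onto
the TR1 curve of the desingularized system (the tests require
agreement within 1% at $C_m = 0.01$ pF).

`extract_features()` reduces a voltage trace to regime, period, active
phase duration and spikes per burst:

* **cycles** are delimited by minima of the slow variable $c$,
  restricted to the lower quarter of the $c$ range so that per-spike
  ripple minima inside the active phase are ignored;
* **active phase** is time with $V$ above a threshold, $-40$ mV by
  default — pseudo-plateau silent phases sit well below it, and the
  value is exposed in the interface and reported with results;
* **spikes** are strict local maxima above the threshold, judged by
  topographic prominence (each peak is measured against the nearest
  higher sample on either side, which makes the count robust to noise)
  with a default floor of 0.5 mV; the cycle's global maximum is the
  burst envelope top, and it counts as a spike only when it rises
  above the active-phase median, so a flat but noisy plateau
  contributes no spurious spike.  Peak detection runs on a lightly
  smoothed copy of $V$ (5 ms moving average) while all threshold
  measures use the raw trace.
* **regime**: steady if the voltage range is under 1 mV; spiking if
  exactly one prominent maximum per cycle; bursting otherwise.

The 0.5 mV prominence default separates visible spikes from solver
ripple in ordinary use.  Near the Hopf-side border of the bursting
region, however, the mid-burst canard rotations decay geometrically
through many decades of amplitude (down to $10^{-8}$ mV within a
single burst) with no natural gap, so *any* millivolt-scale cut
undercounts rotations there.  The map of burst extremes
(`max_spikes_scan()`) therefore counts rotations with a prominence
floor of $10^{-4}$ mV — safely above the integrator ripple at the
tolerances it uses (rtol $10^{-11}$) and far below the smallest
physically grown rotation it needs to resolve.  The rotation count is
necessarily a function of this floor; it is reported together with the
protocol so the number is reproducible.

The scan protocol itself: for each $g_{BK}$ in a fixed grid
(0.5–2.5 nS), locate the full-system Hopf in $g_K$, walk outward in
0.25 nS steps until the bursting attractor appears (the mid-spike
initial condition $(-20\ \mathrm{mV}, 0.05, 0.3\ \mathrm{µM})$ is used
because the band next to the border is bistable with continuous
spiking, and the hyperpolarized start lands on the spiking attractor),
bisect the spiking/bursting border to 0.01 nS, and measure one fixed
0.01 nS step inside it.  Spikes per burst and active-phase duration
increase monotonically toward the border, so the border step — not a
grid optimum — determines the reported maximum; with these settings
the longest bursts have active phases of 8–9 s and several dozen
rotations.  These problem sizes (five slices, 160 s simulations)
keep a full scan in the ten-minute range on one core.

## Two-fast/one-slow comparison

`build_zcurve()` performs the complementary classical decomposition:
equilibria of the $(V, n)$ fast subsystem as the slow $c$ varies, with
fold and Hopf points located by bisection in $c$, and the $c$-nullcline
overlay giving the full-system equilibria.  Hopf criticality is
labelled by numerical probing — integrating the fast subsystem just on
the unstable side from a tiny perturbation and asking whether the
oscillation saturates at small amplitude (supercritical) or escapes to
a distant attractor (subcritical) — rather than via a first-Lyapunov
coefficient, which the qualitative use here does not need.  The package
reproduces the known negative result: at $g_K = 5.1$ nS the z-curve is
bistable (normally read as "bursting possible") yet the full system
spikes continuously, while the one-fast/two-slow quantity $\delta < 0$
predicts exactly that.

## Synthetic traces

`synth_spec()`/`make_trace()` generate surrogate voltage traces with
known ground truth: silent phase at a baseline voltage, active phase at
a plateau carrying a chosen number of evenly spaced raised-cosine
spikes, Gaussian noise, and a matching sawtooth Ca$^{2+}$ channel so
that the extractor's cycle segmentation is exercised end to end.  The
raised-cosine width (half the inter-spike distance) makes each spike's
prominence exactly the specified amplitude, so detector thresholds can
be tested deliberately.  What these fixtures do *not* emulate is the
model's waveform detail — decaying rotation amplitudes, drifting
plateaus, stiff jump transients — so passing recovery tests
demonstrates correctness of the feature logic, not end-to-end accuracy
on arbitrary electrophysiological recordings.

## Numerical choices and limitations

* Root finding is dense-scan-plus-bisection everywhere; all scans are
  deterministic, and bisection tolerances (1e-6 nS for bifurcation
  parameters, 1e-10 mV for fold voltages) are stated alongside
  results.  Results are required (by test) to be invariant under
  halving the tolerance.
* Boltzmann exponents are clamped at $\pm 500$; saturation is exact to
  double precision far before the clamp engages.
* Degenerate double roots at a folded saddle-node resolve to either a
  near-tangent pair or no root at the scan resolution; boundaries are
  always located by bisection on the count, never by trusting a single
  scan.
* The reduced-flow integrations use `lsodar` with rtol $10^{-10}$ and
  event roots for fold crossings ($10^{-7}$ mV effective tolerance),
  folded-node approach and window exit; paths are re-integrated over
  the detected span for dense output.
* Secondary canards as explicit curves, twisted slow-manifold surfaces,
  Floquet-based period-doubling continuation and the A-type K$^+$
  current are out of scope; rotation counts are exercised only through
  $S_{max}$ and spike counting in simulations.
* The $\delta$ computation requires both a folded node and a strong
  canard that reaches $P(L^-)$; outside the folded-node window the
  quantity is undefined and the functions say so rather than
  extrapolate.
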