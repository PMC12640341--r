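---
title: "A spherical-cap continuum model of contact-inhibited colony growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spherical-cap continuum model of contact-inhibited colony growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonycap)
```

## The model

`colonycap` simulates a cell colony growing on a flat plate as a continuum:
two coupled ordinary differential equations track the number of cells in the
basal layer, $N_{L1}$, and in the whole colony, $N_{TOT}$, while a
spherical-cap shape assumption converts those counts into colony dimensions
at every instant.

An isolated cell divides and matures by a first-order process with lumped
rate constant $k$ (min$^{-1}$), so a dilute culture grows as
$N(t) = N_0 e^{kt}$. Two mechanisms slow this down in a colony:

* **Contact inhibition.** Cells fully surrounded by neighbours divide at a
  rate scaled by the transition parameter $\gamma \in [0, 1]$: $\gamma = 1$
  means no inhibition, $\gamma = 0$ complete arrest of internal cells
  ($\beta = 1 - \gamma$ is the inhibition extent). Every sub-population is
  therefore split into a *perimeter* class dividing at full rate and an
  *internal* class dividing at rate $\gamma k$.
* **Growth anisotropy.** The rate constant is resolved into directional
  fractions $f_x = f_y$ and $f_z$ ($f_x + f_y + f_z = 1$), giving aggregate
  rates $k_\parallel = (f_x + f_y)k$ parallel to the plate and
  $k_\perp = f_z k$ perpendicular to it. The degree of anisotropy is
  $\Gamma = \tfrac{1}{2} k_\parallel / k_\perp$: 1 is isotropic, above 1
  laterally favoured, below 1 vertically favoured. Anisotropy is a
  surface-induced effect, so only basal-layer cells feel it; cells above the
  basal layer divide with the full lumped $k$.

### Geometry closure

The basal layer is a circle of $N_{L1}$ cells at two-dimensional packing
efficiency $F_{2D}$, so its radius is $r_{L1} = r_C \sqrt{F_{2D} N_{L1}}$
for cell radius $r_C$. The colony volume is bookkept as
$V_{COL} = N_{TOT} F_{3D} \tfrac{4}{3}\pi r_C^3$ with
$F_{3D} = F_{2D}^{3/2}$ by default. The colony itself is assumed to be a
spherical cap standing on the basal circle, so its height solves

$$V_{COL} = \frac{\pi}{6}\left(h_{COL}^3 + 3 h_{COL} r_{L1}^2\right),$$

a strictly increasing cubic inverted numerically at every evaluation
(safeguarded Newton with a bisection fallback on the bracket
$[0, (6V/\pi)^{1/3} + 2 r_{L1}]$, relative tolerance $10^{-14}$, at most 200
iterations; in practice it converges in about six). The greater-sphere
radius follows from the chord relation $R = (r_{L1}^2 + h_{COL}^2)/(2
h_{COL})$. Both expressions are single algebraic identities valid for flat
(minor, $h \le r_{L1}$) and bud-like (major, $h > r_{L1}$) caps; the tests
verify they coincide with the piecewise sphere-minus-cap subtraction form on
the major side, and with brute-force disc integration everywhere, which
avoids any branch discontinuity at the hemisphere point.

Shape observables derived from the resolved cap are the composite parameter
$\Omega = h_{COL}/R$ (1 at a hemisphere, approaching 2 as the colony closes
into a detached sphere) and the receding contact angle
$\theta = 90^\circ - \sin^{-1}\!\big((R - h_{COL})/R\big)$ for
$h_{COL} \le R$, $\theta = 90^\circ + \cos^{-1}\!\big(r_{L1}/R\big)$ above;
the two branches meet continuously at $90^\circ$. Angles are reported in
degrees.

### Population partitions

Three perimeter/internal splits feed the derivatives:

* **Basal, in-plane** (`basal_inplane_split()`): the outer annulus of the
  basal disc holds approximately
  $(2\sqrt{F_{2D} N_{L1}} - 1)/F_{2D}$ cells. The expression is a geometric
  estimate, not an exact count, so it is clamped to $[0, N_{L1}]$ and the
  internal class is defined as the remainder — the partition then conserves
  $N_{L1}$ exactly by construction.
* **Basal, vertical** (`basal_vertical_split()`): division out of the plane
  is inhibited where layer two already covers layer one. With coverage
  $\eta = 1 - N_{L1}/N_{TOT}$, the perimeter (uncovered) class is
  $\tfrac{N_{L1}}{2}(1 - \eta)$ and the internal class
  $\tfrac{N_{L1}}{2}(1 + \eta)$. The linear form is used as stated; note it
  assigns a lone plated cell ($\eta = 0$) a half-inhibited vertical channel
  — a known quirk of the transition function, kept deliberately rather than
  patched.
* **Upper cap** (`upper_cap_split()`): the cells above the basal layer. The
  *total* is the population bookkeeping count $N_{TOT} - N_{L1}$, which is
  the volume ratio $V_{UC}/\big(F_{3D}\tfrac{4}{3}\pi r_C^3\big)$ once the
  basal-layer volume is identified with its cell count
  ($V_{L1} = N_{L1} F_{3D} \tfrac{4}{3}\pi r_C^3$ and
  $V_{UC} = V_{COL} - V_{L1}$). The *interior* part comes from geometry:
  the upper cap shrunk inward by one cell radius
  ($h'' = h_{COL} - 2 r_C\sqrt{F_{2D}} - r_C$, $R'' = R - r_C$), converted
  to cells and clamped to the total; the perimeter class is the remainder.

This pairing of a count-based total with a geometry-based interior was a
genuine design decision. A purely geometric upper-cap total (the reduced cap
with $h' = h_{COL} - 2 r_C\sqrt{F_{2D}}$ on the same sphere, available via
`upper_cap()` and the default mode of `upper_cap_split()`) does not equal
$N_{TOT} - N_{L1}$ — the one-layer slab does not hold exactly one cell
volume per basal cell — and wiring it into the dynamics would (i) break
conservation of cells between the sub-populations, (ii) destroy the defining
property that $\gamma = 1$ recovers pure exponential growth
$\mathrm{d}N_{TOT}/\mathrm{d}t = k N_{TOT}$, and (iii) make the three
anisotropy regimes differ even with inhibition switched off. With the
count-based total, all three properties hold exactly (the partitions
telescope and $k_\parallel + k_\perp = k$), which is what the model's
uninhibited limit demands.

### The coupled system

$$\frac{\mathrm{d}N_{L1}}{\mathrm{d}t} =
  k_\parallel\left[(N_{L1})^\parallel_{per} + \gamma (N_{L1})^\parallel_{int}\right]$$

$$\frac{\mathrm{d}N_{TOT}}{\mathrm{d}t} =
  \frac{\mathrm{d}N_{L1}}{\mathrm{d}t}
  + k_\perp\left[(N_{L1})^\perp_{per} + \gamma (N_{L1})^\perp_{int}\right]
  + k\left[(N_{UC})_{per} + \gamma (N_{UC})_{int}\right]$$

Both derivatives are nonnegative and
$\mathrm{d}N_{TOT}/\mathrm{d}t \ge \mathrm{d}N_{L1}/\mathrm{d}t$, so
$1 \le N_{L1} \le N_{TOT}$ is preserved from the initial condition
$N_{L1} = N_{TOT} = N_0 = 1$ (a single plated cell).

## Numerical choices

* **Integrator.** Explicit fixed-step classical Runge-Kutta (RK4), default
  `dt = 0.5` min. The system is smooth, non-stiff and two-dimensional, and a
  fixed step makes runs bit-reproducible; an adaptive stiff solver buys
  nothing here (a test cross-checks trajectories against `deSolve::lsoda` at
  tight tolerances). The geometry is re-resolved at every RK4 *stage*, not
  once per step, so the closure error enters at $O(\mathrm{d}t^5)$.
* **Dense output.** States are emitted at requested times by cubic Hermite
  interpolation of the step grid (values and derivatives at the bracketing
  nodes), which matches the integrator's accuracy without constraining the
  step to divide the output spacing.
* **Degenerate caps.** Reduced heights $h'$, $h''$ that fall to or below
  zero yield a well-defined empty cap (zero volume, no cells), so the
  monolayer-to-multilayer transition is continuous. For an all-basal colony
  the resolved height tends to the pancake constant
  $\tfrac{8}{3} r_C \sqrt{F_{2D}}$ (volume and base area both scale
  linearly in $N$), which is *above* the one-layer thickness
  $2 r_C\sqrt{F_{2D}}$ — a thin geometric sliver persists above the basal
  slab even for arbitrarily flat colonies, while its cell population is
  zero by the count bookkeeping.
* **No randomness.** Nothing in the model draws random numbers; repeated
  runs are byte-identical.

## Reference study conditions

The defaults reproduce the reference parameterization: a spherical cell of
diameter 2 um ($r_C = 1$ um), doubling time 90 min (so
$k = \ln 2 / 90 \approx 0.0077$ min$^{-1}$), $F_{2D} = 1.2$ for imperfectly
packed spheres (hence $F_{3D} = 1.2^{3/2} \approx 1.3145$; a configuration
override exists for users who prefer a measured value), a 3000-min horizon,
and three anisotropy regimes — isotropic ($f_z = 1/3$, $\Gamma = 1$),
laterally favoured ($f_z = 1/6$, $\Gamma = 2.5$) and vertically favoured
($f_z = 1/2$, $\Gamma = 0.5$) — crossed with
$\gamma \in \{0, 0.25, 0.5, 0.75, 1\}$. `run_growth_grid()` runs all
fifteen:

```{r grid, eval = FALSE}
grid <- run_growth_grid()
plot_grid_kinetics(grid, "N_TOT")
```

On the lumped rate: a doubling time of 90 min corresponds to
$k = \ln 2/90 \approx 0.0077$ min$^{-1}$, and that derived value is used
throughout (a configuration supplying both `k` and `t_double` resolves the
conflict in favour of the doubling time, with a warning, since the doubling
time is the directly measured quantity).

Two structural results characterize the grid. First, $N_{TOT}(t)$ is
nondecreasing in $\gamma$ at every time — more inhibition, fewer cells —
and at $\gamma = 1$ the three regimes collapse onto the same exponential.
Second, for $\gamma = 0$ the log-radius curve is concave throughout and the
log-height curve is concave once multilayer growth is established (roughly
$t \gtrsim 600$ min under the reference conditions): the
exponential-to-linear transition of colony dimensions. Height shows an
early convex kink around $t \approx 300$–$500$ min where the colony
switches from monolayer to multilayer growth and vertical expansion turns
on; this is model behaviour, not a numerical artefact. In the planar
fully-inhibited limit ($\gamma = 0$, $f_z = 0$) the front speed
$\mathrm{d}r_{L1}/\mathrm{d}t$ approaches $k_\parallel r_C$ with relative
deficit $r_C/(2 r_{L1})$, so reaching the asymptote to 1 % requires
$r_{L1} > 50\, r_C$ (about $10^4$ min at these rates).

## What the simulator does and does not emulate

The generator-of-record here is the model itself: deterministic, continuum,
shape-constrained. It emulates bulk colony kinetics — cell numbers, radius,
height, curvature, contact angle — for colonies that actually grow as
spherical caps, a regime with broad experimental support for bacterial and
yeast colonies and for anchorage-independent eukaryotic lines. It does not
represent nutrient depletion fields, mechanical stress and elasticity,
discrete-cell granularity, stochastic division noise, non-cap morphologies,
or colony-colony interactions. Passing tests therefore certify the
mathematics and numerics of this idealization, not agreement with any
particular culture experiment.

## Problem sizes used in the test suite

The suite exercises full-horizon (3000 min) runs for the fifteen-run grid
and the uninhibited-limit checks at the production step `dt = 0.5` min,
1000-cap random geometry sweeps against the disc-integration oracle,
six-decade aspect-ratio sweeps of the height inversion, and one
$10^4$-min planar run for the front-speed asymptote — sizes chosen so each
property is probed in the regime where it is informative.
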