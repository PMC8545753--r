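---
title: "The capillary-bridge model of fibrillar wet adhesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The capillary-bridge model of fibrillar wet adhesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capibridge)
```

## The problem

Many insects climb with hairy adhesive pads: arrays of cuticular setae whose
tips secrete femtolitre volumes of an oily fluid. Each wetted tip forms a
liquid bridge to the substrate, and the pad's pull-off force is, to a good
approximation, the sum of the capillary forces of those bridges. Because the
secretion is immiscible with water, the same mechanism can operate on a
submerged substrate — with the fluid's interfacial tension and contact angle
taking their underwater values — and a hydrophobic pad may additionally trap
an air bubble (a plastron, the Cassie state) among the hairs.

`capibridge` implements this model end to end: a solver for a single pinned
liquid (or gas) bridge, the wetting relation that supplies the underwater
contact angle, the pad-level superposition for the three contact modes
(in air, underwater without a bubble, underwater with a trapped bubble),
parameter studies built on top, and a small toolbox for reducing
experimental-style force recordings to pull-off forces.

## A single pinned bridge

The unit problem is an axisymmetric bridge of fixed volume $V$, pinned to a
circular rim of radius $R_\mathrm{pin}$ at height $d$ above a flat rigid
substrate that the bridge meets at its equilibrium contact angle $\theta$,
under interfacial tension $\gamma$. Two assumptions are load-bearing:

* **The contact line at the rim is pinned.** Discoidal hair tips are nearly
  circular, so the fluid anchors mechanically at the tip perimeter; no angle
  condition is imposed there. Pinning is what produces the characteristic
  *repulsive* force at small gaps: the fixed rim and fixed volume force the
  meniscus to bulge, giving a positive Laplace pressure.
* **Gravity is neglected.** At hair scale the Bond number
  $\rho g R^2/\gamma \lesssim 10^{-6}$; the equilibrium surface therefore
  has constant mean curvature, and the whole problem is scale free — forces
  are exactly linear in the length scale at fixed $(\theta, \phi, \gamma)$.
  This is a statement about the regime, not a configurable option.

Volumes are parametrized either directly or through the size parameter
$\phi = R_\mathrm{pin}/s$ with $s = (3V/4\pi)^{1/3}$ the equivalent-sphere
radius; $\phi = 2$ (the default in the sweeps) means the bridge volume is
that of a sphere of half the pin radius.

### Shooting backend

In reduced units (lengths over $R_\mathrm{pin}$, pressure times
$R_\mathrm{pin}/\gamma$) the profile is integrated in arc length $s$ with
tangent angle $\psi$ measured from the radial axis:

$$\frac{dr}{ds} = \cos\psi, \qquad \frac{dz}{ds} = \sin\psi, \qquad
\frac{d\psi}{ds} = p - \frac{\sin\psi}{r}, \qquad
\frac{dV}{ds} = \pi r^2 \sin\psi,$$

starting on the substrate at $(r, z, \psi) = (R_\mathrm{bottom}, 0,
\pi - \theta)$. The three unknowns — reduced Laplace pressure $p$, bottom
contact radius $R_\mathrm{bottom}$, and total arc length $S$ — are matched
by a damped Newton iteration to the three terminal conditions: the profile
ends on the rim ($r = 1$) at height $z = d$, and the enclosed volume equals
$V$. Treating $S$ as an unknown (rather than stopping on a height event)
keeps the formulation smooth even for reentrant profiles. The integrator is
a fixed-step fourth-order Runge–Kutta scheme in compiled code; 200 segments
by default, doubled until the force changes by less than 0.2%. Residuals
are driven below $10^{-10}$ (relative), and returned states conserve volume
to better than $10^{-6}$.

The vertical force on the substrate is evaluated at the bottom contact:

$$f = \Delta P \, \pi R_\mathrm{bottom}^2 \;-\;
      2\pi R_\mathrm{bottom} \gamma \sin\theta,$$

with attraction negative: a negative Laplace pressure over the wetted patch
pulls the substrate toward the bridge, and the contact-line tension always
pulls toward the liquid. Both components are reported separately.

### Energy-minimization backend

An independent backend discretizes the profile as $r(z)$ on a uniform
height grid and minimizes the interfacial energy

$$E = \gamma A_\mathrm{lv} - \gamma \cos\theta \cdot A_\mathrm{bottom}$$

at fixed volume with an augmented-Lagrangian BFGS scheme (the wetted-area
term is the Young–Dupré energy of the contact patch; the contact angle at
the substrate is not imposed and emerges from the minimization, as does the
Laplace pressure, via the volume multiplier). This is the brute-force
counterpart of a gradient-descent surface minimizer. The force is recovered
as $-\partial E/\partial d$ by centred differences of neighbouring
minimizations.

The two backends are genuinely independent — different unknowns, different
discretizations, different convergence machinery — and agree in force to
within 1% across a $5\times5$ grid of $(\theta, d)$ at $\phi = 2$
(typically much better; worst observed about 0.5%). Two analytic limits
anchor them: at $\Delta P \approx 0$ the profile must be a catenoid
$r = c\cosh((z - z_0)/c)$ (matched pointwise to 0.1%), and at $\theta =
90^\circ$ with zero pressure the force is the pure tension term
$-2\pi R_\mathrm{bottom}\gamma$.

### Reentrant shapes and the equivalence region

At small contact angles and squat gaps the equilibrium surface can overhang
its own pinning plane (the tangent angle leaves $(0, \pi)$). Such shapes
are not representable as $r(z)$, so the energy backend converges to the
best function-constrained surface instead and the two backends legitimately
disagree there; backend equivalence is therefore asserted on the
representable region. Overhanging states also imply the meniscus would
intersect the hair flank, which the model does not resolve; they carry an
`overhang` flag so downstream code can note the deviation. Only the
smallest-gap, most-wetting corner of the sweeps is affected.

### Rupture and branch selection

Force–distance curves are computed by continuation: each gap is
warm-started from the previous solution, which keeps the solver on the
equilibrium branch connected to contact (the branch a descending energy
minimizer would track). Rupture is the loss of that branch — a turning
point of the continuation — not a Plateau–Rayleigh criterion; the rupture
gap is refined by bisection to $10^{-3}$ relative, and forces beyond it are
reported as zero with a flag. A rupture is signalled as a classed
condition, distinguishable from numerical non-convergence.

## The underwater contact angle

Combining the Young–Dupré balances of the fluid–air, water–air and
fluid–water contact lines on one solid eliminates the solid surface
energies:

$$\cos\theta_{fw} = \frac{\gamma_{fa}\cos\theta_{fa} -
\gamma_{wa}\cos\theta_{wa}}{\gamma_{fw}}.$$

`underwater_contact_angle()` evaluates this and refuses (with an error
naming the offending side) when the right-hand side leaves $[-1, 1]$ —
complete wetting or dewetting underwater — rather than clamping. Receding
angles are the intended inputs, since pull-off is a receding process; the
configuration stores one angle per (substrate, liquid) and no hysteresis
model. Two consequences worth internalizing: a fluid that wets mildly in
air on a hydrophilic surface can become strongly non-wetting underwater
(the water term dominates the numerator), and on a hydrophobic surface the
fluid can keep a low angle underwater while its interfacial tension roughly
doubles — which is exactly why the model predicts *stronger* wet adhesion
there.

## The pad model

The pad is `N` identical rigid hairs at one common gap `d` (rigid pad,
simultaneous detachment — the model gives the theoretical maximum, not the
peeling force). Bridges do not interact. The three modes:

* **air**: $F_\mathrm{net}(d) = N f_\mathrm{air}(d)$ with
  $(\gamma_{fa}, \theta_{fa})$;
* **underwater, no bubble**: $N f_\mathrm{water}(d)$ with
  $(\gamma_{fw}, \theta_{fw})$;
* **underwater, bubble**: $N_\mathrm{in} f_\mathrm{air}(d) +
  N_\mathrm{out} f_\mathrm{water}(d) + f_\mathrm{bubble}(d + L)$.

The bubble is itself a pinned bridge: volume $V_b$, pinned at the pad rim
$D_p/2$, tension $\gamma_{wa}$, contact angle $180^\circ - \theta_{wa}$
measured through the gas, spanning $d + L$ because it reaches from the pad
plane (where the hairs are rooted) down to the substrate. Hairs whose tips
fall inside the bubble's substrate contact sit in air; the rest sit in
water. With uniform areal hair density the partition is the contact-area
fraction, $N_\mathrm{in} = \mathrm{round}\!\left(N \min(1,
(R_\mathrm{b,bottom}/(D_p/2))^2)\right)$, ties rounded up. The partition is
re-evaluated at every gap (the bubble's contact radius changes slightly as
the pad retracts); evaluating it once at contact was the alternative, and
the per-gap choice is visible in the output so the two can be compared.
Fluid bridges inside the bubble carry the same volume as those outside, the
bubble is incompressible at fixed $V_b$, and a bubble that cannot span
$d + L$ contributes zero force and zero contact (flagged ruptured).

The adhesion of a mode is the minimum of $F_\mathrm{net}$ over a 200-point
gap grid from $0.05\,D_h$ to $2.5\,s_f$ (past rupture of the fluid
bridges), with a parabola through the three bracketing points refining the
minimum. Per-gap component bookkeeping ($N_\mathrm{in}$, $N_\mathrm{out}$,
$f_\mathrm{air}$, $f_\mathrm{water}$, $f_\mathrm{bubble}$) is exact by
construction.

## Default parameter set, and why

`beetle_config()` represents a typical male ladybird-beetle distal pad on
the two standard laboratory substrates. The tarsal secretion of such
beetles is a long-chain hydrocarbon oil, so the fluid is given
n-hexadecane's tensions: $\gamma_{fa} = 27.5$, $\gamma_{fw} = 53.5$ mN/m
(the underwater tension roughly twice the in-air one), with water at
$\gamma_{wa} = 72.8$ mN/m. Receding contact angles: fluid 6°/56° and water
20°/93° on untreated glass / fluorosilanized (PFOTS) glass. The derived
underwater fluid angles are then about 140° on glass and 69° on PFOTS —
the hydrophilic substrate turns the oil non-wetting underwater, the
hydrophobic one leaves it wetting.

Geometry: hair tip diameter $D_h = 2$ µm and $N = 2000$ hairs, i.e. a
total hair contact area of $6283$ µm² $= 2000\pi$, which is also the fixed
area of the contact-splitting sweep; hair length $L = 50$ µm; pad diameter
$D_p = 200$ µm; fluid volume per hair set by $\phi_f = 2$ (0.52 fl, the
right order for a femtolitre-scale secretion). The trapped bubble defaults
to $\phi_b = 1.5$ — an equivalent-sphere radius two-thirds of the pad
radius, a plastron somewhat smaller than the pad. That volume sits in the
physically interesting regime: it spans the hair layer, its curvature is
slightly positive on the hydrophilic substrate (weakly repulsive) and
slightly negative on the hydrophobic one (weakly attractive), and it
engulfs most but not all hairs, so the bubble mode interpolates between
the other two. All of these values are ordinary literature-scale numbers
for the system, not fitted quantities; `config_table()` echoes the full
resolved set in every study output so any transcription can be audited,
and `read_config()` accepts the same structure from YAML.

`gecko_config()` carries the whole-animal thought experiment: setal tips of
400 nm, 4 mm toes at 10% hair coverage, a phospholipid-like fluid
(30/42 mN/m, volume $4.19\times10^{-3}$ fl, again $\phi_f = 2$) on glass,
PMMA, OTS-SAM and PTFE, 20 toes per animal. Its point is the sign flip: on
glass the dry prediction exceeds the wet one, on PTFE the wet exceeds the
dry, because the derived underwater angle drops to ~70° while the
interfacial tension rises.

## The studies

* `sweep_contact_angle()` — normalized single-bridge adhesion
  $F_{\min}/(\gamma s_f)$ and its Laplace/tension split across
  $\theta \in \{6, \dots, 150\}°$ at $\phi_f = 2$. The default grid
  includes every angle the presets use. High adhesion (≥60% of the sweep
  maximum) persists up to ~70°; by 150° the net force is a few percent of
  maximum and the Laplace term has turned weakly repulsive.
* `substrate_comparison()` — the six (mode × substrate) pad curves plus the
  isolated bubble term and an adhesion summary table.
* `sweep_bubble_volume()` — adhesion and $N_\mathrm{in}/N$ versus $V_b$,
  flagging the all-entrapped region. Once some hairs contact in water the
  trends on the two substrates are opposite: shrinking the bubble weakens
  adhesion on glass (hairs move from air to a non-wetting environment) and
  strengthens it on PFOTS (they move into a higher-tension wetting one).
* `sweep_hair_diameter()` — contact splitting at fixed total area: $f
  \propto D_h$ (self-similar bridges) against $N \propto D_h^{-2}$ gives
  $|F_{\min}| \propto D_h^{-1}$; the tabulated log–log slope is $-1$
  within discretization.
* `predict_whole_animal()` — per-toe and 20-toe forces, dry vs wet.
* `sensitivity()` — elasticity $d\log(\mathrm{ratio})/d\log(\mathrm{parameter})$
  of the wet/dry adhesion ratio. For the no-bubble ratio every geometric
  parameter cancels exactly (both numerator and denominator scale the same
  way); only the tensions and angles move it. Contact area and bubble
  volume matter only through the bubble mode.

Study functions default to 200-point gap grids and 200-segment profiles —
the resolution at which tabulated adhesion values are converged to well
under 0.5% — and are deterministic: identical configuration, identical
output. Tests and examples use coarser grids (60–150 points) where only
qualitative structure is asserted.

## Force-trace reduction

The `forcetrace` functions mirror how instrument recordings become pull-off
numbers. A recording is a `force_trace` — time, force, and a per-sample
motion-stage label in the fixed protocol order approach → lateral →
approach2 → pause → retract. Stage labels are required input (they come
from the instrument's motion log); no changepoint detection is attempted.
`resample_per_step()` block-averages each stage to 512 points;
`background_subtract()` removes a contact-free recording of the same
protocol by evaluating it at the trace's timestamps (linear interpolation
by default; a nearest-sample option exists for step-like backgrounds);
`pulloff_force()` is the minimum force in the retraction, with a
no-adhesion flag when the retraction never goes negative;
`replicate_mean()` averages replicate pull-offs.

`synth_trace()` generates seed-deterministic surrogate recordings — stage
kinematics at 62.5 µm/s, a smooth ~50 µN-scale background, Gaussian sensor
noise, and an injected adhesion dip with the ground truth in the metadata —
so the reduction chain is testable without instrument data. It emulates the
*structure* of a recording, not its physics: no viscoelastic creep, no
drift other than the smooth background, no contact mechanics. Round-trip
tests bound the recovery error by the block-averaged noise (including the
$\sqrt2$ from subtracting a noisy background) plus the extreme-value bias
of a minimum taken over noisy samples; passing them says the bookkeeping is
right, not that real traces are this clean.

## Numerical choices, in one place

* Newton residual tolerance $10^{-10}$ (relative) on (rim radius, height,
  volume); volume conservation $10^{-6}$.
* 200 profile segments, doubled (up to 3 times) until the force moves by
  < 0.2%; energy backend uses the same resolution with an
  augmented-Lagrangian volume loop to $10^{-8}$ relative.
* Continuation along the gap grid; cold starts fall back to a cylindrical
  initial guess and, failing that, gap-ramping from one-eighth of the
  target gap.
* Rupture bisection to $10^{-3}$ relative; post-rupture force identically 0.
* Adhesion minima refined by an exact parabola through the three
  bracketing grid points (used only when the middle point is the grid
  minimum and the fit is convex).
* Hair partition rounding: nearest integer, ties up.
* Degenerate inputs: $N = 0$ pads give identically zero curves; vanishing
  bubble volumes reduce the bubble mode exactly to the no-bubble mode;
  contact angles of exactly 0° or 180° are rejected as invalid rather than
  solved.

## Known limitations

Quasi-static and capillary-only: no viscous or van der Waals contribution,
no contact-angle hysteresis during the pull, no bridge–bridge interaction,
no hair elasticity or peeling, no drainage dynamics of the interfacial
water film, no substrate roughness. The rigid simultaneous-detachment
assumption makes pad-level forces upper bounds; mode *ratios* are far more
robust than absolute values, which is why the sensitivity study reports
ratios. The bubble is incompressible and pinned at the pad rim; gas
dissolution is outside the model. Reentrant menisci are flagged, not
resolved against the hair flank.
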