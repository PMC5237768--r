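---
title: "Bone remodeling with biodegradable implants: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone remodeling with biodegradable implants: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

osteosim simulates how a bone defect filled with a biodegradable implant
heals under load, by coupling two processes on a 2D plane-stress finite
element domain: Wolff-law density adaptation of the surrounding bone, and
progressive mechanical and mass degradation of the implant. This vignette
describes the model, the numerical choices, and what the synthetic
domains can and cannot say about real bone.

## The adaptation model

Bone is described by a per-element apparent density $\rho_j$ (g/cm$^3$),
which sets the isotropic elastic modulus through the cubic power law

$$E_j = 2315\,\rho_j^3 \quad \text{(MPa)},$$

a standard apparent-density–stiffness relation for cancellous and
cortical bone. Under the habitual loads, the tissue is assumed to move
its density field toward the minimizer of total strain energy

$$F(\rho) = \sum_j \tfrac12\,\sigma_j^\top S_j\, \sigma_j\, v_j,$$

subject to conservation of total bone mass $\sum_j \rho_j v_j = M$ and
the physiological bounds $\rho_{\min} < \rho_j \le 1.8$ g/cm$^3$, the
upper bound being the maximum density of cortical bone. Here $S_j$ is
the plane-stress compliance matrix of element $j$, $\sigma_j$ its stress
vector, and $v_j$ its volume (area times unit thickness). The daily
update moves each element a small fraction $c = 0.02$ of the way toward
the constrained optimum $\hat\rho$:

$$\rho_j(t+1) = \rho_j(t) + c\,(\hat\rho_j(t+1) - \rho_j(t)),$$

and the iteration stops once no element changes by more than
0.001 g/cm$^3$ in a day. Stress is the *cause* here and density the
*response*: stiff, strongly loaded regions densify toward the cortical
cap while unloaded regions resorb toward the floor.

### Solving for the predicted density

The constrained minimization is solved by the optimality-criteria (OC)
method. Holding the current stress field fixed, element compliance
scales as $1/E_j \propto \rho_j^{-3}$, so the predicted-energy objective
is separable, $\sum_j U_j (\rho_j/x_j)^3$, and each inner iteration
scales the trial density by the ratio of its energy sensitivity to a
Lagrange multiplier $\lambda$,

$$x_j \leftarrow \mathrm{clip}\!\left[x_j
  \left(\frac{3 U_j \rho_j^3 / x_j^4}{\lambda v_j}\right)^{\eta}\right],$$

with $\lambda$ found by bisection on the mass constraint and a
move limit $\zeta = 0.2$ per inner iteration. At the fixed point the
energy sensitivity per unit mass is equal across all elements strictly
inside the bounds (the KKT condition), which the test suite checks
directly and against an exhaustive grid search on 2–3-element problems.

The damping exponent defaults to $\eta = 1/(p+1) = 0.25$ for the cubic
law ($p = 3$). This choice is deliberate: the fixed-stress subproblem
gives the multiplicative update a local contraction rate of
$|1 - \eta(p+1)|$, so the classical $\eta = 0.5$ cycles without
converging, while $\eta = 1/(p+1)$ cancels the trial density from the
update and solves each $\lambda$-subproblem exactly; the move limit then
only throttles how far one inner iteration may travel.

## The implant

A defect of 36 elements is filled by a biodegradable implant with
initial modulus $E1_0$, expressed in the bone density scale as
$\rho_{\mathrm{imp},0} = (E1_0/2315)^{1/3}$. Two empirical degradation
laws act over the degradation period $T$:

* mechanical: $E1(t) = (1 - t/T)^{1/2}\,E1_0$, zero from $T$ on;
* mass: $r(t) = \rho_{\mathrm{imp},0}\,(t/T)^2$, the cumulative density
  removed — slow at first, fastest near $T$ ("second-order" behavior).

Each day the implant elements lose $r(t+1) - r(t)$ of density on top of
the remodeling update; the elasticity solve always uses the total
density through $E = 2315\rho^3$. The two laws are the literature's
separate descriptions of stiffness loss and mass loss and are *not*
mutually consistent through the density–modulus law; we keep both as
printed — $E1(t)$ enters only the osteogenesis score, $r(t)$ only the
mass bookkeeping — rather than forcing one onto the other.

Osteogenesis metrics over the 36 defect elements:

* **score**: mean bone-attributable modulus
  $\max(0,\,2315\rho_j^3 - E1(t))$, MPa;
* **new-bone fraction**: percentage of elements whose bone-attributable
  density $\rho_j - \max(\rho_{\mathrm{imp},0} - r(t), 0)$ reaches
  $\theta = 0.9$ of that element's pre-defect baseline density;
* **refilled area**: area (mm$^2$) of defect elements whose total
  density is at least half the implant's initial equivalent density —
  the radio-visible region an in-vivo micro-CT would segment.

## Domains and loads

All geometries are parametric stand-ins built on structured grids of
square elements; the reference study's CT outlines are not public, so
absolute anatomy is schematic while mesh statistics are matched.

* **Femur-like domain**: ~1,165 elements of 0.25 cm$^2$ (shaft, neck,
  head, greater trochanter), clamped distally, loaded by three
  alternating joint-force/abductor-tension pairs (1700 N at 25° + 576 N
  at 35°; 2271 N at 66° + 703 N at 62°; 1049 N at 15° + 248 N at 8°,
  angles from the horizontal) whose element energies are averaged with
  equal weight. The 6 × 6-element defect sits on the medial metaphyseal
  cortex, the candidate window whose converged baseline contains all
  three density classes (dense cortex, intermediate, low).
* **Rat metaphysis**: an 8 × 10 mm cross-section of 0.5 mm elements
  with a two-part cortical wall (7000 MPa diaphyseal, 2000 MPa
  metaphyseal), 900 MPa cancellous interior, and a 3 × 3 mm lateral
  defect (36 elements, 9 mm$^2$) filled with 800 MPa calcium-sulfate
  cement degrading over 28 days (in-vivo range 4–8 weeks). A 0.65 N
  joint force — one third of rat body weight — is distributed across
  the top edge, the growth-plate cross-section. The intact domain is
  remodeled to convergence before the defect is drilled, so the
  pre-defect state is an equilibrium of the adaptation dynamics.
* **Plates**: rectangular fixtures for verification (patch test,
  closed-form uniaxial states, refinement studies).

Units: coordinates are cm externally and mm internally, so N and MPa
are consistent; element volumes assume 1 cm out-of-plane thickness.

## Numerical choices

* 4-node bilinear isoparametric quadrilaterals, 2 × 2 Gauss quadrature;
  element stress reported as the quadrature mean. Element energies are
  evaluated per quadrature point, so their sum equals the
  displacement-form energy $\tfrac12 u^\top K u$ to machine precision.
* The global system is solved by sparse Cholesky factorization with the
  symbolic analysis cached across days (the sparsity pattern never
  changes; only the per-element moduli do).
* Near-void elements keep a modulus floor of 0.01 MPa and a density
  floor of 0.01 g/cm$^3$ so the system stays nonsingular.
* The mass-constraint bisection runs to $10^{-10}$ relative; the inner
  OC loop stops when no trial density moves by $10^{-6}$ g/cm$^3$.
* Everything is deterministic: identical configurations produce
  bit-identical traces.

### Stopping rules

Baseline adaptation runs until the daily change criterion
(< 0.001 g/cm$^3$ per element) is met — about 1,900 days for the femur
stand-in, which is also the scale of the problem sizes used by the test
suite (one baseline per session, memoized). For defect experiments the
run continues until the degradation period has elapsed *and* the field
has converged. Parameter sweeps instead observe every cell at its own
$T$ plus a 20-day follow-up: near the converged bang-bang state the
remaining relaxation happens through very slow two-element mass
exchanges that can keep the max-change criterion above threshold for
hundreds of days, and at asymptotic convergence the structure is set by
the load regime alone, so the implant's influence — the quantity a sweep
is meant to compare — washes out. `follow_up_days = NULL` restores the
run-to-convergence rule.

## What the stand-ins do and do not show

The synthetic domains reproduce the method's qualitative behavior: a
dense cortical shell with a resorbed interior emerges from a uniform
start; defect healing depends jointly on implant stiffness and
degradation speed; a near-zero-modulus filler (0.002 MPa) heals worse
than a 30 MPa one; the rat defect's radio-visible area shrinks
monotonically through days 7/17/27.

Two behaviors of the reference study do not transfer quantitatively, and
the acceptance suite reports them honestly rather than calibrating
toward them:

* The converged stand-in baseline is nearly bang-bang (densities pinned
  at the cap or the floor, fewer than 20 intermediate elements out of
  1,165). On CT-derived anatomy the same method retains broad
  intermediate-density cancellous regions. The new-bone classification
  is *relative to baseline*, so the day-17 → day-19 jump in new-bone
  fraction — driven by elements whose baseline sits in an intermediate
  band that growth crosses on exactly those days — is muted here: we
  obtain roughly 25/31/33 % at days 7/17/19 instead of ~0/33/53 %.
  Floor-density baseline sites also make the day-7 fraction nonzero,
  because 90 % of a floor density is a trivial threshold.
* With the stated update laws, slower mass removal is never penalized:
  a 30-day degradation period retains more density at every observation
  time than a 20-day one, so the "degradation too slow leaves no space
  for new bone" optimum at $T = 20$ does not emerge on this geometry,
  and the modulus optimum at 1000 MPa appears only when the defect
  interrupts the primary (lateral) load path.

Both phenomena are geometry-dependent, not parameter-tuning targets;
the defect placement, thresholds and generator defaults were fixed once
from the anatomical description and left alone.

## Reproducing an experiment

```{r}
library(osteosim)

cfg  <- remodel_config()
mesh <- generate_femur_domain(cfg)

baseline <- run_baseline(mesh, femur_load_cases(), cfg)
plot_density_field(mesh, baseline$state$density)

trace <- run_defect_experiment(mesh, baseline$state,
                               implant_state(1000, 20, cfg),
                               femur_load_cases(), cfg, stop_day = 21)
tidy(trace)
autoplot(trace)

sweep <- run_sweep(mesh, baseline$state,
                   E1_0_list = c(30, 500, 1000, 2000, 3000),
                   T_list = 20, femur_load_cases(), cfg)
glance(sweep)
```

## Limitations

2D plane stress with isotropic material; no anisotropy, no geometric or
material nonlinearity, no biological signaling beyond the strain-energy
stimulus; uniform degradation across the implant bulk; parametric
rather than image-derived anatomy. These match the scope of the
underlying remodeling framework — the package is a laboratory for the
coupled adaptation–degradation mechanism, not a patient-specific tool.
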