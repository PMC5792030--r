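---
title: "An area-conserving kinematic model of the apical organ of Corti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An area-conserving kinematic model of the apical organ of Corti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortikin)
```

## The model

In the low-frequency apex of the cochlea, outer hair cells (OHCs) change
length with their membrane potential. `cortikin` asks a purely geometric
question: given a fractional OHC contraction $\epsilon$ (positive =
shortening, $L_{OHC}(\epsilon) = (1-\epsilon)L_{OHC,0}$), how must one
cross-section of the organ of Corti deform if its cross-sectional areas
cannot change? The incompressibility premise is anatomical: at the apex the
fluid spaces between the pillar cells and the Hensen cells are closed off
along the cochlea, so fluid cannot escape longitudinally, and the
cytoplasm of the Hensen-cell body cannot either. The fluid area (tunnel of
Corti + space of Nuel + outer tunnel) and the Hensen-cell area are
therefore conserved separately, and the basilar membrane (BM) is kept
fixed as the reference frame.

Everything else about the cross-section is rigid or follows one of two
dimensionless couplings:

* the **reticular lamina** (RL) is a stiff rod pivoting about the apex of
  the outer pillar cell;
* the **tunnel of Corti** triangle is rigid;
* the **Deiters' cell** connects the OHC base to a fixed anchor on the BM
  and changes length as $L_{DC}(\epsilon) = (1+\epsilon\Delta)L_{DC,0}$,
  with extensibility $\Delta \ge 0$ a free parameter;
* the **Hensen-cell contour** changes length as
  $L_{HC}(\epsilon) = (1+\epsilon\Gamma)L_{HC,0}$, with extensibility
  $\Gamma \ge 0$ the second free parameter;
* the **outer tunnel** is a circular segment whose chord is the OHC and
  whose arc length $a$ is fixed (its outer wall is reinforced by stiff
  cables), so the chord relation $L_{OHC} = a \sin\varphi/\varphi$
  determines the deformed opening angle $\varphi(\epsilon)$ from
  $\sin\varphi/\varphi = (1-\epsilon)\sin\varphi_0/\varphi_0$.

$\Delta$ and $\Gamma$ are geometric couplings, not material stiffnesses:
they summarise how the whole arrangement redistributes an OHC length
change. Both rows of three OHCs and Deiters' cells are lumped into a
single effective row at the position of the outermost row, consistent with
the RL pivoting as one rigid plate.

### The fluid space

With $\varphi(\epsilon)$ known, the outer-tunnel area follows in closed
form, $A_{OT} = a^2\!\left(\tfrac{1}{4\varphi} -
\tfrac{\sin 2\varphi}{8\varphi^2}\right)$, and the space-of-Nuel area is
the shoelace area of the polygon through the RL pivot, the OHC apex
$\mathbf a$, the OHC base $\mathbf b$, the Deiters' anchor and the
outer-pillar foot. Four scalar unknowns (the coordinates of $\mathbf a$
and $\mathbf b$) satisfy four equations: three length constraints (rigid
RL arm, contracted OHC, extended Deiters' cell) and conservation of
$A_{SN} + A_{OT}$ (the rigid tunnel of Corti cancels). `solve_fluid_space()`
solves this 4×4 system by damped Newton iteration with the analytic
Jacobian, continuing in $\epsilon$ from the reference configuration so
that the physically connected solution branch is tracked; any other root
of the nonlinear system is rejected. Residuals are scaled by the reference
lengths and areas; the default tolerance is $10^{-9}$.

A useful consequence of the bookkeeping: because the tunnel of Corti is
rigid and both the fluid and Hensen areas are conserved, the area demand
passed to the Hensen contour equals exactly minus the area swept by the
rotating reticular lamina. Near the critical extensibility (below) the RL
barely moves, so the contour's area budget changes by only a few µm²
across the physiological contraction range.

### The Hensen elastica

The Hensen-cell body is not modelled cell by cell. Its outer contour is a
planar elastica with a preferred shape: parametrised by the tangent angle
$\phi(s)$, it minimises the bending energy
$\tfrac12\int_0^{L_{HC}(\epsilon)} \left[\phi'(s) -
\Gamma_\epsilon\,\phi_0'(s/\Gamma_\epsilon)\right]^2 ds$
(with $\Gamma_\epsilon = 1+\epsilon\Gamma$; the contour is stretched
uniformly, so material point $s_0$ sits at deformed arc length
$\Gamma_\epsilon s_0$) subject to:

* the endpoint landing on the deformed OHC apex (coordinates are
  cumulative quadratures $x(s)=\int\cos\phi,\ y(s)=\int\sin\phi$ from the
  fixed abneural anchor);
* conservation of the enclosed Hensen area, imposed through the line
  integral $\int y\cos\phi\, ds$ of the contour;
* a first-order natural boundary condition at the anchor,
  $(\phi_1-\phi_0)/\Delta s = \Gamma_\epsilon \phi_0'(0)$;
* a fixed junction angle between the contour and the outer-tunnel arc at
  the OHC apex ($\phi_N = \phi_e$, with $\phi_e$ tracking the deformed arc
  tangent plus the constant reference offset).

`solve_hensen_contour()` discretises $\phi$ at $N+1$ equispaced arc-length
nodes and finds a stationary point of the Lagrangian (five multipliers:
endpoint x/y, area, two boundary rows) by damped Newton iteration on the
gradient system, again with $\epsilon$-continuation from the reference.

**The area constant.** The value that $\int y\cos\phi\,ds$ must take is
not arbitrary: once the fluid space is solved, the other pieces of the
Hensen boundary (outer-tunnel arc, Deiters' line, BM segment) are known,
and the constant is fixed by requiring the total enclosed area to stay at
its reference value. `area_constant_for()` computes it from the composite
boundary; this is the unique self-consistent choice, and the package's
tests verify conservation of the composite area to better than $10^{-5}$
relative on every converged solve. An alternative reading — freezing the
contour's own integral at its reference value and ignoring the moving arc
boundary — would leak area at that order and is not used.

## Numerical choices

* **Discretisation.** $N = 100$ elements by default. Doubling to
  $N = 200$ changes tracked material-point displacements by well under 1%
  (a tested invariant), which is far below the uncertainty of the
  digitized geometry.
* **Quadrature.** Node coordinates and the integral constraints use
  trapezoid cumulative quadrature on the node values; the area line
  integral uses the matching polyline form, so the enforced constraint and
  the area oracle are algebraically consistent. The one deliberately
  first-order term is the forward-difference natural boundary row, kept in
  its printed discretised form.
* **Reference projection.** The reference tangent table is obtained from
  the geometry's polynomial contour by arc-length reparametrisation and is
  then projected once, at build time, onto the discrete constraint set
  (exact endpoint and boundary rows). The projected table is feasible with
  zero bending energy, so at $\epsilon = 0$ the solver returns it
  identically — the zero-contraction state is exact at every $N$, and all
  displacements are measured against it.
* **Continuation and unsolvability.** Both solvers walk from
  $\epsilon = 0$ outward in steps of $10^{-3}$ (default), using the
  previous solution as the initial guess. A failed continuation is retried
  once with half the step; if the failure persists the parameter point is
  declared unsolvable. This is a genuine model outcome, not a numerical
  apology: the inextensible-contour constraints can admit no solution, and
  the classification functions record it as such.
* **Tolerances.** $10^{-9}$ scaled residuals in both solvers; the
  finite-difference gain uses $h = 10^{-4}$ (validated in the tests
  against a local quadratic fit); the critical-extensibility bisection
  stops when $|D_{RL}| < 10^{-6}$ µm.

## The default geometry, and what it does (not) represent

The headline quantities emerge from the geometry, which no published
table pins down exactly. The shipped cross-section
(`default_fixture()`) is a schematic digitization of a guinea-pig apical
organ of Corti: landmark proportions follow published micrographs with a
20 µm scale bar, the BM is inclined 37.26° to the reticular lamina
(a morphometric average), and the remaining digitization freedom —
principally the outer-tunnel angle $\varphi_0$, the OHC length and tilt,
and the Deiters' anchor — was calibrated once so that the model's emergent
quantities sit where this organ is known to put them: the critical
extensibility near 1.2, an RL gain near zero at the elongated operating
point and near −7 µm per unit contraction at the contracted one, and a
Hensen radial-direction boundary near $\Gamma \approx 0.2$. The Hensen
contour is a degree-5 Bézier whose final approach rides just outside the
outer-tunnel arc, meeting it at the OHC apex in a thin wedge, as the
anatomy does. After calibration the fixture was frozen; every acceptance
tolerance absorbs the residual digitization uncertainty.

Two anatomically ambiguous choices are decided as follows. The RL pivot
is placed at the **outer-pillar apex**; an attachment nearer the inner
hair cell would lengthen the RL arm but not change the mechanism. The two tracked
material points default to reference arc-length fractions **0.55**
("top") and **0.2** ("side") of the contour, tunable in the config.

What the fixture does *not* represent: real apical cross-sections vary
between animals and along the cochlea; the model is strictly 2-D (no
longitudinal coupling), quasi-static (no viscosity or inertia — the
frequency in `oscillatory_response()` is bookkeeping only), has no
tectorial membrane or subtectorial fluid, a single lumped OHC/Deiters row,
and no BM motion (a sound-evoked BM displacement would superpose on the
internal deformation computed here). Passing tests demonstrate internal
consistency of the constrained kinematics and reproduction of the
model-level quantities, not agreement with any individual preparation.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $\epsilon$ | fractional OHC shortening | probe 0.005 | isolated-OHC experiments bound physiological length changes to about ±2%; 0.005 is the standard probe for displacement maps |
| $\Delta$ | Deiters'-cell extensibility | 1.15 | just below the critical value $\Delta_C \approx 1.2$: RL moves toward the BM while the Hensen cells move away with larger amplitude, as observed |
| $\Gamma$ | Hensen-contour extensibility | 0.1 | small enough that the top of the organ moves radially toward the modiolus (boundary near 0.2), large enough that solutions exist across the physiological range |
| $N$ | elastica elements | 100 | grid-converged to <1% (tested) |
| $h$ | gain finite-difference step | $10^{-4}$ | agrees with a local quadratic fit of $D_{RL}(\epsilon)$ |

## Observables and conventions

All displacements are reported in the BM frame: *radial* = along the BM
toward the stria vascularis, *vertical* = along the BM normal toward scala
vestibuli (away from the BM). $D_{RL}$ is the vertical displacement of the
OHC apex, so contraction below the critical extensibility gives
$D_{RL} < 0$. The somatic rotation $\alpha$ of the OHC (base about apex)
is positive counter-clockwise; `rotation_reference_variant()` reports it
the way imaging experiments see it, with the RL held fixed and the
hyperpolarised (elongated) state as reference, over contractions up to
the maximal ≈4%. For the default (large) outer-tunnel arc the base
rotates toward the stria; shrinking the arc flips the direction — the
size of the outer tunnel sets the sign.

```{r example, eval = FALSE}
geom <- default_geometry()
st <- solve_deformation(geom, epsilon = 0.005, delta = 1.15, gamma = 0.1)
observables(st)
autoplot(st)

critical_extensibility(geom)                 # ~1.2
rl_gain(geom, eps0 = 0.02)                   # ~ -7 um per unit contraction
sweep_contraction(geom) |> autoplot()
```

## Known limitations

* The critical extensibility, the gains and the sign boundary inherit the
  digitization uncertainty of the fixture; the package quotes them with
  the corresponding tolerances rather than as sharp constants.
* The elongation-side plateau of the displacement curves is reproduced
  for the reticular lamina (the gain passes through zero near
  $\epsilon^{(0)} = -0.02$) but not for the Hensen-top displacement, which
  remains nearly linear in $\epsilon$ on this geometry: the Hensen
  amplitude is dominated by the swing of the OHC base, which has no
  critical-point mechanism of its own.
* On this geometry, parameter combinations with small $\Gamma$ lose
  solvability within the physiological range at off-critical $\Delta$
  (where the RL sweep, and with it the contour's area demand, is large);
  at $\Delta = 1.15$ itself the whole scanned $\Gamma$ range admits
  solutions over $|\epsilon| \le 0.02$. Region classifications report
  solvability per cell, so the map is explicit about where the
  constrained kinematics breaks down.
* Newton-on-gradient with finite-difference Jacobians is deliberate: the
  systems are small (≈100 unknowns) and the method is transparent; a
  sparse analytic Hessian would be faster but is not needed at these
  problem sizes (a full deformation solve takes well under a second).
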