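---
title: "Continuum damage in knee ligaments: model, surrogate, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum damage in knee ligaments: model, surrogate, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kneedamage)
```

`kneedamage` simulates how localized damage in the anterior cruciate
ligament (ACL) redistributes load onto the neighboring knee ligaments
(PCL, MCL, LCL). It combines a fiber-reinforced hyperelastic law with a
history-dependent continuum damage variable, a quasi-static nonlinear
finite-element solver on a parametric knee surrogate, and a staged loading
protocol: damage induction by a large quadriceps force, then anterior
shear or internal tibial torque reloading, for undamaged, moderately
damaged, and ACL-removed joints. This vignette records the model, the
assumptions behind the synthetic surrogate, and every numerical decision a
reader would need to reproduce or criticize the results.

## The constitutive model

Each ligament is a nearly incompressible solid reinforced by one family of
collagen fibers with reference direction $a_0$. With
$C = F^T F$, $J = \det F$, and isochoric invariants
$\bar I_1 = J^{-2/3}\,\mathrm{tr}\,C$ and
$\bar I_4 = J^{-2/3}\, a_0 \cdot C a_0$, the strain energy density is

$$
W \;=\; C_1(\bar I_1 - 3)
\;+\; \frac{k_1}{2k_2}\Bigl(e^{\,k_2 E^2} - 1\Bigr)
\;+\; \frac{1}{D}\Bigl(\frac{J^2-1}{2} - \ln J\Bigr),
\qquad
E = k(\bar I_1 - 3) + (1-3k)(\bar I_4 - 1),
$$

the Holzapfel–Gasser–Ogden form with dispersion $k$ fixed at zero (fully
aligned fibers). The fiber term is active only in tension
($\bar I_4 > 1$); ligament fibers buckle rather than support compression.
The volumetric term with compliance $D$ enforces near-incompressibility
(bulk modulus $2/D = 2\times10^9$ Pa at $J = 1$ for the packaged
parameters).

Damage enters through the maximum historical fiber stretch
$\lambda_{\max} = \max_t \sqrt{\bar I_4(t)}$, an irreversible internal
variable, which scales the energy by

$$
G(\lambda_{\max}) \;=\;
\frac{1 - e^{\beta/2\,(\lambda_{\max}^4 - \lambda_c^4)}}
     {1 - e^{\beta/2\,(\lambda_0^4 - \lambda_c^4)}},
$$

equal to one below the initiation stretch $\lambda_0$ and clamped below at
the residual fraction $g_{\text{floor}} = 0.25$: degraded stiffness never
falls under 25% of the undamaged stiffness — a practical degradation limit
that also keeps the tangent well conditioned near complete tears. At the packaged
$\beta = 1.9\times10^{-4}$ the law is numerically indistinguishable from
its small-$\beta$ limit $(\lambda_c^4-\lambda_{\max}^4)/(\lambda_c^4-\lambda_0^4)$,
which the tests exploit as an independent oracle.

The packaged parameter set (`material_params()`) is, in SI units:
$C_1 = 5\times10^6$ Pa, $D = 10^{-9}$ Pa$^{-1}$, $k_1 = 2.06\times10^7$ Pa,
$k_2 = 0.201$, $k = 0$, $\lambda_0 = 1.183$, $\lambda_c = 1.35$,
$\beta = 1.9\times10^{-4}$. All four ligaments share it; damage evolution
is enabled in the ACL only — the analysis isolates the effect of ACL
degradation on pristine neighbors.

Two deliberate interpretation choices, both switchable:

* **Isochoric split.** Evaluated with full invariants the printed energy
  carries a spurious reference stress $2C_1 I$ at $F = I$. We therefore
  use isochoric invariants in the $C_1$ and $k_1$ terms (the convention
  of the anisotropic hyperelastic families in commercial finite-element
  codes), guaranteeing a stress-free reference;
  `material_params(isochoric = FALSE)` restores the literal form.
* **Damage scope.** Literally, $W_{\text{mod}} = G \cdot W$ scales the
  volumetric constraint too, which degrades incompressibility exactly
  where tissue integrity is the question. Default: $G$ scales the
  isochoric terms only — equivalent to degrading the moduli $C_1$ and
  $k_1$ — with `material_params(damageVolumetric = TRUE)` as the literal
  variant.

The closed-form incompressible uniaxial response along the fiber,
$\sigma = G(\lambda)\,[\,2C_1(\lambda^2 - \lambda^{-1}) +
2k_1(\lambda^2-1)e^{k_2(\lambda^2-1)^2}\lambda^2\,]$, gives about
13.6 MPa at $\lambda = 1.1$ undamaged and anchors both the calibration
model and the finite-element verification.

## Calibration

`fit_params()` performs bounded Levenberg–Marquardt least squares of that
closed form against uniaxial stress–stretch data (Cauchy stress by
default; a nominal-stress flag exists because digitized tension data often
report force over reference area). `generate_uniaxial_curve()` produces
synthetic curves from the model itself — the packaged stand-in for
averaged bovine/human ligament tension data — with seeded Gaussian noise.
Identifiability drove two defaults: $D$ is invisible to incompressible
uniaxial data and stays fixed; $\beta$ at its small packaged value is
nearly confounded with $(\lambda_0, \lambda_c)$ and is fixed unless the
user frees it. When the data never exceed $\lambda_0$ the damage
thresholds are reported as unidentifiable and held at their initial
values rather than fitted to noise. Self-recovery behavior: noiseless
curves sampled through the softening regime return $C_1, k_1, k_2$ within
1% from ±20% perturbed starts. Under additive noise the picture changes
qualitatively: the sensitivity curves of $C_1$ and $k_1$ on a uniaxial
stretch grid are 96% correlated (the exponential fiber term masks the
ground matrix almost everywhere above $\lambda \approx 1.02$), so with
noise at 5% of peak stress the Monte-Carlo medians over 20 seeds show
$k_1$ recovered at the tens-of-percent level and $C_1$ essentially
unidentified — a property of single-protocol uniaxial data for this law,
not of the optimizer (the wandered fits sit at the noise-floor residual).
Pinning $C_1$ requires either a second deformation protocol or an
informative prior; the package reports the medians rather than
overstating what one curve can deliver.

## The synthetic knee surrogate

Full-anatomy knee geometries come from subject-specific image
segmentation and do not transfer; `build_knee()` instead generates a
parametric surrogate: four straight ligament struts with rectangular cross-sections,
swept between attachment footprints and meshed with a conforming
six-tetrahedra-per-cell (Kuhn) subdivision; bones are rigid frames. The
femur is fixed; the tibial frame carries the loads; the fibula follows
the tibia rigidly (the LCL's distal anchor). Each ligament gets one
end-to-end unit fiber direction — the standard assignment for whole-
ligament models — and a mid-substance tag: elements whose centroids fall in the
central 20% of the axial extent (a band rather than a planar slice —
robust on coarse meshes and faithful to the "mid-substance" language).

Dimensions are literature-informed adult values chosen once: ACL and PCL
about 36 mm long with 45 and 56 mm² cross-sections, the MCL a long thin
sheet (75 mm, 14 × 3 mm), the LCL a cord (56 mm, 4 × 4 mm). The cruciates
cross with a small medial–lateral offset so their volumes clear each
other. Attachment obliquities encode the restraint roles: the ACL drops
anteriorly from femur to tibia (so anterior tibial translation stretches
it), the PCL the reverse, the MCL's tibial end sits slightly anterior of
its femoral end, and the LCL's fibular end slightly posterior.

**In-situ pre-strain.** Ligaments are not stress-free in the mounted
joint; near full extension the MCL carries several percent in-situ
stretch, the ACL and LCL a little, the PCL essentially none. The
generator therefore builds each strut with a stress-free rest length
shorter than its mounted length (MCL 1.04, ACL and LCL 1.02, PCL 1.00)
and `mount_state()` equilibrates the resulting pre-tension before any
loading. This matters scientifically: a pre-tensioned collateral responds
to superimposed shear at second order, which is precisely the mechanism
that leaves the MCL's average stress nearly unchanged when the ACL is
lost while the unstressed PCL's response grows by multiples. Without
pre-strain every ligament's stress scales with tibial translation and no
ligament can be insensitive. Note the consequence for the damage
variable: fiber stretch exceeds one at baseline, so "no damage" means
$G \equiv 1$ (all stretches below $\lambda_0$), not
$\lambda_{\max} \equiv 1$.

What the surrogate does **not** emulate: condylar contact (we fix the
tibial flexion rotation as its stand-in, and fix longitudinal translation
per the protocol; medial–lateral and anterior translation, axial rotation
and varus–valgus stay free), menisci and capsule, ligament wrapping,
curved insertion footprints, subject-specific anatomy. Joint-level
numbers are therefore scaled-down/qualitative; material-point and
element-level results are quantitative.

## The solver

Total-Lagrangian quasi-static finite elements on 4-node tetrahedra, with
compiled element kernels (analytic first Piola stress and the full
consistent tangent $\partial^2 W/\partial F \partial F$, verified against
finite differences to $10^{-10}$).

* **Element technology.** Near-incompressibility locks plain linear tets.
  The default element evaluates the volumetric energy at volume-weighted
  *nodal* Jacobian averages (average-nodal-pressure tetrahedron), the
  condensed form of a mixed displacement–pressure formulation with nodal
  pressure projection; `"mixed-up"` and `"nodal-pressure-averaged"` name
  the same element, `"displacement"` selects the plain tet as a negative
  control. In the bending benchmark the plain tet is several times too
  stiff while the mixed element keeps the nodal volumetric strain under
  $10^{-3}$; both pass homogeneous patch tests to machine precision.
* **Rigid ties.** Distal attachment nodes are slaved to the tibial frame
  (translation plus rotation-vector parametrization, exact Rodrigues
  derivative in the residual, second derivatives of the rotation by
  differencing the analytic first derivative — they only affect the
  tangent). Applied frame loads are dead loads; their rotation-dependent
  generalized forces and load stiffness are included.
* **Newton strategy.** Full Newton steps; the stiff volumetric term makes
  the residual grow transiently before the quadratic phase, so no
  monotone line search is imposed — backtracking only rescues invalid
  ($J \le 0$) states, divergence falls back to load-step bisection (4
  levels). Far-from-equilibrium starts are damped by a trust-region-style
  cap: 5 mm per nodal step, 0.02 rad per frame-rotation step (0.005 rad
  during mounting, which has no load scale to Newton against).
  Convergence: residual below $10^{-9}$ times the load scale, with an
  absolute nano-newton floor so load-free equilibria pass; the tight
  relative tolerance is what makes the global force-balance check hold at
  $10^{-8}$.
* **Damage stepping.** $\lambda_{\max}$ is frozen during each Newton
  solve (well-defined tangent) and updated in a staggered fixed point per
  load level until the $G$ field is stationary; under monotone loading
  the converged state is then step-count independent (verified at 0.5%
  between 10 and 30 steps), and unloading retains the damage field.
* **Mounting.** The pre-strained reference is reached by a homotopy that
  ramps the stress-free reference geometry in four stages from the
  mounted shape, each stage starting near its equilibrium.

## The loading protocol

`run_scenario()` drives the three-scenario, two-mode experiment. The
quadriceps stage applies 2000 N along an anterior–superior line of action
at 25° to the tibial long axis — the patellar-tendon angle near full
extension lies in the 20–30° range, and the anterior component
(about 845 N) is what drives the anterior drawer that overstretches the
ACL. The angle's default sits where the surrogate's ACL resistance peak
exceeds that component, so the induced state is genuinely *moderate*
localized damage — in the default surrogate roughly 40% of ACL elements
pass $\lambda_0$, with a fully degraded core and an intact remainder —
rather than a complete tear (a few degrees steeper and the load-controlled
ramp snaps through the softening branch to full rupture). "Moderate
damage" is defined operationally as this post-2000 N state; there is no
separate damage magnitude knob. Anterior shear (up to 300 N, reported at
100 N) is applied through the middle of the tibial horn region; internal
tibial torque (up to 10 N·m, reported at 10 N·m) as an equal-and-opposite
force couple at the distal tibia with a 0.05 m arm — only the moment
matters on a rigid frame. The ACL-removed scenario deletes the ACL mesh
before mounting.

Summaries are volume-weighted mid-substance von Mises averages per
ligament and load level (a plain element mean is available via a flag);
fields export to ASCII VTU with von Mises stress, $G$, and
$\lambda_{\max}$ arrays, in Pa throughout.

## Problem sizes and verification scope

The refinement ladder shrinks the target edge length by 1.5 per level:
roughly 1.6k tetrahedra at level 0, 4.1k at level 1 (the default for
scenario work), 11k at level 2, and 34k at level 3. The mesh-convergence
study runs the undamaged 100 N shear case on levels 1–3 and compares
neighbor-ligament mid-substance averages between the two finest levels
(an under-3% criterion on mid-substance averages, the conventional
convergence yardstick for this kind of model). These sizes are the package's default study conditions;
everything scales by configuration.

Qualitative load-sharing orderings (which ligament carries most under
each mode, the LCL overtaking after complete ACL loss) are
geometry-sensitive on a strut surrogate; `check_scenario_orderings()`
evaluates them and *warns* rather than fails where the surrogate
deviates. On the default surrogate the undamaged-to-ACL-removed increase
concentrates in the PCL and LCL with the MCL least affected, the pattern
full-anatomy models report; the surrogate's MCL change at 100 N exceeds
the ~5% of such models because thin-sheet bending of the straight clamped
MCL strut adds a translation-sensitive stress component that the
anatomical (broad, wrapping) MCL does not have — a known, documented limitation of the
surrogate rather than of the damage model.

## Known limitations

* No contact, menisci, capsule, or wrapping; the flexion constraint
  stands in for condylar contact, and all moment transfer runs through
  the four struts.
* One material parameter set for all ligaments, from one data source at
  one rate; no viscoelasticity, permanent set, or damage outside the ACL.
* Straight prismatic struts with rigid end planes concentrate stress at
  attachments; attachment-zone values should not be over-read, which is
  why all reported averages are mid-substance.
* Load-controlled damage induction near the softening peak is sensitive
  to the quadriceps line of action by design — the real injury mechanism
  is similarly thresholded.
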