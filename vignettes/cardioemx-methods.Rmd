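---
title: "Coupled cardiac electromechanics with stretch-activated feedback: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled cardiac electromechanics with stretch-activated feedback: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cardioemx` simulates the fully coupled electromechanics of ventricular
myocardium: a quasi-static finite-strain mechanical balance and a monodomain
reaction-diffusion equation for the transmembrane potential, solved
monolithically with an implicit scheme.  Its purpose is comparative: how do
different passive material laws — compressible vs. nearly incompressible,
polynomial vs. exponential, transversely isotropic vs. orthotropic — change
the behavior of the stretch-activated mechano-electrical feedback (MEF) in a
beating left ventricle?

All quantities are expressed in a fixed unit system: mm, ms, kPa, mV.
Derived units follow (force = kPa mm$^2$ = mN, conductivity = mm$^2$/ms).

## Field equations

Two primary fields live on the reference configuration $\Omega_0$: the
placement (displacement $\mathbf u$) and the transmembrane potential $\Phi$.
The mechanical problem is quasi-static,

$$\mathbf 0 = \mathrm{Div}\,[\mathbf F\,\mathbf S] + \mathbf F^{\varphi},$$

with deformation gradient $\mathbf F$ and second Piola–Kirchhoff stress
$\mathbf S$; the electrical problem is a monodomain equation in the material
frame,

$$\dot\Phi = \mathrm{Div}\,[\mathbf Q] + F^{\Phi}, \qquad
  \mathbf Q = \mathbf D(\mathbf C)\,\nabla\Phi .$$

The stress splits into a passive part from a strain-energy density and an
active part driven by excitation,
$\mathbf S = 2\,\partial\Psi/\partial\mathbf C + T_{\mathrm{act}}\,
\mathbf f_0\!\otimes\!\mathbf f_0$.  The active part is a rank-one
second Piola--Kirchhoff tension along the reference fiber; its push-forward
carries the factor $I_{4f}/J$, so the active Cauchy stress falls off as the
fibers shorten.  This self-limiting behavior is what keeps the unloaded
isotonic contraction of a soft myocardium specimen at a finite shortening
instead of collapsing, and it is the convention of the excitation-contraction
framework this model family descends from.

## Passive material laws

Three laws share the fiber/sheet/normal frame
$(\mathbf f_0, \mathbf s_0, \mathbf n_0)$:

* **TIC** — transversely isotropic, *compressible*, polynomial:
  $\Psi = \tfrac\Lambda2 \ln^2 J + \tfrac\mu2 (I_1 - 3 - 2\ln J)
  + \vartheta\,\tfrac\eta2 (I_{4f}-1)^2$.
* **TII** — transversely isotropic, *nearly incompressible*, polynomial:
  $\Psi = \tfrac\mu2(\bar I_1 - 3) + \vartheta\,\tfrac\eta2(\bar I_{4f}-1)^2
  + \kappa (J-1)^2$, with isochoric invariants
  $\bar I_\bullet$ of $\bar{\mathbf C} = J^{-2/3}\mathbf C$.
* **HO** — orthotropic, nearly incompressible, exponential
  (Holzapfel–Ogden form):
  $\Psi = \tfrac a{2b} e^{b(\bar I_1-3)}
  + \sum_{i\in\{f,s\}} \vartheta_i \tfrac{a_i}{2b_i}
    \big(e^{b_i(\bar I_{4i}-1)^2}-1\big)
  + \tfrac{a_{fs}}{2b_{fs}}\big(e^{b_{fs}\bar I_{8fs}^2}-1\big)
  + \kappa (J-1)^2$.

The quadratic/exponential fiber and sheet terms carry a *tension switch*
$\vartheta$: they contribute only when the corresponding stretch exceeds one
(total stretch $\lambda=\sqrt{I_{4f}}$ for TIC, isochoric stretch for
TII/HO).  The switch is a sharp Heaviside evaluated per quadrature point; the
tangent at the switch point uses the one-sided branch selected by the strict
inequality $\lambda > 1$, which makes the reference-state tangent the plain
isotropic one.  The fiber–sheet shear term uses $\bar I_{8fs}^2$, so the sign
of shear is immaterial, and it carries no switch.  Stresses and consistent
tangents are analytic; a generic invariant toolkit assembles
$2\,\partial\Psi/\partial\mathbf C$ and $4\,\partial^2\Psi/\partial\mathbf
C^2$ from per-invariant first/second derivatives, which keeps all three laws
on one verified code path (finite-difference checked to $10^{-6}$ relative
for stress, $10^{-5}$ for the tangent).

Near-incompressibility is enforced by the displacement-only penalty
$\kappa(J-1)^2$ with $\kappa = 10^4$ kPa.  A stabilized selectively
reduced integration of the penalty (`vol_sri`) is implemented with a fully
consistent linearization: a small fraction (default 5 %) of $\kappa$ stays
on the full $2\times2\times2$ quadrature and the remainder is integrated
at the element center only.  The center-point part relieves the volumetric
locking of coarse hexahedra; the retained full-quadrature part keeps the
tangent away from singularity when the deviatoric response is very soft
(with pure single-point integration and the HO ground stiffness of a few
hundredths of a kPa, the element volumetric modes are almost unconstrained
and Newton fails at the first stimulus).  The flag is off by default — the
plain penalty formulation — and switched on by the ventricle driver, which
runs coarse meshes.

### Parameter values

The HO constants are one half of the classical simple-shear fit of the
Holzapfel--Ogden law to porcine shear data, a standard way to obtain
rat-scale stiffness: $a = 0.0295$, $b = 8.023$, $a_f = 9.236$,
$b_f = 16.026$, $a_s = 1.2405$, $b_s = 11.12$, $a_{fs} = 0.108$,
$b_{fs} = 11.436$ (stress-like constants in kPa).

The polynomial models were calibrated once, by least squares, against the
same six simple-shear response curves evaluated from the HO set over shear
0--0.5: $\mu = 0.39$ kPa (carried by the transverse modes) and
$\eta = 21.3$ kPa (carried by the fiber modes).  TIC shares $\mu$ and
$\eta$ and adds $\Lambda = 2\mu = 0.78$ kPa, a distinctly compressible
first Lam\'e constant, so that compressibility — not overall stiffness —
differentiates the two polynomial laws.  A polynomial cannot reproduce an
exponential over the whole strain range: the polynomial laws are stiffer
than HO at small strain and softer at large strain, which is exactly the
trade-off such fits show when plotted over the shear data.  These values
are frozen package defaults and are not re-tuned per experiment.

## Electrophysiology

The two-variable phenomenological excitation model uses a dimensionless
potential $\phi$ and recovery variable $r$:

$$f^\phi_e = c\,\phi(\phi-\alpha)(1-\phi) - r\phi + I, \qquad
  \dot r = \Big[\gamma + \frac{\mu_1 r}{\mu_2 + \phi}\Big]
  \big[-r - c\,\phi(\phi - b - 1)\big],$$

with $\alpha = 0.01$, $c = 8$, $b = 0.15$, $\mu_1 = 0.2$, $\mu_2 = 0.3$.
Physical scales are $\Phi = k_\phi\phi - \delta_\phi$ with $k_\phi = 100$ mV
and $\delta_\phi = 80$ mV (rest at $-80$ mV, $\phi_s = 0.6$ at $-20$ mV) and
$t = k_t\bar t$ with $k_t = 12.9$ ms.  The recovery rate $\gamma$ controls
the late repolarization tail.  We calibrated it once, at the single-cell
level, so that a cell stimulated at $t=0$ is repolarized to about
$-78.5$ mV by $t = 300$ ms — the cardiac-cycle timeline of the ventricular
study — which gives $\gamma = 0.012$; it is then frozen.

Conduction is deformation-dependent,
$\mathbf D = J d_{\mathrm{iso}} \mathbf C^{-1} +
J d_{\mathrm{ani}}\, \mathbf f_0\!\otimes\!\mathbf f_0/\lambda^2$; the
fiber-direction term adds to the isotropic part.  The plate benchmark uses
$d_{\mathrm{iso}} = 1.0$, $d_{\mathrm{ani}} = 0.1$ mm$^2$/ms at the
100 mm scale and $d_{\mathrm{iso}} = 0.1$, $d_{\mathrm{ani}} = 0.3$ at the
rat scale, the latter also for the ventricle.

The stretch-activated (MEF) current is
$f^\phi_m = \vartheta\,G_s(\lambda - 1)(\phi_s - \phi)$ with the same sharp
switch $\vartheta = [\lambda > 1]$, $\lambda = \sqrt{I_{4f}}$ of the *total*
deformation (the same $\lambda$ used in the conductivity, to keep the two
couplings consistent).  It is depolarizing for $\phi < \phi_s$ under
tension.  Both kinetic sources enter the physical equation scaled by
$k_\phi/k_t$, applied once at assembly.

## Active stress

The active fiber tension follows
$\dot T = \varepsilon(\Phi)\,[\,k_T(\Phi - \Phi_r) - T\,]$ with
$k_T = 0.49$ kPa/mV and $\Phi_r = -80$ mV, so a sustained plateau of
$+20$ mV saturates the tension at $49$ kPa.  The activation rate
$\varepsilon(\Phi) = \varepsilon_0 + (\varepsilon_\infty - \varepsilon_0)
\exp(-e^{-\xi(\Phi - \bar\Phi)})$ switches smoothly from a slow resting rate
($\varepsilon_0 = 0.1$/ms, relaxation) to a fast depolarized rate
($\varepsilon_\infty = 1$/ms) around $\bar\Phi = 0$ mV with
$\xi = 0.1$/mV.  After repolarization the tension decays to zero, which is
what lets the ventricle return to its initial shape when the feedback is
off.

## Discretization and solver

Eight-node hexahedra with $2\times2\times2$ Gauss quadrature carry both
fields (dofs per node: $u_x, u_y, u_z, \Phi$).  Time integration is backward
Euler for $\dot\Phi$ and for both internal variables, which live at
quadrature points: $r$ by a local implicit (scalar Newton) update and $T$ by
its closed-form backward-Euler step, both re-evaluated *inside* every global
Newton iteration with their consistent sensitivities
$\partial r/\partial\phi$, $\partial T/\partial\Phi$.  The monolithic
Jacobian therefore carries all four blocks, including
$\partial R_u/\partial\Phi$ through the active tension and
$\partial R_\Phi/\partial\mathbf u$ through the deformed conductivity and
the stretch current; a global finite-difference test keeps it honest to
$10^{-5}$ relative.

The linear solves use a sparse LU with approximate-minimum-degree ordering
and relaxed partial pivoting.  The factorization of an earlier Jacobian is
reused across iterations and steps: each Newton direction is obtained from
the cached factor plus iterative refinement against the freshly assembled
matrix, and the matrix is refactorized only when refinement stops
contracting (stale factor) or the constraint set or step size changes.
Newton directions are therefore (near-)exact in either case, convergence is
always judged on the true assembled residual, and in the nearly linear
regime the iteration converges quadratically.  Two robustness layers wrap
the iteration: a divergence/overshoot backtracking line search (halving the
last update up to eight times when the residual jumps or an element inverts
mid-iteration), and automatic time-step halving (up to five times) with
geometric recovery.  Dirichlet data — mechanical fixations, the stimulus
potential, prescribed plateau drives — are imposed by row elimination; the
stimulus value is ramped over 2 ms to avoid shocking the soft exponential
material in the first step, and stimulus nodes return to free evolution
when the stimulus window ends.

Default steps are 0.5 ms for the plate benchmarks and 1 ms for the
ventricle runs, coarsened to 2 ms after 150 ms when the dynamics are down
to the slow repolarization tail; a dt- and mesh-consistency test on a
fiber-direction conduction strip keeps the front-arrival discretization
error within 2 % (dt halving) and 5 % (mesh halving).  Newton tolerances
are absolute residual norms in the mN / mV mm$^3$ ms$^{-1}$ residual units;
the drivers use 1e-3 (plate) and 1e-4 (ventricle), several orders below
the milli-Newton force scale of the experiments, because the sharp tension
switches produce a residual chatter floor near 1e-4 under the softest
parameter sets; the reported read-outs are insensitive to a further
tightening (checked to 1e-6).

## Geometries

All meshes are generated programmatically; nothing is read from disk.

* **Plate**: structured bricks, $21\times21\times2$ by default; fibers along
  $x$, sheets along $y$.  Mid-plane edge nodes fixed in $z$, two corner pins
  remove the in-plane rigid modes, and the central parallelepiped (one fifth
  of the plate in each in-plane direction, full thickness) takes the
  triangular load pulse (peak at 5 ms, zero at 10 ms).
* **Cube**: unit cube with uniform fibers and a minimal 3-2-1 rigid-body
  support; used for isotonic contraction under a prescribed uniform
  potential plateau.
* **Left ventricle**: a synthetic truncated ellipsoid at rat scale
  (endocardial semi-axes $2.5\times2.5\times4.5$ mm, epicardial
  $4\times4\times6$ mm, truncated at the equatorial plane), meshed as a
  structured hexahedral shell closed at the apex by collapsed-hex wedges
  around the axis.  This stand-in deliberately replaces an image-derived
  geometry; it reproduces wall thickness, apex-to-base distance and
  transmural fiber rotation at rat scale, but not the individual anatomy, so
  ventricle-specific printed numbers are reproduced only as orderings and
  signs, not magnitudes.  The transmural coordinate $d$ comes from the
  analytic interpolation parameter between the two ellipsoid surfaces; the
  helix angle varies linearly from $+80^\circ$ (endocardium) to $-70^\circ$
  (epicardium) about the circumferential direction, the sheet direction is
  transmural (a standard rule-based choice; the sheet field of a real
  ventricle is more structured), and frames are orthonormalized per element.
  Hexahedra were chosen over the more common tetrahedra for this geometry
  because a conforming structured shell needs no general mesh generator and
  linear tetrahedra with a volumetric penalty lock badly; the collapsed
  wedges at the apex keep positive Jacobians at all interior quadrature
  points.

## Study drivers

* `run_plate_benchmark()` reproduces stretch-induced excitation: the load
  pulse stretches the central fibers, the stretch current ignites a
  depolarization wave ($G_s = 15$), and the completion time — the earliest
  time every nodal potential exceeds 0 mV — is reported.  The pulse
  magnitude is not part of the printed protocol at rat scale; the naive
  loaded-area scaling of the large-plate pulse produces well under 1 %
  fiber stretch (the stiff fiber term $\eta$ dominates out-of-plane
  loading), which cannot nucleate a wave against diffusion — a sub-critical
  nucleus.  The default (60 mN small plate, 6000 mN large, a configurable
  override) is instead calibrated once to stretch the center region to
  $\lambda \approx 1.13$, which nucleates reliably at the load peak.
  Completion time is then governed by conduction, not by the load choice.
* `run_cube_isotonic()` drives a free cube with a plateau from 10 ms to
  250 ms inside a 350 ms window and records $J(t)$: the compressible TIC
  loses volume ineluctably during the plateau, while TII/HO stay within
  $|J-1| < 10^{-2}$ by the penalty.
* `run_lv_sweep()` runs the ventricular protocol per passive model and
  $G_s$: base ring mechanically fixed, seven contiguous basal endocardial
  rim nodes held at $-20$ mV for 40 ms, apex (epicardial pole) probed.
  Runs last 420 ms with the residual ("peak 2") level read as the mean over
  the final 50 ms, a window in which a feedback-free cell has settled at
  rest; metrics are
  $\Delta\square_{i} = |\square_i(G_s{=}0) - \square_i(G_s{=}x)|$ for the
  peak-1 maximum/time and the residual potential and displacement.

The acceptance-scale study uses a 1.25 mm target mesh (160 elements) so
the full sweep stays within desk-scale runtimes; this resolves two elements
across the wall, which is coarse but preserves the transmural fiber
rotation that drives mid-wall stretch — the mechanism behind the feedback
differences between the laws.  On this synthetic ventricle the feedback
effects are much larger than the printed ventricle-specific values (tens of
mV of residual potential instead of a couple): the stretch levels of the
synthetic wall put the stretch current well beyond its small-signal regime.
Orderings and signs are the reproducible content here, not magnitudes.

## What the synthetic data do and do not show

The generators emulate the study conditions (geometry scale, fiber rules,
stimulus and loading protocols, parameter sets), not any individual heart:
no chamber pressure, no Purkinje system, no right ventricle, a fixed base,
and a phenomenological two-variable cell model.  Passing tests therefore
demonstrate the *mechanisms* — stretch-triggered excitation, volume behavior
by material class, residual depolarization/deformation under feedback and
its ordering across material laws — and not patient- or animal-specific
magnitudes.

## Known limitations

* On the synthetic ventricle the stretch-current response of the HO law
  *saturates*: its residual potential at a maximum conductance of 10 is
  already tens of mV above rest, and at 50 the apex residual is lower than
  at 10 (the feedback redistributes spatially once the residual approaches
  the channel reversal potential).  Strict monotonicity of the residual
  metrics in the conductance therefore holds for the polynomial
  incompressible law but not for the exponential one under the package's
  frozen parameter set; this is a regime difference of the soft exponential
  ground state, reproducible at two mesh resolutions, and documented rather
  than tuned away.

* Coarse hexahedra with the full-integration penalty are volumetrically
  stiff (locking); the stabilized selective integration used by the
  ventricle driver relieves most but not all of it, and retains a small
  fully integrated penalty fraction purely for conditioning.
* The apex wedge elements are first-order accurate at best near the pole.
* Quasi-static mechanics omits inertia; very fast load transients are then
  resolved only through the time regularization of the load pulse itself.
* The polynomial stiffness values are a one-time least-squares fit to the
  HO shear response standing in for the underlying shear data; other
  published parameter sets will shift the magnitudes (and, near saturation,
  some orderings) of the feedback metrics.
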