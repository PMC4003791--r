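---
title: "Methods: 3D diffuse optical tomography with Broyden-accelerated MoBIIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D diffuse optical tomography with Broyden-accelerated MoBIIR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the forward model and its assumptions, the inverse method, the synthetic
study the package ships, and the numerical and design choices that were
genuinely open.  Nothing here states an empirical result that the test
suite does not itself compute.

## Forward model

Near-infrared light transport in strongly scattering tissue is modelled by
the continuous-wave (time-independent) diffusion approximation to the
radiative transfer equation,

$$-\nabla\cdot\kappa(r)\nabla\Phi(r) + \mu_a(r)\,\Phi(r) = q_0(r),
\qquad \kappa = \frac{1}{3(\mu_a + \mu_s')},$$

where $\Phi$ is the photon density, $\mu_a$ (mm$^{-1}$) the absorption
coefficient, $\mu_s'$ (mm$^{-1}$) the reduced scattering coefficient and
$\kappa$ (mm) the diffusion coefficient.  The approximation requires
$\mu_s' \gg \mu_a$; `optical_map()` warns when $\mu_s' < 10\mu_a$
anywhere.  The boundary carries the Robin condition
$\Phi + 2A\kappa\,\partial\Phi/\partial n = 0$ with Fresnel coefficient
$A$.  No published value of $A$ exists for the reference study, so the
default is the index-matched choice $A = 1$, exposed as a setting of
`build_scan_geometry()`.

The time-derivative term of the transient diffusion equation is dropped:
only the continuous-wave amplitude is modelled.  Frequency-domain (complex)
solves, radiative-transfer or Monte-Carlo forward models, and anisotropic
$\kappa$ are out of scope.

### Discretization

Galerkin finite elements on linear tetrahedra give the sparse symmetric
system $[K(\kappa) + C(\mu_a) + F]\,\Phi = Q$ with exact element
integrals: stiffness $\kappa_e V (\nabla b_i\cdot\nabla b_j)$ with
constant basis gradients, element mass $\mu_a V/10$ (diagonal) and
$\mu_a V/20$ (off-diagonal), and boundary-triangle mass $S/6$ and $S/12$
scaled by $1/(2A)$.  The system is solved by sparse Cholesky factorization
(`Matrix::Cholesky`), cached so that all sources and adjoint sources of a
scan reuse one factorization; every solution is verified to a relative
residual of $10^{-8}$.  An iterative solver was considered and rejected:
at the problem sizes the package targets (≤ 15 k nodes) the direct solve
is both faster and exact.

Sources are modelled by the standard collimated-source approximation: an
isotropic point source placed one transport mean free path, $1/\mu_s'$,
inside the surface along the inward normal, its unit strength spread onto
the enclosing tetrahedron's nodes by barycentric weights.  Detectors read
$\Phi$ at the boundary by barycentric interpolation on the containing
boundary face.  Both choices are unspecified in the reference study; they
are the common defaults of diffusion-theory codes.

## Inverse method (MoBIIR)

The reconstruction minimises the $L_2$ data misfit
$\chi(\mu_a) = \lVert M^E - F(\mu_a)\rVert_2$ over element-wise constant
$\mu_a$ (only absorption is reconstructed; $\kappa$/$\mu_s'$ recovery is a
non-goal).  Each iteration applies the damped normal-equations step

$$\Delta\mu = (J^\top J + \lambda I)^{-1} J^\top \Delta M .$$

When parameters outnumber measurements — always, here — the algebraically
identical dual form
$\Delta\mu = J^\top (J J^\top + \lambda I)^{-1}\Delta M$ is used so the
factorized system is only `n_pairs × n_pairs`.

The Jacobian is computed **once**, at the homogeneous initial estimate, by
the adjoint method: entry $(s d, e)$ is $-\int_e \Phi_s \Phi_d\,dV$,
evaluated exactly from the element mass matrix.  One build costs one
forward solve per unique source plus one adjoint solve per unique detector
position (the package counts solver calls to keep this honest).  All later
iterations maintain $J$ by the Broyden rank-1 secant update; among all
matrices satisfying the secant condition it is the Frobenius-closest to
the previous Jacobian.  A conventional mode that rebuilds the adjoint
Jacobian every iteration is available for comparison
(`mobiir_settings(broyden = FALSE)`).

The derivative is taken with respect to the absorption term alone, holding
$\kappa$ fixed: the $\kappa(\mu_a)$ cross-sensitivity is of relative order
$\mu_a/\mu_s' \approx 10^{-2}$ and is ignored, as is standard in DOT
linearization.  The finite-difference verification Jacobian uses the same
convention, and the two agree to better than $10^{-3}$ on the largest
entries (tested).

### Regularization

$\lambda$ is parameterised as $\alpha\,\mathrm{tr}(J^\top J)/n_{el}$, i.e.
$\alpha$ times the mean diagonal of the Gauss–Newton Hessian, recomputed
from the current Jacobian each iteration.  The default is $\alpha = 1$,
the classic Marquardt scaling.  Smaller values ($\alpha \lesssim 10^{-2}$)
were evaluated and rejected: they drive the residual far below the
inter-mesh model-error floor (over-fitting), push background elements onto
the positivity floor and displace the recovered inclusions — the
discrepancy principle favours stopping near that floor.  An optional
geometric easing of $\alpha$ per iteration (`alpha_decay`) is off by
default.  Row normalization of the Jacobian is available but off by
default; spatially varying (column/depth) regularization is deliberately
not offered.

### Step control and stopping

Positivity is enforced by clamping to a floor ($10^{-4}$ mm$^{-1}$) after
each additive update.  A step that increases the misfit is halved up to 5
times; if no decrease is found the loop stops.  Additional stopping rules:
maximum iterations (default 25) and relative cost change below $10^{-4}$.
A cost exceeding $10\times$ the initial misfit raises a divergence error
carrying the trajectory.

### Calibration

Reconstructing data simulated on a fine mesh with a coarser model mesh
exposes a systematic per-pair discretization offset much larger than the
inclusion signal.  As in experimental practice — where source/detector
coupling is unknown — the data are calibrated against a homogeneous
reference: $M^{cal}_i = M^E_i \cdot M^C_{ref,i} / M^E_{ref,i}$, with the
reference measured (or simulated) like the data and predicted by the model
at the initial homogeneous estimate.  The synthetic pipeline therefore
simulates a homogeneous-reference measurement alongside each phantom
measurement.

## The synthetic study

The generator reproduces the reference simulation study: a cylinder of
diameter 60 mm and height 70 mm, background $\mu_a = 0.01$ mm$^{-1}$,
$\mu_s' = 1.0$ mm$^{-1}$, with a spherical absorber (diameter 7.9 mm,
centre $(0, -16, -10)$, $\mu_a = 0.02$) and a z-parallel full-height
cylindrical absorber (diameter 7.9 mm, $\mu_a = 0.03$).  The transverse
position of the cylindrical absorber is not published; it is placed at
$(0, +16)$, mirroring the sphere, and is configurable.  A second,
"experimental-style" phantom uses background $(0.005, 0.8)$ with
full-height cylinders of 10 and 12 mm at $\mu_a = 0.02$ and $0.035$.
Inclusion membership is decided by element centroid — unambiguous for
element-wise constant coefficients.

Measurements use 12 equally spaced sources per plane and, for each source,
7 detectors on the opposite side; the detector arc (120°–240° in 20°
steps) and the plane levels ($z = \pm 10$ mm for two planes,
$0, \pm 15$ mm for three) are not published and are configurable defaults.
Noise is multiplicative white Gaussian,
$M \mapsto M(1 + \epsilon\,\mathcal N(0,1))$ at level $\epsilon$ (2 % in
the robustness study): relative noise is the standard DOT convention and
is scale-free across detectors.

Meshes come from a deterministic generator: a ring-structured disk
triangulation extruded along $z$ into prisms, each split into three
conforming tetrahedra by the minimum-vertex-index diagonal rule.  The
presets approximate the reference discretizations of roughly 14.6 k /
30.8 k / 66.5 k tetrahedra to within a few percent (the original mesh
generator is unknown, so exact counts are not a contract).  Data are
always simulated on a finer mesh than the reconstruction mesh; an
inverse-crime guard refuses same-size pairs unless explicitly overridden.

### What the generator does and does not emulate

It emulates the published geometry, optical coefficients, scan pattern and
noise level.  It does **not** emulate the physical instrument: modulation
and lock-in detection, fibre coupling, LED spectra, phase data, or
detector nonlinearity.  Passing tests therefore demonstrate correctness of
the numerical method under the stated model, not performance on real
measurements.

## Validation design and numerical choices

* **Forward accuracy** is checked against the infinite-medium Green's
  function $\exp(-\mu_{\mathrm{eff}} r)/(4\pi\kappa r)$,
  $\mu_{\mathrm{eff}} = \sqrt{\mu_a/\kappa}$, for an interior point source.
  The comparison uses 1 mm spherical-shell averages over
  $r \in [5, 15]$ mm: pointwise nodal values on the ~3 mm fine-preset
  elements carry $O(h^2\,\Phi''/\Phi)$ interpolation scatter on a field
  this sharp, while shell averages isolate the discretization bias.
* **Scan-symmetry convergence**: the node layout repeats every 60°, but
  the index-based tetrahedralization does not, so rotational symmetry of
  homogeneous boundary data holds only up to discretization error; the
  tests assert that this error shrinks under refinement rather than that
  it vanishes.
* **Far-field sign artifacts**: at 60 mm source–detector separations the
  field decays by $e^{-10}$, and coarse meshes oscillate slightly negative
  in the far field.  Presets below ~9 k elements can produce negative
  boundary readings; the packaged presets do not.  A consequence is that a
  small fraction (≲ 2 %) of adjoint-Jacobian mass is spuriously positive
  on coarse meshes; all signal-carrying entries are negative.
* **Problem sizes in the shipped study**: data on the fine preset
  (~67 k elements), reconstruction on the coarse preset (~15 k elements),
  20 iterations — sizes chosen so the full study, including the 5-seed
  noise experiment, runs in minutes on a single core while preserving the
  published phantom and scan configuration exactly.

## Known limitations

* The damped $L_2$ Gauss–Newton/LM solution blurs small deep targets: in
  the shipped study the 7.9 mm, 2:1-contrast sphere is localized to within
  a few millimetres, but its *mean* recovered contrast inside the true
  footprint saturates near 1.25× background across the entire admissible
  setting range (damping scale, row normalization, Broyden vs
  conventional, plane count, iteration budget — even with data generated
  on the reconstruction mesh itself).  This is the resolution limit of
  unweighted $L_2$ regularization with 168 continuous-wave measurements,
  not a solver defect; edge-preserving priors that would sharpen it are
  out of scope.  The high-contrast full-height cylinder does not suffer
  from this: its recovered contrast exceeds 1.5× background.
* Reconstruction quality near threshold is seed-sensitive under 2 %
  noise: the cylinder's recovered contrast scatters by roughly ±0.07
  around ~1.5 across noise realisations.
* The CW data carry no path-length (phase) information, so simultaneous
  $(\mu_a, \mu_s')$ separation is impossible in principle and not
  attempted.
* Meshes are limited to the structured cylinder generator plus MSH/VTK
  import of externally generated tetrahedral meshes; no adaptive or
  curved elements.
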