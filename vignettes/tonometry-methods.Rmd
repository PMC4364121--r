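---
title: "Methods: simulating non-contact tonometry of the human cornea"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tonosim` simulates the air-puff test used by non-contact tonometers: a
cornea loaded by its intraocular pressure (IOP) receives a metered air
pulse, and the maximum posterior displacement of its apex (the
*deformation amplitude*) is the clinical readout. This vignette documents
the model, its parameters, the numerical machinery and the choices made
where the design was genuinely open — the things a user should know
before trusting, or extending, a result.

## Constitutive models

The corneal stroma is a stack of collagen lamellae in a hydrated matrix;
macroscopically it behaves as an anisotropic, nearly incompressible
hyperelastic solid with two preferred fiber directions (nasal-temporal
and superior-inferior, turning circumferential at the limbus). We use the
Gasser–Holzapfel–Ogden (G-H-O) energy

$$U = C_{10}(\bar I_1 - 3) + U_{vol}(J) +
      \frac{k_1}{2k_2}\sum_{\alpha=1}^{N}
      \left(e^{k_2\langle E_\alpha\rangle^2} - 1\right),
\qquad
E_\alpha = \kappa(\bar I_1 - 3) + (1-3\kappa)(\bar I_{4(\alpha\alpha)} - 1),$$

where $\bar I_1$ is the first modified invariant, $\bar I_{4}$ the squared
isochoric fiber stretch, $\kappa \in [0, 1/3]$ the in-plane fiber
dispersion and $\langle\cdot\rangle$ the Macaulay bracket: fibers buckle
under compression and only store energy when $E_\alpha > 0$. All families
share $(k_1, k_2, \kappa)$. Parameters and units:

| parameter | meaning | unit | presets A / B / C |
|---|---|---|---|
| `C10` | matrix shear-like modulus | MPa | 0.05 |
| `D`   | compressibility (0 = incompressible) | MPa⁻¹ | 0 |
| `k1`  | fiber stiffness | MPa | 25 / 60 / 130.9 |
| `k2`  | fiber exponential coefficient | – | 2490 |
| `kappa` | fiber dispersion | – | 0.33329 |

The three presets span the soft-to-stiff range observed in human corneal
inflation tests; `uniaxial_response()` and `membrane_inflation()`
reproduce the corresponding homogeneous-deformation and apical-rise
curves and are tested for the A < B < C stress ordering and the
A > B > C inflation-rise ordering.

Two consequences of $\kappa = 0.33329 \approx 1/3$ matter for
interpretation. First, the fiber term is almost isotropic: $1-3\kappa =
1.3\times10^{-4}$, so the direction-specific part of $E_\alpha$ is four
orders of magnitude weaker than the dispersed part. Second, because
$\bar I_1 \ge 3$ always, $E_\alpha$ is non-negative wherever the material
deforms at all — the tension-only cutoff switches fibers off *exactly*
only in the aligned limit $\kappa = 0$. At the bent anterior apex the
dispersed fiber term therefore still carries a modest share of the
compressive stress (about 29% in the baseline run). The package keeps
$\kappa = 0.33329$ exact and never rounds it to $1/3$.

The sclera uses the isotropic Yeoh energy
$U = \sum_i C_{i0}(\bar I_1-3)^i + \sum_i (1/D_i)(J-1)^{2i}$. Its
coefficients are not patient-derived; the shipped defaults
(C10 = 0.81, C20 = 56.05, C30 = 2332.26 MPa) are representative
literature-range values, configurable in `inst/extdata/presets.yaml`,
and the results are insensitive to them (the globe moves ~0.01 mm during
a puff). Limbus material equals the cornea by default.

`D = 0` is treated as incompressibility imposed through a volumetric
penalty $U_{vol} = \tfrac{\kappa_v}{2}(J-1)^2$ with bulk modulus
$\kappa_v = 1000\,C_{10}$ (configurable via `bulk_factor`). When `D > 0`
the standard $\frac1D(\frac{J^2-1}{2} - \ln J)$ form is used. A cap on
$k_2\langle E\rangle^2$ (default 50) turns fiber-exponential overflow
into a loud error instead of silent infinities.

## Geometry, axisymmetric reduction, mesh

The cornea is built from two conics of revolution (apical radius +
asphericity, the parameterization topographers report), with the central
thickness enforced exactly on the axis. Thickness variation
(`thickness_offset`, or `geometry_preset("baseline", cct = ...)`) moves
the posterior surface along the anterior normal, leaving the anterior
shape — what a device images — unchanged, and tapers to zero across the
limbus so the sclera is unaffected. The limbus is a 1 mm Hermite-blended
ring; the sclera a 25 mm-diameter spherical cap down to its equator, with
wall thickness defaulting to the limbal thickness (both are weakly
constrained anatomically and configurable). Axial displacement is
restrained on the equatorial scleral cut, radial displacement on the
axis.

The model is axisymmetric. This is justified by the near-isotropic
dispersion above (the two orthogonal fiber families reduce to one
meridional + one circumferential family with no measurable loss of
anisotropy at $1-3\kappa = 1.3\times10^{-4}$) and by the small
astigmatism (0.4 D) of the baseline eye. Patient-specific 3D topography
is out of scope; the topography module instead *emulates* a topographer
export from the conic model (`synthesize_topography()`) and recovers
(R, Q, CCT) by linear least squares (`recover_geometry()`), exactly on
noise-free data.

The mesh uses 9-node Lagrangian quadrilaterals (biquadratic), the single
element family implemented: quadratic interpolation is needed for
bending through 2–5 thickness elements, and one well-tested kernel was
preferred over a configurable triangle/quad pair. Default densities are
40 meridian × 3 thickness elements (567 nodes); the IOP-pressurized apex
displacement changes by 0.2% and a full puff run by < 0.1% when both
densities are doubled (asserted in the test suite as a nested-refinement
convergence check).

## FE engine

Total-Lagrangian kinematics with the axisymmetric deformation gradient
(hoop stretch $1 + u_r/R$; on the axis the limit $F_{33} = F_{11}$ is
used). Near-incompressibility is handled by selective reduced
integration: deviatoric terms at 3×3 Gauss points, volumetric penalty at
2×2 — a displacement-only approximation of a mixed pressure formulation,
adequate for the displacement-level quantities reported here. IOP is a
follower pressure on the whole interior surface (load stiffness
included, unsymmetric); the jet is a collimated axial traction acting on
the projected deformed surface, matching a collimated air column
(a surface-normal follower variant would differ only at large surface
slopes). The assembled Jacobian is exact (verified by finite differences
to 1e-10) and the follower reaction balances pressure × projected area
to machine precision.

Newton iteration with load stepping: default relative residual tolerance
1e-8 (absolute floor 1e-10 N for zero-load states), 10 increments for a
cold start, one warm-started increment per puff step, adaptive bisection
of failed increments. Two non-standard choices earn their keep here:

* **Non-monotone step acceptance.** The exponential fiber stiffening
  produces a large transient residual hump that full Newton steps cross
  in a handful of iterations; a monotone line search rejects those steps
  and creeps. Steps are therefore accepted unless they produce an
  inadmissible state (element inversion, material overflow) or an
  outright blow-up; after half the iteration budget the solver falls
  back to strict monotone backtracking.
* **Step cap.** Near applanation the central cornea passes a
  shallow-shell snap regime where the tangent is nearly singular; the
  largest nodal increment of a Newton step is capped (default 0.4 mm) to
  keep those steps bounded.

Warm starts that fail (e.g. a stale displacement seed across
zero-pressure iterates) silently fall back to a cold ramp.

## Zero-pressure algorithm

Imaged geometry is IOP-loaded, so simulations must start from the
unknown stress-free shape. `find_stress_free()` implements the undamped
fixed-point rule: pressurize the candidate, form the error
$E = x_{def} - X_{ref}$, update $X_{init} \leftarrow X_{init} - E$, stop
when $\|E\|_\infty < \varepsilon$. Restrained coordinates are excluded
from both the update and the norm. Defaults $\varepsilon = 10^{-4}$ mm
and 50 iterations are package choices; the baseline cornea converges
geometrically in ~5 iterations at any preset/IOP combination. An
optional damping factor and an element-inversion guard (bisect the
update if the mesh would tangle) handle stiff cases; the linear-model
fixed point (one update) and the stiffness → ∞ limit (vanishing
correction) are tested.

## Air-puff load model

The pulse is parametric, since only its scalar specification is known:
peak 25 kPa, duration 30 ms, and a footprint whose ≥ 90%-of-peak region
is 3 mm in diameter. Temporal shape: $\sin^2(\pi t/T)$ (smooth, zero at
both ends, peak at mid-pulse). Spatial shape: flat-top super-Gaussian
$e^{-(r/r_0)^m}$ with $m = 8$ and $r_0$ calibrated so the 90% contour
sits exactly at $r = 1.5$ mm. Only the rising half of the pulse is
traversed: the model is elastic and quasi-static, so the unloading path
is a mirror image and only the maximum displacement is of interest.
Applanation is detected as the zero crossing of the central anterior
meridional curvature (even quadratic fit over the central ±0.75 mm,
tolerance 1e-3 mm⁻¹, linear interpolation in time); the displacement
datum is the IOP-loaded pre-puff state, i.e. what a device camera sees
at puff onset.

## Parametric studies

`run_grid()` executes named grids (`"iop_study"`: IOP {10, 12, 19, 28}
mmHg × materials {A, B, C}; `"cct_study"`: CCT 300–600 µm in 50 µm steps
for C at IOP {10, 19, 28} and A, B at IOP 19), caches prestress results
across rows, records failures per row, and is deterministic for a fixed
configuration. `fit_linear()` / `fit_cubic()` are ordinary least
squares; for a zero-variance response the slope is 0 and $R^2$ is
defined as 0. `overlap_analysis()` reports the per-material displacement
intervals over the IOP range and their pairwise intersections.

Problem sizes: a full tonometry run uses the default 40 × 3 mesh,
~5 prestress pressurizations and 24 puff steps (a few seconds each on
one CPU); the acceptance script runs the eleven-simulation physiological
sweep, chosen to keep a complete reproduction within minutes while
staying mesh-converged.

## What the synthetic data do and do not show

The generator emulates an axisymmetric healthy eye with conic surfaces
and optional Gaussian measurement noise. It does not produce
astigmatism, keratoconic thinning patterns, surface irregularity or
correlated topographer noise — so passing tests demonstrate the
mechanics of the pipeline on idealized geometry, not robustness to real
device exports.

## Known limitations

* **Quasi-static traversal.** The 30 ms pulse is traversed without
  inertia (tissue density and the fluid chamber are not modelled).
  Together with the parametric jet footprint this is the main reason the
  soft and intermediate presets overshoot clinically reported
  deformation amplitudes (healthy-eye devices report ~0.7–1.3 mm; the
  sweep computed by `scripts/acceptance.R` spans 1.06–2.76 mm, with the
  stiff preset C inside the clinical band and A/B above it). The
  flat-top footprint delivers ~0.28 N of total jet force; a jet whose
  pressure decays inside the 3 mm spot, as impingement CFD profiles do,
  would deliver roughly half, and inertia would further reduce the peak
  response. Because the operating point at 25 kPa sits deep in the
  fiber-stiffened regime, this also compresses the *relative* influence
  of IOP, so the per-material displacement intervals over IOP 10–28 mmHg
  do not overlap in this configuration.
* **Constant IOP.** The chamber pressure does not rise as the cornea is
  indented (no fluid model) — shared with comparable FE studies.
* **Elasticity only.** No viscoelasticity; the recovery phase and
  corneal hysteresis are out of scope.
* **Penalty incompressibility.** Displacement-level results are
  insensitive to `bulk_factor` above ~10³, but pointwise pressures are
  smoother in a true mixed formulation; Gauss-point stresses are the
  reliable sampling locations (probes evaluate stress at the nearest
  reduced-integration point for this reason).
* **Fiber "irrelevance" in compression is approximate.** See the
  dispersion discussion above: at $\kappa = 0.33329$ the anterior apex
  keeps a weak fiber contribution; only the aligned limit switches off
  exactly.
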