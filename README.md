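# tonosim

Simulation of corneal biomechanics under non-contact (air-puff) tonometry.

Non-contact tonometers deform the cornea with a metered air pulse while
imaging its motion, and report the *deformation amplitude* — the maximum
posterior displacement of the corneal apex. That amplitude is not a pure
material readout: it mixes the intraocular pressure (IOP), the central
corneal thickness (CCT) and the stiffness of the stromal collagen network.
`tonosim` is an in-silico laboratory for studying this coupling. It is
aimed at researchers in ocular biomechanics who want a transparent,
scriptable alternative to commercial finite-element stacks for air-puff
sensitivity studies.

## What is inside

* **Constitutive models.** Cornea and limbus follow the
  Gasser–Holzapfel–Ogden (G-H-O) anisotropic hyperelastic energy with two
  dispersed, tension-only collagen fiber families:

  U = C10 (Ī₁ − 3) + U_vol(J) + k1/(2k2) Σ_α ( exp[k2 ⟨E_α⟩²] − 1 ),
  E_α = κ (Ī₁ − 3) + (1 − 3κ)(Ī₄(αα) − 1),  ⟨E⟩ = max(E, 0)

  with κ ∈ [0, 1/3] the fiber dispersion (κ = 1/3 is isotropic) and
  Ī₄(αα) the squared isochoric fiber stretch. The sclera uses a Yeoh
  reduced-polynomial energy. Three corneal parameter presets `"A"`,
  `"B"`, `"C"` (low / intermediate / large stiffness, k1 = 25, 60,
  130.9 MPa at C10 = 0.05 MPa, k2 = 2490, κ = 0.33329) span the human
  inflation-test range. Analytic stresses and tangents are verified
  against finite differences in the test suite.

* **Synthetic geometry and topography.** A conic-of-revolution bi-surface
  cornea (anterior R = 8.08 mm, Q = −0.22; posterior R = 6.64 mm,
  Q = −0.12; CCT 585 µm; 12 mm aperture), a limbus ring and a 25 mm
  scleral cap; a topographer-export emulator (elevation + pachymetry CSV
  grids with optional noise) and least-squares recovery of (R, Q, CCT).

* **FE engine.** Geometrically nonlinear, total-Lagrangian axisymmetric
  solver: 9-node quadrilaterals, selective reduced integration for
  near-incompressibility, follower IOP pressure, collimated air-jet
  traction, Newton iteration with load stepping, compiled element kernels
  (RcppArmadillo).

* **Zero-pressure algorithm.** The imaged cornea is already loaded by the
  IOP; the iterative stress-free-configuration recovery
  (X_init ← X_init − (x_def − X_ref)) makes every simulation start from a
  mechanically consistent state.

* **Tonometry pipeline and studies.** `simulate_tonometry()` chains
  prestress → IOP pressurization → rising air pulse (25 kPa peak, 30 ms,
  3 mm footprint), and returns the apical displacement time course,
  first-applanation time, apex stress–stretch paths and field snapshots.
  `run_grid()`, `fit_linear()`, `fit_cubic()` and `overlap_analysis()`
  reproduce the IOP / CCT / stiffness parametric studies.

## Worked example

```r
library(tonosim)

res <- simulate_tonometry(material = "C", iop_mmhg = 19)
res
#> Non-contact tonometry simulation
#>   material C, IOP 19 mmHg, CCT 585 um
#>   max apical displacement: 1.1320 mm
#>   first applanation at 5.96 ms

paths <- extract_apex_paths(res)
paths[c(1, nrow(paths)), c("anterior_sigma_MPa", "anterior_lambda",
                           "posterior_sigma_MPa", "posterior_lambda")]
```

The run recovers the stress-free configuration, pressurizes it to
19 mmHg and traverses the rising half of the pulse. The apex moves
1.13 mm posteriorly; the central cornea flattens (first applanation) at
5.96 ms. The apex paths show the key mechanical distinction of the test:
before the puff both corneal surfaces are in membrane tension (anterior
+0.010 MPa at stretch 1.010, posterior +0.020 MPa at 1.015), while at
the pulse peak the cornea bends — the anterior surface goes into
compression (−0.699 MPa, stretch 0.951) and the posterior surface into
increased tension (+0.507 MPa, stretch 1.050). Tension-only collagen
fibers therefore stop contributing on the anterior side, which is why
the deformation amplitude confounds fiber stiffness with IOP and CCT.

A command-line interface wraps the same pipeline:

```sh
exec/tonosim simulate --material C --iop 19
exec/tonosim study --grid iop_study --outdir out/
exec/tonosim fit --results out/study_results.csv
```

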