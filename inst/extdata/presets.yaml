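# Declarative presets: material parameter sets and the baseline geometry.
# Units: moduli MPa, compressibility 1/MPa, lengths mm, thickness microns.
#
# Corneal materials A/B/C: low / intermediate / large stiffness sets whose
# inflation responses span the human experimental range; they differ only
# in the fiber stiffness k1. The scleral Yeoh coefficients are
# representative literature-range values (synthetic defaults, not
# patient-matched) and are configurable.
materials:
  A:
    type: gho
    C10: 0.05
    D: 0.0
    k1: 25.0
    k2: 2490
    kappa: 0.33329
  B:
    type: gho
    C10: 0.05
    D: 0.0
    k1: 60.0
    k2: 2490
    kappa: 0.33329
  C:
    type: gho
    C10: 0.05
    D: 0.0
    k1: 130.9
    k2: 2490
    kappa: 0.33329
  sclera:
    type: yeoh
    C10: 0.81
    C20: 56.05
    C30: 2332.26
    D1: 0.0
    D2: 0.0
    D3: 0.0

geometry:
  baseline:
    anterior_radius: 8.08
    anterior_asphericity: -0.22
    posterior_radius: 6.64
    posterior_asphericity: -0.12
    cct: 585
    diameter: 12
    limbus_width: 1.0
    sclera_diameter: 25

air_puff:
  default:
    peak_pressure: 25000   # Pa
    duration: 30           # ms
    footprint_diameter: 3  # mm
    temporal_shape: sin2
    spatial_shape: supergaussian
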