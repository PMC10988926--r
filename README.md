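# ectfield

Adaptive-conductivity volume-conductor modeling of electroconvulsive
therapy (ECT) impedance at a representative frequency of 1 kHz.

ECT devices report a **static impedance** (a low-intensity test signal,
~2 µA at ~800 Hz; typically 1–2 kΩ) and a **dynamic impedance** (from the
peak voltage driving the ~900 mA stimulus; typically 200–400 Ω). The gap
between the two is an intensity effect — skin under a strong local
electric field becomes far more conductive — and `ectfield` reproduces
both numbers with a single mechanism, for researchers modeling
transcranial current flow and clinicians' engineers reasoning about
device readouts.

The package covers the full pipeline:

* **Waveforms** — alternating-polarity rectangular pulse trains
  `x_T(t) = +A` on `[0, Δ)`, `−A` on `[T/2, T/2+Δ)`, with the analytic
  amplitude spectrum `|C_n| = (A/πn)·|sin(πnΔ/T)|·(1−(−1)^n)` and its FFT
  counterpart (`pulse_train_spec()`, `analytic_harmonics()`,
  `numeric_spectrum()`, `first_envelope_null()`).
* **Lumped circuit** — the electrode–body equivalent circuit
  `Z(f) = Rs + Rp/(1 + j·2πf·Rp·Cp)`, fitted to measured impedance
  spectra (>100 Hz) by Levenberg–Marquardt and summarized by `|Z(1 kHz)|`
  (`rrc_circuit()`, `fit_rrc()`, `magnitude_at_1khz()`).
* **Adaptive scalp conductivity** — the piecewise-linear transfer
  function `σ_SS(E)`: floor `A = 5e-3` S/m below `B = 85` V/m, then
  `C·E − D` (`C = 4.49e-4`, `D = 0.032`), saturating at a
  subject-specific maximum `σ̄_SS` at `Ē_SS = (σ̄_SS + D)/C`
  (`sigma_ss()`, `saturation_field()`).
* **FEM on synthetic head phantoms** — multilayer slab or concentric-shell
  phantoms with bifrontal gel pad electrodes, a trilinear-hexahedron
  Laplace solver (`∇·(σ∇V) = 0`, conjugate gradients), and an
  under-relaxed Picard loop coupling scalp conductivity to the local
  field (`phantom_spec()`, `build_phantom()`, `solve_linear()`,
  `solve_adaptive()`).
* **Calibration** — monotone bisection recovering `(σ_DS, σ̄_SS)` from a
  subject's clinical (static, dynamic) impedance pair (`calibrate()`,
  `subject_report()`).

Results are tibbles or small S3 records with `tidy()` / `glance()` /
`autoplot()` methods; see the vignette
(`vignettes/adaptive-impedance-modeling.Rmd`) for the model's
assumptions, parameter meanings and numerical choices.

## Worked example

```r
library(ectfield)

# a measured subject's fitted circuit, evaluated at the modeling frequency
circ <- rrc_circuit(rs_ohm = 522, rp_ohm = 9890, cp_f = 175e-9)
circ
#> <rrc_circuit> Rs = 522 ohm, Rp = 9890 ohm, Cp = 175 nF  (|Z| at 1 kHz: 1086 ohm)

# the default bifrontal slab phantom and one subject's scalp parameters
mesh <- build_phantom(phantom_spec())
mesh
#> <labeled_mesh> layered_slab: 5768 nodes, 4788 hexahedral elements
#>   elements per tissue: csf=462, deep_scalp=693, gel=168, gray_matter=693, skull=1155, superficial_scalp=693, white_matter=924
#>   terminal faces: 42 driven, 42 ground

subject <- scalp_params(0.002, 0.16)   # sigma_DS, sigma_SS_max (S/m)
static  <- solve_adaptive(mesh, scalp = subject, bc = boundary_condition(2e-6))
dynamic <- solve_adaptive(mesh, scalp = subject, bc = boundary_condition(0.9))
static
#> <adaptive_solution> impedance 2162.86 ohm at 2e-06 A; 2 iterations (converged)
dynamic
#> <adaptive_solution> impedance 653.174 ohm at 0.9 A; 12 iterations (converged)
```

At the 2 µA test current, scalp fields stay below the 85 V/m threshold,
the scalp keeps its floor conductivity, and the model reports a kiloohm
static impedance. At 0.9 A the scalp under the electrodes saturates and
the terminal impedance drops to a third — the static/dynamic gap emerges
from the field-dependent conductivity alone.

The inverse direction recovers subject parameters from a clinical
impedance pair:

```r
cal <- calibrate(mesh, target = clinical_impedance_pair(2200, 400))
cal
#> <ect_calibration> converged after 11 model evaluations
#>   deep scalp 0.002 S/m, superficial max 0.425 S/m (saturation 1018 V/m)
#>   static: 2163 ohm (target 2200, 1.69%); dynamic: 395 ohm (target 400, 1.22%)
```

A command-line front-end over the same functions lives at
`inst/cli/ectfield.R` (subcommands `spectrum`, `fit-circuit`, `phantom`,
`solve`, `calibrate`).

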