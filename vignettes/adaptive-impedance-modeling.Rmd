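---
title: "Adaptive-conductivity modeling of ECT static and dynamic impedance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-conductivity modeling of ECT static and dynamic impedance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectfield)
```

## The modeling problem

Electroconvulsive therapy (ECT) devices report two impedances per subject:
a *static* impedance, probed before treatment with a low-intensity,
high-frequency test signal (on the order of 2 µA at ~800 Hz), and a
*dynamic* impedance, computed from the peak voltage required to drive the
~900 mA current-controlled stimulus train. Static impedance is typically
1–2 kΩ; dynamic impedance 200–400 Ω. The gap is not a waveform effect —
applying the stimulus waveform at test-signal intensity still yields
kiloohm impedances — it is an *intensity* effect: skin under a strong
local electric field becomes much more conductive.

`ectfield` packages a representative-frequency (1 kHz) quasi-static
pipeline that reproduces both impedances with a single mechanism. All
tissues receive real-valued conductivities taken at 1 kHz (1 kHz sits
inside the main spectral lobe of clinical pulse trains and tracks
device-reported impedance), current flow obeys the Laplace equation
$\nabla\!\cdot(\sigma\nabla V) = 0$, and the *superficial scalp* layer
adapts: its conductivity is a piecewise-linear function of the local
electric-field magnitude. Two subject-specific parameters — the fixed
deep-scalp conductivity $\sigma_{DS}$ and the superficial-scalp maximum
$\bar\sigma_{SS}$ — are calibrated so that the model reproduces a
subject's clinical (static, dynamic) impedance pair.

## Stimulus waveforms and their spectra

The idealized stimulus is an alternating-polarity rectangular pulse
train: amplitude $A$, pulse width $\Delta$, period $T$ (one `+` pulse and
one `-` pulse per period). Its two-sided Fourier-coefficient magnitudes
are

$$|C_n| \;=\; \frac{A}{\pi n}\,
  \left|\sin\!\frac{\pi n \Delta}{T}\right|\,\bigl(1-(-1)^n\bigr),$$

so even harmonics vanish and the $\sin$ envelope has its first null at
$1/\Delta$ (2 kHz for a 0.5 ms pulse, 4 kHz for 0.25 ms). Conventions the
package fixes, since devices and textbooks differ:

* **Cycle rate.** A clinical "0.5 ms at 20 Hz" dose is interpreted as 20
  full alternating cycles per second ($T = 50$ ms containing both
  polarities), matching the single-period definition above. Devices
  sometimes quote pulses per second (twice this rate); `pulse_train_spec()`
  documents the convention prominently.
* **Single- vs two-sided.** $|C_n|$ is the two-sided coefficient
  magnitude; a measured single-sided FFT spectrum carries $2|C_n|$ at each
  harmonic. The square-wave limit $\Delta = T/2$ then reproduces the
  standard $4A/\pi n$ single-sided amplitude, which is the check that
  fixed the convention.
* **Edges and leakage.** Sampling uses half-open pulse intervals
  $[t_0, t_0+\Delta)$; records are half-open in time ($t \in [0, D)$) so an
  integer number of periods contains no duplicated endpoint; no window is
  applied. With these choices the FFT amplitudes of a 1 s record agree
  with $2|C_n|$ to better than $10^{-4}$ relative, and even-harmonic
  leakage is at numerical zero.

The static test signal is modeled as an 800 Hz, ±2 µA biphasic square
wave (`square_wave_spec()`); no device-internal shaping is attempted.

## The lumped R-RC circuit

At low current, electrode–body impedance over ~100 Hz–1 kHz is well
described by a series resistance with a parallel RC pair:

$$Z(f) = R_s + \frac{R_p}{1 + j\,2\pi f R_p C_p}.$$

Its real/imaginary locus is a semicircular arc of radius $R_p/2$; the DC
limit is $R_s + R_p$ and the high-frequency limit $R_s$. Measured spectra
deviate from this arc *below* ~100 Hz (both components rise in a way a
single dispersion cannot capture), so `fit_rrc()` retains only points
strictly above a 100 Hz floor. Fitting choices:

* Levenberg–Marquardt (`minpack.lm`) on the stacked real and imaginary
  residuals, unweighted, in absolute ohms.
* Parameters are log-transformed, keeping them positive without
  constrained optimization.
* Initialization is deterministic — $R_s$ from the highest-frequency real
  part, $R_p$ from the low-frequency real part minus $R_s$, $C_p$ from the
  frequency of the most negative imaginary part via
  $2\pi f R_p C_p = 1$ — so identical inputs give identical fits; there
  are no random restarts.

The 1 kHz magnitude of the fitted circuit (`magnitude_at_1khz()`,
rounded half-away-from-zero to the ohm) is the representative-frequency
summary. The bundled reference table `eis_subject_fits()` carries ten
measured subjects' fitted circuits; for nine of them direct evaluation
reproduces the recorded 1 kHz value within ±1%, while subject 207's
recorded value is inconsistent with its own circuit (704 Ω computed vs
810 Ω recorded, almost certainly a transcription slip) and is flagged
rather than used as a check.

## The field–conductivity transfer function

Superficial-scalp conductivity follows the local electric-field
magnitude $E$:

$$\sigma_{SS}(E) = \begin{cases}
  A & 0 \le E < B\\
  C\,E - D & B \le E < \bar E_{SS}\\
  \bar\sigma_{SS} & E \ge \bar E_{SS}
\end{cases}$$

with population constants $A = 5\times10^{-3}$ S/m (floor), $B = 85$ V/m
(threshold), $C = 4.49\times10^{-4}$ S/m per V/m (slope) and $D = 0.032$
S/m (offset). The subject's saturation field follows from continuity of
the middle branch: $\bar E_{SS} = (\bar\sigma_{SS} + D)/C$, e.g. ~428 V/m
for $\bar\sigma_{SS} = 0.16$ S/m and ~1185 V/m for 0.5 S/m.

Three points are worth making explicit:

* **The threshold step.** The printed constants leave a small upward jump
  at $B$ (floor 0.005 vs branch value $CB - D = 0.0061650$ S/m). The
  function is implemented exactly as printed — no smoothing rule is part
  of the model — but `sigma_ss()` accepts an optional `blend_width`
  (default 0, i.e. off) that linearly bridges the step, provided purely as
  a solver-robustness aid. With the default under-relaxed iteration the
  blend has never been needed.
* **"Local field"** means the Euclidean magnitude of the element-averaged
  field vector in each superficial-scalp element; the model source does
  not specify the averaging and element-constant fields are the natural
  choice for first-order elements.
* **Deep-scalp bounds.** Calibrated subjects fall between
  $4.5\times10^{-4}$ and $0.008$ S/m; `scalp_params()` enforces this as a
  configurable soft range, not a physical limit. (The degenerate case
  $\bar\sigma_{SS}$ at or below the branch value at threshold is allowed
  and yields an effectively flat transfer function saturating at $B$ —
  useful as a no-adaptivity control.)

## Synthetic head phantoms

The reference models this pipeline was developed for are MRI-derived
subject head meshes; those are not reproducible from tabulated data, so
the package generates *synthetic phantoms* that isolate the parameterized
physics:

* **Layered slab (default).** Six flat layers, outside-in: superficial
  scalp 3.5 mm, deep scalp 3.5 mm (the scalp is bisected into its two
  compartments), skull 7 mm, CSF/meninges 3 mm, gray matter 4 mm, white
  matter 6 mm, over a 14 × 7.5 cm footprint; two 4.2 × 4.9 cm gel pads
  (1.7 mm thick, 0.018 S/m) on the top face, 2 cm apart. The slab
  reproduces the series current path — gel, adaptive scalp, deep scalp,
  skull — that dominates terminal impedance, and admits the analytic
  series-resistance oracle $\sum_i L_i/(\sigma_i A)$ via the companion
  `column_phantom()` geometry (full-face terminals).
* **Concentric shells.** The same stack wrapped onto spheres (nodes on a
  radially projected cube lattice, so the ball is meshed without polar
  degeneracies) around an unmeshed interior cavity, for curvature
  effects. Electrode patches are placed by angular extent on the outer
  surface.

Layer thicknesses are declared defaults, not subject-derived: per-subject
anatomy is out of reach of a phantom, and none of the package's
quantitative claims depend on them. Tissue conductivities (skull 0.01,
gray matter 0.276, white matter 0.126, CSF 0.85, air $10^{-15}$, gel
0.018 S/m) live in `tissue_table()`.

Meshing uses structured hexahedra with two resolutions: `element_size_m`
(default 1.5 mm) resolves the layer stack — every layer gets at least two
elements through its thickness, and a size coarser than half the thinnest
layer is rejected — while `inplane_size_m` (default 7 mm) sets the
lateral/surface resolution. The two are decoupled because terminal
impedance converges much faster laterally than through the thin-layer
stack; at the defaults, halving both sizes changes the uniform-phantom
impedance by ~1.4% (the suite asserts < 2%).

What the phantom does *not* emulate: real scalp curvature and thickness
variation, skull inhomogeneity, anatomical electrode placement, and the
shunting geometry of a full head. Passing tests therefore demonstrate
that the *mechanism* (adaptive scalp conductivity reproducing the
static/dynamic gap) and the *machinery* (solver, calibration) are
correct and self-consistent — not that the phantom predicts any
particular subject's absolute impedance or brain field. Orderings
(static ≥ dynamic, impedance non-increasing in current) are asserted;
anatomy-dependent magnitudes are not.

## FEM solver

First-order trilinear hexahedra with element-constant conductivity and
field; 2×2×2 Gauss integration of general (not only axis-aligned)
elements, so slab and shell share one assembly path. The drive is a
uniform current density over the driven gel outer faces (consistent
nodal loads by quarter-face areas) with homogeneous Dirichlet conditions
on the ground faces; terminal impedance is the area-weighted mean
driven-face potential divided by the applied current. A
contact-impedance (complete electrode) model is deliberately absent: the
electrode interface behavior this pipeline cares about is carried by the
superficial-scalp layer itself.

The linear solver is Jacobi-preconditioned conjugate gradients (relative
residual tolerance, default $10^{-3}$; a sparse-Cholesky `"direct"`
option exists). The adaptive problem is solved by under-relaxed Picard
iteration: solve, evaluate `sigma_ss()` on the superficial-scalp element
fields, update $\sigma \leftarrow (1-\omega)\sigma + \omega\,\sigma_{new}$
with $\omega = 0.5$, repeat until both the relative impedance change and
the largest relative conductivity change drop below $10^{-3}$ (cap 1000
iterations, warm-starting each solve from the previous potentials).
Picard was chosen over Newton–Raphson because the transfer function's
derivative is undefined at its threshold jump and zero on two of three
branches; with $\omega = 0.5$ the loop converges in ~2 iterations at
2 µA (fields never reach threshold) and ~10–15 at 900 mA on the default
phantom. Hitting the cap flags `converged = FALSE` on the result rather
than raising, so long-running sweeps can triage afterwards. The solver
contains no randomness: identical inputs give identical traces.

Verification is layered: exact agreement (to solver tolerance) with the
series-resistance oracle on layered columns, where uniform vertical flow
lies in the trilinear space; agreement of the sparse CG path with a dense
base-R solve to $10^{-10}$ on small meshes; discrete current conservation
across cut planes via nodal balances of $Kv$; mirror symmetry under
terminal swap; and fixed-point self-consistency (re-evaluating the
transfer function on converged fields reproduces the converged
conductivities).

## Subject calibration

`calibrate()` inverts the forward model for a subject's
(static, dynamic) impedance pair. The search exploits two monotonicities
that the suite verifies by sweep: static impedance (2 µA) is strictly
decreasing in $\sigma_{DS}$, and dynamic impedance (900 mA) strictly
decreasing in $\bar\sigma_{SS}$. Each parameter is bisected on a log
scale against its own residual — $\sigma_{DS}$ against the static target,
then $\bar\sigma_{SS}$ against the dynamic target — and the pair of
searches is repeated until both impedances match within tolerance
(default 2% relative). Because scalp fields at 2 µA sit far below the
transfer-function threshold, static impedance is essentially independent
of $\bar\sigma_{SS}$ and the alternation converges in one or two outer
passes; a nested search (a full inner $\bar\sigma_{SS}$ solve per outer
$\sigma_{DS}$ step) would multiply cost for no accuracy gain. Targets
outside what the bounds can reach fail fast with the limiting bound
named; bisection needs no derivatives and is immune to the transfer
function's kinks.

On the default phantom, round-trip recovery of known
$(\sigma_{DS}, \bar\sigma_{SS})$ pairs over a 3×3 grid spanning the
clinical ranges ($4.5\times10^{-4}$–$0.008$ and 0.16–0.5 S/m) comes back
within 5% on both parameters at a 0.5% impedance-match tolerance,
typically in 11–17 model evaluations.

## Problem sizes and determinism

The suite and examples run on the default slab (≈4.8k elements, ≈5.8k
nodes) and refinement checks up to ≈36k elements — sizes chosen so the
full verification ladder (including the 3×3 calibration grid) completes
in a few minutes on one core while keeping discretization effects ≲2%.
Production reference models of this kind use millions of tetrahedra; the
package's claims are about mechanism and machinery, which are
resolution-stable, not about converged anatomical field values. The only
stochastic ingredient anywhere is the noise injected in fitting tests
(fixed seeds); solver and calibration are deterministic.

## Known limitations

* Quasi-static, purely resistive: no permittivity, no induction, no
  explicit time dependence (adaptive conductivity is instantaneous).
* Single-dispersion R-RC only; constant-phase and diffusion (Warburg)
  elements, and the sub-100 Hz rise they model, are out of scope.
* Phantoms are geometric idealizations (see above); absolute impedances
  and brain fields are anatomy-dependent and not asserted.
* The transfer function is implemented with its printed threshold step;
  whether that step is physical or a rounding artifact of the printed
  floor is undecidable from the available constants.
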