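---
title: "Models, numerics and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendspike)
```

This vignette is the package's own account of what it simulates, how the
numerics work, and where design choices had to be made that the model
definitions leave open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The two models

The **single-compartment model** is the classical Hodgkin–Huxley soma: leak,
delayed-rectifier K⁺ (gate n) and transient Na⁺ (gates m, h) conductances,
with the textbook rate functions and the parameter set gNa = 0.12,
gK = 0.036, gL = 0.0003 S/cm², ENa = +50, EK = −77, EL = −54.3 mV,
Cm = 1 µF/cm². The neuron is treated as an equipotential sphere, so injected
current Ie (nA) enters as a density Ie/A.

The **two-compartment model** adds a dendrite carrying only leak plus a
dendritic calcium action potential (dCaAP) current. The dCaAP is
threshold-triggered (V_thresh = −36 mV), refractory (200 ms), and its
amplitude factor K = exp(−F·(V − V_thresh)/τ_K) is evaluated **once**, at
the first sample at or above threshold, then frozen for the waveform. The
waveform itself is the difference of two sigmoids, A rising with τ_A = 3 ms
and B cutting off Δt′ = 21 ms later with τ_B = 0.4 ms. Two decisions the
definitions leave open:

* **τ_B in the cutoff.** The decay sigmoid is printed elsewhere with τ_A in
  its denominator, but τ_B = 0.4 ms is introduced as a parameter and is
  otherwise unused; we use τ_B. With τ_A in both sigmoids the waveform would
  have a symmetric, slow cutoff and the characteristic sharp termination of
  the dendritic spike would be lost.
* **V_rest in F = 1/(V_thresh − V_rest).** The dendrite at rest carries only
  leak, so its resting potential is the leak reversal, EL = −54.3 mV, giving
  F = 1/18.3 per mV.
* **Threshold tie-break.** "Crosses the threshold" is implemented as
  at-or-above at the sample; at 0.1 ms resolution the distinction from
  strictly-above is not observable.

A − B is clamped at zero: in exact arithmetic the difference becomes
negligibly negative (≈ −10⁻⁴ at most) once the cutoff sigmoid overtakes the
rise, near t − t′ ≈ 24 ms; the waveform is considered finished when its raw
value drops below 10⁻⁹ (direct evaluation) or past the table end (LUT path,
truncated at 10⁻⁶). Both cutoffs end the waveform at ≈ 24 ms, far inside
the 200 ms refractory period.

Compartments are coupled resistively. The coupling current is implemented in
its physical (diffusive) form g·(V_other − V_self) added to each side's
right-hand side; the anti-diffusive sign that a literal reading of the
coupled equations would give diverges and is treated as a sign typo.

**Synapses** are conductance-based and excitatory (Esyn = 0 mV):
gsyn = gmax·Ps with Ps reset to Pmax = 1 on a presynaptic event and decaying
with τ_s = 10 ms. Inside the stepper the decay is the exact per-step
recursion Ps ← Ps·e^(−Δt/τs) (one multiply, the hardware formulation), with
the reset applied at the end of the step containing the event.

## Units

Channel conductances are stored in the classical S/cm² convention and
converted to mS/cm² internally so that mS/cm² × mV = µA/cm² matches
µF/cm² × mV/ms. Injected currents convert as
Ie[nA] / A[mm²] × 0.1 = µA/cm². Two quantities need a unit decision of
their own:

* **Synaptic gmax = 0.05** is interpreted directly as mS/cm². Read as
  S/cm² it would exceed the sodium conductance and clamp the dendrite to
  Esyn within one timestep; as mS/cm² a synapse at rest delivers ≈ 3 µA/cm²,
  the same scale as the nA-range current injections.
* **The dCaAP weight ω = 3 is dimensionless**, so the product ω·K·(A−B)
  needs a current-density scale. `dcaap_current()` returns the dimensionless
  form; the solver multiplies by `dcaap_scale` (µA/cm² per unit, default 80,
  calibrated below).

## Numerical scheme

Per step, in order: (1) synaptic events are applied and release decays;
(2) somatic gates advance by their exact exponential update using the
pre-step somatic voltage; (3) the dCaAP trigger is evaluated on the pre-step
dendritic voltage (K frozen there if it fires); (4) membrane voltages
advance by one backward-Euler step, which is linear in voltage given the
updated states — a scalar closed form for one compartment, a 2×2 Gaussian
elimination for two; (5) spikes are detected as upward crossings of −20 mV
with hysteresis (no re-detection until the voltage falls back below
threshold). The joint implicit 2×2 solve was chosen over a staggered update
for stability; at Δt = 0.1 ms the two agree to plotting accuracy.

Backward Euler is unconditionally stable here (all conductances and the
capacitance are positive, so the linear systems are diagonally dominant);
the suite checks boundedness up to Δt = 1 ms at 10 nA. It is first-order:
halving Δt leaves onset timing (first spike within 0.2 ms) and firing rates
(within ~1.5%) intact but shifts the phase of late spikes in long tonic
trains, which is why cross-arithmetic comparisons are always run at the
same Δt.

All runs begin at V = −65 mV with gates at their −65 mV equilibrium, dCaAP
inactive and eligible, followed by a 100 ms unrecorded settling period
before stimulus onset (time 0). The removable singularities of the rate
functions (αn at −55 mV, αm at −40 mV) take their analytic limits whenever
the denominator argument is within 10⁻⁷.

## Lookup tables

The gating table spans −100…+100 mV (201 nodes at the default 1 mV) and
stores x∞ and the per-step factor e^(−Δt/τx) for each gate — the stable
negative exponent; the positive sign sometimes quoted for this factor would
grow without bound. Queries interpolate linearly and clamp outside the
domain. The A − B table is indexed by t − t′, which is always an exact
multiple of Δt, so it is queried by nearest node — a single lookup; at
0.1 ms resolution and 4-byte entries it occupies ≈ 0.97 kB. A gating update
through the tables is three lookups plus one multiply and one add per gate.

## Fixed-point emulation

Two 32-bit formats: signed s16.15 *accum* (step 2⁻¹⁵ ≈ 3.05×10⁻⁵, limits
±65536) for voltages, currents and conductances; unsigned u0.32 *fract* for
everything confined to [0,1) — gates, release probabilities, K, A − B and
the gating decay factors. Every operation computes an exact wide
intermediate (64/128-bit integer), rounds to nearest with ties away from
zero, and **saturates** on overflow rather than wrapping; saturation events
are counted and reported (`$sat_count`), and all shipped protocols run with
a count of zero. The gate update is rearranged as
x′ = x∞ − x∞·e + x·e so that every intermediate stays non-negative for the
unsigned format. Exponentials (needed only for K at trigger time and in the
no-LUT path) follow the software-exponential contract: a double-precision
core whose result is quantized into the target format. The double and fixed
steppers are instantiations of the same templated C++ code, so they execute
the identical operation sequence and differ only in rounding.

The validation harness's default reference is double precision **with the
same gating path** as the implementation under test. This mirrors how such
implementations are benchmarked in practice — the standard reference
simulator for HH models itself tabulates the gating functions at 1 mV — and
isolates the arithmetic error. Measured that way the fixed-point
implementation tracks the reference to exactly one timestep (0.1 ms) across
the whole 0–10 nA sweep. Crossing the gating-path boundary instead
(LUT versus direct evaluation, either arithmetic) introduces a small
systematic shift of the oscillation period that accumulates over seconds of
tonic firing; `lut_resolution_study()` quantifies it, and the suite asserts
its ordering (1 mV tables strictly more accurate than 2 mV).

## Calibrated defaults

Four constants are not fixed by the model definitions and were calibrated
once against the qualitative two-compartment behaviors, then frozen:

* **A_soma = 0.01 mm²** (sphere of radius ≈ 28 µm): maps 0.3 nA to
  ≈ 3 µA/cm² (single spike then accommodation) and 3 nA to ≈ 30 µA/cm²
  (repetitive firing) — the classical HH regimes.
* **A_dend = 0.002 mm²**: the dendritic area sets the current-density scale
  of the amplitude decay. With this value, nA-scale dendritic injections
  cross the dCaAP threshold within about one timestep, so the activation
  overshoot — and hence K — varies smoothly and monotonically with drive.
  With a larger dendrite the crossing takes many steps and the overshoot at
  the crossing *sample* jitters with the sub-step crossing phase, making
  the amplitude-versus-drive curve non-monotonic at the sampled points.
* **g_ds = g_sd = 0.03 mS/cm²**: large enough that a dendritic dCaAP drives
  somatic firing, small enough that 10 nA of somatic drive (spiking at full
  amplitude) never pulls the resting dendrite across −36 mV, and small
  enough that the direct synaptic depolarization of the dendrite (bounded
  by Esyn = 0) stays subthreshold at the soma — the XOR experiment's "both
  inputs" case must stay silent.
* **dcaap_scale = 80 µA/cm²** per unit of ω·K·(A−B): sets the dCaAP strong
  enough that a K ≈ 0.6 waveform fires the soma through the weak coupling.
  A consequence worth knowing: during a strong dCaAP the passive linear
  dendrite reaches large nominal voltages (hundreds of mV); the dendrite
  has no active repolarizing conductances, so these excursions are nominal
  model quantities, not biophysical predictions — what matters downstream
  is the current delivered to the soma.

The XOR encoding (25 synapses per input, synchronous at 20 Hz, 500 ms
window) was calibrated the same way: one group crosses threshold with
K ≈ 0.57 and fires the soma; two groups overshoot to K ≈ 0.32 and the soma
stays silent. The margin holds identically in double and fixed arithmetic.

## The feature battery

The ten firing features are demonstrated with the single default parameter
set; only the stimulus differs per feature, and each predicate is
machine-checkable: tonic (≥5 spikes, ISI CV < 0.1 at 3 nA), phasic (exactly
one spike at 0.3 nA), subthreshold oscillations (≥2 damped post-spike maxima
below −40 mV with ≥0.1 mV prominence), accommodation (ramp to 0.5 nA silent,
step to 0.5 nA spikes), Class II (onset frequency of the first firing
current in a 0.05 nA scan exceeds 40 Hz), rebound (spike within 100 ms of
releasing a −2 nA pulse), integrator (paired 0.36 nA/2 ms pulses spike at a
1 ms gap, not at 20 ms), variable threshold (a 0.3 nA probe spikes only
after a −0.2 nA pre-pulse), dendrite-mediated adaptation (0.17 nA dendritic
drive yields ≥4 spikes containing three successively longer ISIs, as the
first strong dCaAP gives way to weaker refractory-spaced ones), and the XOR
truth table. The battery's stimuli are part of the package's shipped
configuration; the acceptance surface is the predicate outcome.

One qualitative behavior is reproduced on a different axis than one might
first expect: with *current* injection into the dendrite, somatic firing
does not cease at the top of the 0–10 nA range, because the passive
coupling baseline g·(V_dend − V_soma) grows linearly with drive and
eventually dominates the bounded, K-damped dCaAP. The fire-then-cease
behavior appears cleanly on the *synaptic* axis, where Esyn = 0 caps the
baseline: 25 active synapses recruit the soma, 50 silence it. The
amplitude-versus-current decay itself (the dCaAP current, not the somatic
response) is monotone and is asserted in the suite.

## Problem sizes and determinism

The shipped experiments use 2 s simulations at Δt = 0.1 ms (20 000 steps)
for the regularity, regime and sweep checks; 0.5–1.5 s for the battery's
per-feature runs; and the full 21-current sweep for the cross-arithmetic
comparison — all desk-scale (the whole suite runs in about a minute).
Nothing in the package consumes a random number source: identical
configurations produce byte-identical traces, spike lists and reports, in
both arithmetic modes.

## Known limitations

* The dendrite is passive apart from the stereotyped dCaAP; its large
  nominal voltage excursions under strong drive are discussed above.
* Backward Euler's first-order phase drift means spike *times* in long
  tonic trains are only comparable between runs at equal Δt.
* The between-window dendritic error floor in cross-arithmetic comparisons
  is set by somatic spike-edge differences coupling through g, roughly
  10⁻² mV — far above the raw s16.15 quantization step, though still an
  order of magnitude below the in-window error.
* Networks, plasticity, hardware code generation and energy/time profiling
  are out of scope.
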