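---
title: "Digital spiking models of tactile afferents: models, fixed point, and decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital spiking models of tactile afferents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactspike)
```

## The system being modelled

Human glabrous skin conveys touch through populations of primary afferents.
Two types dominate object manipulation: slowly adapting type 1 (SA-I)
afferents, innervating Merkel cells, fire tonically throughout a sustained
indentation with a rate that grows with force; fast adapting type 1 (FA-I)
afferents, innervating Meissner corpuscles, fire only while the stimulus
*changes*, at onset and offset. Neuromorphic tactile front-ends reproduce
this division of labour in digital hardware: a force sensor feeds a spiking
neuron circuit, and the spike train — not the raw analogue value — is what
downstream processing consumes.

`tactspike` is a software twin of such a system: four spiking neuron models
of both afferent types, their bit-accurate fixed-point digital realizations,
population simulation over multi-sensor stimuli, and a rate-coding
machine-learning readout.

## The four spiking models

All four models are explicit Euler discretizations with step
`h = 0.0078125` ms (`2^-7`, exactly representable in the fixed-point format
below). Voltages are in mV; the input `I` is the digitized force signal,
weighted by a per-model input coefficient.

For the SA-I afferent the input enters *inside* the `h`-multiplied bracket;
for the FA-I afferent the bracket carries no input and the term
`C_fa (I[n+1] - I[n])` is added *outside* it, so a constant input
contributes nothing — this single wiring difference produces the
sustained-vs-transient dichotomy.

* **Izhikevich (izh)** — two state variables:
  `v' = v + h(0.04 v² + 5v + 140 − u + C·I)`, `u' = u + h·a(bv − u)`;
  when `v' ≥ 30` mV: `v ← c`, `u ← u + d` (note the reset adds `d` to the
  *pre-step* `u`).
* **Linearized Izhikevich (lizh)** — the quadratic is replaced by
  `k1·|v + 62.5| − k2`, trading a multiplier for an absolute value; same
  reset. (The 62.5 constant is used verbatim as the linearization point of
  the quadratic nullcline; no derivation is given for it, so it is treated
  as part of the model definition.)
* **QIF (qif)** — one variable: `v' = v + h(M1 v² + C·I)`, reset
  `v ← v_reset = 0` at `v_peak = 30` mV.
* **Linearized QIF (lqif)** — `v' = v + h(M2 |v| + C·I)`, same reset.

Default constants are the simulation values (`a = 0.02`, `b = 0.2`,
`c = −65`, `d = 8`, `k1 = 0.75`, `k2 = 20`, `M1 = 1`, `M2 = 0.0625`, input
weights `C11..C42` = 20/960, 24/960, 0.015625/0.5, 1/40 for SA/FA per
model). The *improved* L-QIF circuit uses the separately tuned values
`M2 = 0.25`, `C41 = 0.5`, `C42 = 16` — every coefficient a power of two, so
each multiplication reduces to a bit shift (`improved_lqif_params()`).

```{r}
p <- neuron_params("izh")
step_izh(list(v = -65, u = -13), I_now = 0, params = p)
```

**Initial conditions.** The sources define no `v(0)`; this package starts
Izhikevich-family neurons at their reset point (`v = c`, `u = b·c`) and
one-variable neurons at `v = v_reset`, the only distinguished points of each
model. **FA lookahead.** The difference term needs `I[n+1]`; the final step
reuses the last sample so the difference is zero and no spurious terminal
spike occurs. **Spike convention.** A "spike" is a reset event; the stored
trace shows `v_peak` at the spike step for plotting fidelity while the
carried state is the post-reset value.

## Fixed-point emulation of the digital circuits

The hardware stores every signal in a signed 32-bit register: 1 sign bit, 13
integer bits, 18 fractional bits (Q13.18, resolution `2^-18 ≈ 3.8 µV`,
range ±8192). The `fixedpoint` layer reproduces this bit-accurately:

* quantization rounds to nearest (ties away from zero) and **saturates** at
  the range bounds — wrap-around would inject spurious spikes, so overflow
  is counted in a diagnostics counter instead of raised;
* every product is computed at double width and truncated **toward −∞**
  back to the shared register width, once per multiply, mirroring the
  one-register-per-signal scheduling of the circuits (whether the FPGA
  rounds or truncates intermediate products is unspecified; truncation is
  the typical DSP behaviour and is documented here so results are
  reproducible);
* in the shift-only improved L-QIF, each coefficient multiply is an
  arithmetic shift. Because a fixed-point product by `2^k` is *exactly* a
  shift (including the floor behaviour of right shifts), the shift and
  multiply realizations are bit-identical — a property the test suite
  checks over 10^5 random steps.

```{r}
fixed_format()
fixed_step("lqif", list(v = 0), I_now = 1, params = improved_lqif_params(),
           use_shift = TRUE)
```

Raising the fractional width to 48 bits shrinks per-step quantization error
below 1e-9, which is how the fixed-point engine is validated against the
floating-point reference; at Q13.18 the spike counts of 100-ms reference
runs match floating point within 5% (in practice, exactly, for all eight
model × afferent combinations).

## Stimuli

Force stimuli are piecewise-linear trapezoids (ramp–plateau–ramp), exact on
grid points. Three generators cover the experimental settings:

* `trapezoid()` — single-channel profiles, e.g. the published touch episode
  rising over 4–6 s, holding to 9.5 s, releasing by 10.5 s;
* `grid_scenario()` — multi-sensor scenarios on the 3×3 grid, with
  per-episode randomization of durations, ramp velocities, and amplitudes;
* `haptic_dataset()` — the glove experiment: 3 objects of increasing weight
  × {3,4,5}-finger grasps × 20 repetitions = 180 trials of 4 s with a fixed
  3-s hold, recorded from 135 afferents (5 finger sensors × (10 SA + 17
  FA)).

**Calibration of the characterization amplitude.** The 100-ms
characterization runs print average frequencies but not the input
amplitude, and its exact trapezoid is shown only graphically. The shape is
frozen once — onset 5 ms, rise 10 ms, hold 70 ms, fall 10 ms — and the
single amplitude is fixed by `calibrate_amplitude()`: bisection until the
SA-I Izhikevich run yields exactly 76 spikes (760 Hz). The calibrated rates
of the other models proved insensitive to the shape choice (six shapes
tried during development all gave identical L-Izh rates), which supports
treating the amplitude as the only free scalar.

**Choices the sources leave open (haptic design).** Object force levels are
free parameters; the defaults 6/12/18 (A < B < C, consistent with
glass < tape dispenser < book) put per-finger amplitudes in a range where
the improved L-QIF SA units fire at 60–200 Hz, a realistic SA-I working
range. Grasp load is divided equally among engaged fingers (the simplest
model consistent with the described grasps), the within-trial ramps are
400 ms on each side of the 3-s hold, and per-trial, per-finger force noise
is multiplicative lognormal with cv 0.1 — a typical human trial-to-trial
grip-force variability, taken as the package's "moderate noise" operating
point. Unit-to-unit transduction variability is a lognormal gain jitter
(sdlog 0.05) drawn once per population from a seeded stream; background
activity is an optional Poisson pulse process, off by default so
quantitative checks are uncontaminated.

## Population runs

`build_population()` instantiates the layout (default 9 sensors × (10 SA +
17 FA) = 243 afferents = 90 SA-I + 153 FA-I, the fingertip SA/FA ratio;
the glove layout is 5 × 27 = 135). Units are listed SA before FA per
sensor, sensors in row-major order. The hardware runs all units in
parallel; the software runs them sequentially but draws each unit's
randomness from counter-based seeds, so results are independent of
scheduling order and reproducible bit-for-bit.

```{r, fig.width = 7, fig.height = 4}
pop <- build_population(population_layout(n_sensors = 3, gain_jitter_sd = 0))
sc <- grid_scenario(list(
  list(sensors = 1, spec = trapezoid_spec(20, 30, 100, 30, 10)),
  list(sensors = 3, spec = trapezoid_spec(60, 20, 80, 40, 5))
), n_sensors = 3, duration = 250)
raster <- run_population(pop, sc)
raster_rates(raster)
```

SA firing rate orders with plateau force across sensors, FA units mark the
ramps, and untouched sensors stay silent (with noise off) — the channel-
isolation, rate-order, and count-conservation properties the test suite
enforces.

## Decoding

The readout follows the rate-coding paradigm: the feature of afferent *j*
in trial *i* is its spike count over the counting window (`FR =
spikes/Δt`; the full 4-s trial by default, since the recorded interval is
what the experiment counts over). Per afferent set (SA, FA, or both) and
finger condition:

1. features are z-scored per column **on the training part only**;
2. projected onto the first 3 principal components, fitted on the training
   part only (leakage hygiene; the sources are silent on this);
3. classified by kNN with `k = 5`, Euclidean metric, majority vote; vote
   ties go to the tied class with the smallest mean distance. The prose
   description of the classifier reads like nearest-class-mean; the named
   classifier (kNN) is the primary implementation and
   `nearest_mean_classify()` preserves the described variant as an option.
4. accuracy is estimated by stratified 5-fold cross-validation — each fold
   trains on 80% and tests on the held-out 20%, which is how the 80/20
   split and the 5-fold protocol are reconciled here (their exact
   interaction is not specified in the sources); a fold assignment that
   would lose a class is redrawn.

PCA component signs follow a largest-loading-positive convention so scores
are deterministic; zero-variance features are dropped with a warning.

```{r}
d <- haptic_design(repetitions = 4, trial_duration = 400, hold_duration = 280,
                   grasp_rise = 50, grasp_fall = 50)
trials <- haptic_dataset(d, seed = 1)
ev <- evaluate_decoding(trials, seed = 1)
format_accuracy_table(ev)
```

## What the synthetic data does and does not show

The generator emulates the *structure* of the experiments — trapezoidal
indentation, per-sensor channel wiring, grasp-force sharing, label balance,
trial-to-trial force variability — but not the physics it abstracts away:
FSR transduction nonlinearity, skin viscoelasticity, sensor crosstalk, or
the human variability of real grasps. Decoding accuracies on the synthetic
set therefore validate the pipeline (features → PCA → kNN → CV) and its
noise response, not the published accuracy values, which derive from real
glove recordings that are not publicly deposited. On the synthetic set,
accuracy is perfect at low force noise, exceeds 80% at the moderate
operating point, degrades monotonically as the force-noise cv grows
through {0, 0.1, 0.3, 0.6}, and collapses to the 1/3 chance level under
label permutation.

## Numerical choices and known limitations

* **Time units** are ms throughout the API (`h = 0.0078125` ms); scenario
  narratives quoted in seconds are entered as ms.
* **Calibration** bisects an integer-valued, non-decreasing spike count;
  the returned amplitude is the midpoint of the bracketing interval, making
  the anchor run exact by construction.
* **Model disagreement under a common amplitude.** With the printed
  coefficients, the four SA-I models cannot produce their four printed
  frequencies at any *single* input amplitude: the Izhikevich-anchored
  calibration reproduces the linearized-Izhikevich frequency exactly
  (840 Hz) but leaves QIF and L-QIF well below their printed values (the
  asymptotic Izh/QIF rate ratio is ≈ 7 at any common drive). The package
  reports what the equations produce; reconciling all four would require
  per-model amplitudes, which would make the characterization circular.
* **Residual plateau spikes.** QIF and L-QIF dynamics are self-excitatory
  above their reset (`v² ` resp. `M2|v|` with `v_reset = 0`), so an FA-I
  unit leaving the onset ramp with any positive residual voltage emits at
  most one delayed "blow-up" spike on the plateau before parking at the
  reset fixed point. Izh/L-Izh FA units relax below threshold and are
  strictly silent there. Q13.18 truncation suppresses the residual only
  when the per-step increment falls below one register tick.
* **Offset responses.** With the printed difference-term equations, a
  falling ramp injects negative current, so FA offset spikes require an
  upstream rectification stage (present in the hardware interface, out of
  scope here); the offset-weaker-than-onset asymmetry holds trivially.
* **Problem sizes.** The test suite exercises the full 180-trial, 4-s glove
  set once and runs the noise sweep on a reduced design (1-s trials, 6
  repetitions); both sizes are stated choices of the package, with the
  reduced design documented as the sweep's operating point.
* **Out of scope.** HDL generation, cycle-accurate DSP modelling,
  resource-utilization counts, SA-II/FA-II afferents, conductance-based
  models, adaptive-step integration, and skin mechanics ahead of
  transduction.
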