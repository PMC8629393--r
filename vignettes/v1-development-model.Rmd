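---
title: "A fully plastic spiking model of V1 layer 4: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fully plastic spiking model of V1 layer 4: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`v1plastic` simulates the development of orientation-selective simple
cells in a clock-driven (1 ms) spiking network of primary visual
cortex, layer 4. Whitened natural-scene patches of 12 × 12 pixels are
encoded by 288 Poisson LGN units — 144 ON units carrying the positive
pixel values and 144 OFF units the magnitudes of the negative values,
with the (rare) unit pixel magnitude mapped to 125 Hz. The LGN drives
an excitatory population (144 neurons at reference scale) and an
inhibitory population (36 neurons; the cortical 4:1 ratio) of adaptive
exponential integrate-and-fire (AdEx) neurons through all-to-all
projections. The two cortical populations are mutually connected, and
the interneurons inhibit each other (no self-connections), so the
circuit expresses both feed-forward and feedback inhibition.

Every projection is plastic. Excitatory synapses (LGN→E, LGN→I, E→I)
follow the voltage-based triplet STDP rule: potentiation is gated by
the instantaneous postsynaptic depolarization above
θ⁺ = −45.3 mV together with a fast low-passed voltage above
θ⁻ = −70.6 mV, weighted by a presynaptic spike trace (τ = 15 ms);
depression occurs at presynaptic spikes, scaled by a slow average of
the squared rectified depolarization, ū̄, relative to a reference
u_ref. This slow factor is a homeostat: a persistently depolarized
(or rapidly firing) neuron depresses more, a quiet one potentiates
more. Inhibitory synapses (I→E, I→I) follow the symmetric homeostatic
iSTDP rule: near-coincident pre/post spiking potentiates regardless
of order, lone presynaptic spikes depress by η·ρ, and the target
constant ρ thereby sets the postsynaptic firing rate the rule pulls
toward (ρ = 0.4 implies ≈ 20 Hz under independent spiking with the
10-ms unit-jump traces). ρ of the inhibitory feedback is the single
knob distinguishing the `EI2/1` (ρ = 0.4) and `EI3/1` (ρ = 0.7)
variants.

The AdEx neuron uses the standard voltage-STDP parameter set
(C = 281 pF, g_L = 30 nS, E_L = −70.6 mV, Δ_T = 2 mV, adaptive
threshold resting at −50.4 mV with τ = 50 ms, afterpotential 400 pA
with τ = 40 ms, adaptation a = 4 nS / b = 0.805 pA with τ = 144 ms).
After a threshold crossing the membrane is held at 29 mV for 2 ms and
then reset to E_L; the plateau is visible to the plasticity voltage
traces, which is what lets the potentiation term fire at spikes.

Every 20 s of simulated time, each neuron's OFF-weight vector is
rescaled so its Euclidean norm matches the ON norm, removing slow
ON/OFF drift.

## Numerical scheme

The simulator is clock-driven at dt = 1 ms with a fixed global update
order: (1) LGN Poisson spikes (one uniform draw per unit per step),
(2) synaptic currents incremented by the weights of *previous-step*
spikes (a one-step delay on every projection), (3) AdEx integration
and spike detection, (4) trace updates and plasticity, (5) clipping
of touched weights. Pure-decay variables (spike traces, adaptive
threshold, afterpotential) decay by the exact factor exp(−dt/τ); the
membrane potential, adaptation current, and driven voltage traces use
forward Euler. Spike traces use the unit-jump convention (+1 per
spike, so a single spike at t = 0 leaves exp(−t/τ)). Within a step,
the depression term reads the slow homeostatic trace ū̄ *before* its
update (an O(dt/τ_ū̄) choice), and voltage traces are updated to the
current step before the weight update. The compiled core
(`src/simulator.cpp`) and the exported R step functions
(`lgn_step()`, `adex_step()`, `clopath_update()`, `istdp_update()`)
implement the identical arithmetic; a test drives both over the same
random stream and requires bit-level agreement of spike counts.

All randomness flows through R's RNG (the C++ core consumes
`unif_rand()`), so a seed fully determines a run, and checkpoints
(which store the RNG state) restore bit-identically.

## Calibration choices

Four constants of the published rule set are underdetermined by its
printed form; each is an explicit parameter, with defaults frozen
after a dynamical calibration:

* **Synaptic coupling** (`syn_gain`, default 0.7). The current-based
  synapses approximate pulse input: one spike through weight w
  increments the current by `syn_gain * w * C / tau_syn` pA, i.e.
  delivers a peak depolarization of `syn_gain * w` mV. Taken
  literally, weight-unit increments in pA would depolarize by
  hundredths of a millivolt and nothing would ever spike. The default
  is chosen so that the model has its three qualitatively required
  regimes: a quiet, slowly potentiating developing state; a trained
  state firing a few Hz on natural patches; and a saturated
  all-weights-high state in which depression dominates, so that
  saturation is self-correcting rather than absorbing. At a coupling
  of 1.0 the saturated state becomes a stable attractor (the
  classical runaway failure of competing homeostats); at 0.3 the
  network is silent and decays. The default is tied to the scene
  generator's rate scale (mean LGN rates of ≈ 2.3 Hz); inputs with a
  different rate scale need a matching coupling.
* **Spike-threshold reset** (`VT_max`, default −30.4 mV). With a
  reset far above the reachable voltage range the threshold never
  re-enters it on a useful timescale and sustained firing is
  impossible; −30.4 mV is the value consistent with the rest of the
  parameter set.
* **Depression balance** (`ltd_scale`, default 2.8). With the printed
  LTD/LTP ratio of 0.78 the undifferentiated high-weight state sits
  exactly at LTP = LTD and absorbs every trajectory. The classical
  parameterization of this rule family uses a ratio of 1.75;
  restoring net depression at the undifferentiated state is what
  lets synaptic competition prune weights into bimodal, oriented
  receptive fields.
* **Presynaptic trace normalization** (`x_scale`, default 1/15 =
  dt/τ_x). The potentiation learning rates are only consistent with a
  per-spike presynaptic-trace contribution of dt/τ_x; with a full
  unit-jump contribution in the LTP term, potentiation outruns
  depression ~15-fold and every weight saturates within seconds of
  simulated time.

## Desk scale

Full-scale runs (144 E / 36 I, 400,000 stimuli ≈ 14 h simulated)
take hours of wall clock. The package's standard working point —
used by the worked examples, the acceptance checks, and
`desk_config()` — is 36 E / 9 I neurons trained on 50,000
synthetic-scene stimuli (≈ 100 min simulated time, about 40 s of
wall clock for training). Two scalings keep the reduced model
comparable:

* **Synaptic scaling**: recurrent weight bounds, init ranges, and
  learning rates are dilated by the population ratio (×4 for
  inhibitory sources, ×4 for E→I), preserving the total recurrent
  current a neuron can receive. The 288 LGN afferents are never
  scaled.
* **Schedule compression**: the inhibitory homeostat (η = 10⁻⁵) is
  calibrated for the 400,000-stimulus schedule; desk runs multiply η
  by the compression factor (8 at 50,000 stimuli) so the inhibitory
  state reaches a comparable developmental point.

## The synthetic scene generator

`generate_whitened_scene()` emulates whitened natural scenes: a base
image of sparse hard-edged elliptical patches (Laplacian-ish
amplitudes) over a weak 1/f Gaussian bed is modulated by a smooth
lognormal local-contrast field, then whitened by dividing out the
measured radially averaged amplitude spectrum under a
exp(−(f/f₀)⁴) high-frequency cutoff (f₀ = 0.4 × size, the classic
sparse-coding preprocessing scaled to the image), mean-centred, and
normalized by the maximum absolute pixel. The output is
approximately zero-mean, spectrally flat over the passband,
spatially decorrelated, and heavy-tailed (kurtosis in the tens), so
the per-scene maximum used for normalization is a rare event and
mean LGN rates land at a few Hz — the regime in which the
developmental dynamics are stable. What the generator does *not*
reproduce: long-range scene structure, occlusion statistics beyond
second order, and photometric nonlinearities; conclusions about real
natural images should be drawn from runs on an externally supplied
whitened image set (any grayscale matrix wrapped in
`whitened_scene()` works).

## Measurement protocols

* **Tuning curves** (`measure_tuning()`): sinusoidal gratings over a
  full 0–360° sweep in 8° steps (folded to the 0–180° orientation
  domain afterwards, which yields an effective 4° grid), crossed
  with 5 phases in [0, π] and 5 spatial frequencies in
  [0.05, 0.15] cycles/pixel, peak input rate 85.7 Hz, 125 ms per
  presentation. The per-orientation response is the mean count over
  repetitions, maximized over phase and frequency. The reference
  protocol uses 50 repetitions; desk-scale examples use 10–25.
* **Orientation bandwidth**: half-width at 1/√2 of the peak, linear
  interpolation on both flanks of the circular curve, mean of the
  two half-widths; curves that never cross the level (flat or
  high-baseline) are reported missing. At desk scale the curves of
  all variants saturate above roughly 20 Hz peak input (the
  disinhibited ones first), so sharpness and contrast-invariance
  comparisons are made over the 14.25-20 Hz band where bandwidth is
  measurable in every compared variant.
* **Diversity** (`orientation_diversity_index()`): exp(−D_KL) between
  the preferred-orientation histogram (22 equal bins over 0–180°,
  ≈ 8° wide) and the uniform distribution.
* **Sparseness / correlations / information / discriminability**: on
  randomly sampled natural patches at the training r_max, with
  125-ms spike counts; information uses the count-distribution
  entropies per neuron divided by the mean count; discriminability
  projects repetition-wise population vectors onto the difference of
  class means and — exactly as defined — divides the mean difference
  by the *average of the variances* (a `conventional = TRUE` toggle
  gives the standard-deviation form).
* **Reconstruction** (`image_reconstruction_error()`): overlapping
  12 × 12 patches at stride 3 (stride 4 in the fastest recipes),
  linear decoding by the ON−OFF feed-forward weights, overlap
  averaging, z-normalization of both images, RMSE.
* **E/I balance** (`ei_ratio()`): window-averaged excitatory and
  inhibitory currents of the excitatory population over repeated
  natural patches; summary ratio mean(I_exc)/mean(I_inh), with an
  infinite-ratio flag when inhibition is absent.

Between stimuli nothing is reset — voltages, traces, and currents
persist, during training and during measurement (measurement runs
simply keep plasticity off; all state keeps evolving).

## Design decisions on genuinely open points

* Noise patches for receptive-field mapping are Normal(15, 20) Hz
  draws clipped at zero and presented on the ON plane only (after
  clipping no pixel is negative, so the OFF plane is empty).
* The tuning reduction over phases and frequencies is a maximum (a
  phase-insensitive envelope, appropriate for simple cells probed at
  unknown phase alignment); repetitions are averaged.
* ū̄ is maintained per postsynaptic neuron and per projection.
* The ON/OFF norm equalization applies to both LGN→E and LGN→I.
* For the frozen-inhibition variants, all projections start from
  entry-permuted copies of a trained reference network (preserving
  each projection's weight-value multiset and hence its mean
  current), except LGN→E, which is re-drawn from a normal
  distribution matched to the reference's trained weight moments —
  drawing it from the naive uniform init range instead leaves the
  fresh feed-forward drive too weak against the full-strength frozen
  inhibition, and the network never fires again.
* Experiment orchestration is a set of R functions
  (`run_experiment()`, `sweep_seeds()`) rather than a shell
  executable; reports embed the configuration hash and seed, and a
  run is reproducible from its configuration alone.

## Known limitations

* The desk-scale model compresses development 8-fold and shrinks the
  cortical populations 4-fold. Orderings that depend on *specific*
  (co-tuning) inhibitory structure are noise-dominated at this
  scale: the trained I→E weights saturate at their (scaled) bound in
  all inhibition-bearing variants, so plastic and shuffled-frozen
  feedback inhibition differ much less than at full scale, and the
  diversity gap between `EI2/1` and `fix_fb_inh` lies within the
  sampling noise of 36 preferred orientations. Likewise the
  schedule compression means the frozen-inhibition variant enjoys
  full-strength inhibition from the first stimulus while the plastic
  variant's inhibition is still growing — a desk-scale artifact that
  compresses exactly the comparison the full-scale model makes
  cleanly.
* The desk-scale E/I current ratio on natural patches is ≈ 10:1
  (excitation-dominated) rather than the full-scale 2:1: nine
  interneurons firing a few Hz on sparse input cannot deliver half
  the excitatory current even with saturated weights.
* Individual runs vary substantially with the seed: the interacting
  homeostats put the model near a narrow corridor between silent
  decay and saturated runaway, and at some seeds the inhibitory
  weights fail to develop at all (the model class is known for a
  finite fraction of unstable runs; the reference experiments repeat
  every configuration 20 times for this reason). Conclusions should
  be drawn from seed sweeps (`sweep_seeds()`), not single runs.
* Poisson inputs regenerate independently every millisecond; there is
  no LGN temporal filtering, refractoriness, or bursting.
* The contrast-invariance and gain-control effects are measured with
  the same current-based synapses as training; conductance-based
  shunting effects are outside the model.

## Problem sizes used by the examples and checks

Training: 50,000 stimuli at 36 E / 9 I. Tuning: 25 repetitions per
condition (the reference protocol's 50 halves the noise at twice the
cost). Information: 150 stimuli × 30 repetitions. Reconstruction: one
96-pixel scene at stride 4, 10 repetitions per patch. Sparseness and
correlations: 1000 and 500 patches. These sizes keep a complete
variant comparison under ten minutes on one CPU while leaving every
qualitative contrast measurable.
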