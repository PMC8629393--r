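# v1plastic

A fully plastic spiking network model of primary visual cortex
(layer 4) for studying how **inhibitory plasticity shapes the
development of sensory coding**. The package is aimed at
computational neuroscientists who want a compact, reproducible
simulation of receptive-field development with a complete
measurement suite attached.

## The model

Whitened natural-scene patches (12 × 12 pixels) are encoded by 288
Poisson LGN units — positive pixels drive the ON half, magnitudes of
negative pixels the OFF half, with the (rare) unit pixel magnitude
mapped to 125 Hz. The LGN projects all-to-all onto excitatory and
inhibitory populations (4:1 ratio) of adaptive exponential
integrate-and-fire neurons,

  C du/dt = −g_L (u − E_L) + g_L Δ_T exp((u − V_T)/Δ_T) − w_ad + z + I_exc − I_inh,

with an adaptive threshold V_T, adaptation current w_ad, and
afterpotential z. Excitatory synapses evolve under the voltage-based
triplet STDP rule

  dw_i/dt = A_LTP x̄_i (u − θ⁺)₊ (ū⁺ − θ⁻)₊ − A_LTD (ū̄/u_ref) X_i (ū⁻ − θ⁻)₊,

whose slow factor ū̄ (low-passed squared depolarization) is a local
homeostat, and inhibitory synapses under the symmetric homeostatic
iSTDP rule (on a presynaptic spike w += η(x̄_post − ρ); on a
postsynaptic spike w += η x̄_pre), whose target constant ρ sets the
excitation/inhibition balance. Model variants: `EI2/1` (ρ = 0.4),
`EI3/1` (ρ = 0.7), `noInh` (no inhibition), `blockInh` (inhibition
zeroed after training), and `fix_fb_inh` / `fix_ff_inh` (feedback or
feed-forward inhibition frozen at shuffled reference weights).

The measurement suite covers receptive fields (weights and
spike-triggered averages), orientation tuning and bandwidth (OBW),
tuning diversity (ODI — the exponentiated Kullback–Leibler divergence
of the preferred-orientation histogram from uniform), neuronal gain
curves, E/I current balance, population sparseness (Vinje–Gallant),
mutual information per spike, discriminability (d′), and linear image
reconstruction (IRE).

## Worked example

Train a desk-scale model (36 E / 9 I, 50,000 stimuli — about 40 s)
on synthetic whitened scenes and measure its coding properties:

```r
library(v1plastic)
set.seed(1)
scenes <- generate_scene_set(8, size = 96)
net <- build_network(desk_config("EI2/1"))
net <- train(net, scenes, n_stimuli = 50000)$net

patches <- replicate(1000, rates_to_vector(
  on_off_split(sample_patch(scenes[[sample(8, 1)]]), 125)))
resp <- present_batch(net, patches, plastic = FALSE)
mean(population_sparseness(resp$counts_e), na.rm = TRUE)
#> [1] 0.58

tun <- measure_tuning(net, reps = 25)
orientation_diversity_index(tun$preferred)
#> [1] 0.58
```

A sparseness near 0.6 means most patches are represented by a small
fraction of strongly active neurons; an ODI near 0.6 means the
population's preferred orientations cover the orientation domain
fairly uniformly. The same pipeline with the `noInh` variant yields
visibly lower sparseness (≈ 0.52) and diversity (≈ 0.46), and higher
pairwise response correlations — the model's central claim that
inhibition during learning buys tuning diversity and a sparser, more
informative code. Blocking inhibition *after* training
(`block_inhibition(net)`) raises baseline activity, broadens tuning,
and breaks the contrast invariance of the bandwidth, while leaving
the learned receptive fields untouched.

See the methods vignette (`vignettes/v1-development-model.Rmd`) for
the model equations, numerical conventions, calibration choices, and
known desk-scale limitations.

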