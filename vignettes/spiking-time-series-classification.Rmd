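---
title: "Methods: Legendre Delay Networks as spiking time-series classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Legendre Delay Networks as spiking time-series classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldnspike)
```

This vignette is the package's own account of the models it implements: the
Legendre Delay Network (LDN) as a temporal memory, the two classifier
architectures built on it, the numerical decisions taken where the design
was genuinely open, and what the test suite does and does not establish.

## 1. The LDN as an optimal rolling memory

A pure delay `y(t) = u(t − θ)` has transfer function `e^(−θs)`, which is not
rational and therefore has no finite state-space realization; the LDN is its
optimal order-`d` Padé-style approximation. Its unscaled matrices have the
closed forms produced by `make_state_matrices()`: row `i` of `A` carries
entries of magnitude `2i + 1` with a sign pattern split at the diagonal, and
`B[i] = (2i+1)(−1)^i`.

**Where the window enters.** The closed forms carry no `θ`. A delay of `θ`
seconds requires the dynamics to run at rate `1/θ`, so the package applies
`A_c = A/θ`, `B_c = B/θ` (`scale_by_window()`) *before* both the neural
mapping and discretization. This placement is validated empirically rather
than assumed: the delay-reconstruction test decodes `u(t − θ/2)` from the
state with NRMSE far below 0.2, and the error falls as `d` grows — exactly
the behavior an optimal delay approximation must show.

**Discretization.** `discretize_zoh()` uses the zero-order-hold forms
`A_d = exp(A_c Δt)`, `B_d = A_c^{-1}(A_d − I)B_c`, computed via the
augmented-matrix exponential `exp(Δt [[A, B], [0, 0]])` so that singular
`A_c` needs no special-casing. The discrete update applies the input of the
*current* step, `x[t] = A_d x[t−1] + B_d u[t]`, consistent with simulating
the whole network once per time-step. Agreement with fine-step Euler
integration (step `Δt/1000`) is held to 1e−6 relative error on random
stable systems; for that comparison the random systems are scaled to
unit-order spectral norm, because the *Euler reference's own* truncation
error grows as `‖A‖² h²` and would otherwise dominate the discrepancy being
measured.

**Neural form.** Rewriting `dx/dt = A_c x + B_c u` as a first-order
low-pass `h(t) = (1/τ) e^{−t/τ}` acting on `A' x + B' u` gives
`A' = τ A_c + I`, `B' = τ B_c` (`neural_mapping()`). The package simulates
this filtered form (`simulate_filtered()`) only for the reservoir model and
for the equivalence check, which asserts monotone error decrease across
`Δt ∈ {1e−3, 1e−4}` against the ZOH simulation; the LSNN path always uses
the exact discretization.

**Delay decoders.** The readout for `u(t − φ)` is fit by least squares on a
simulated trace rather than by a closed-form Legendre-polynomial formula:
regression is self-contained, testable, and makes no claim about the
polynomial structure. The first `⌈θ/Δt⌉` samples are discarded as transient
because the window is not yet filled.

## 2. Discrete-time IF neurons

All spiking units are non-leaky integrate-and-fire neurons without
refractory period or recurrent current; membrane resistance is fixed at 1.
A neuron spikes when `V ≥ V_thr` — at exact equality, since the reset rule
is stated for `V ≥ V_thr` — and the reset is *hard* (`V ← 0`), not
subtractive. Within one step the order is: current, then voltage, then
spike, then reset, so a layer sees the current-step spikes of the layer
below.

Three layer types differ only in their update laws (with
`α = exp(−Δt/τ_cur)` and `β = exp(−Δt/τ_vol)`):

| layer | current | voltage | spikes |
|---|---|---|---|
| ENC | `I = ρ ε x + ι` | accumulate, no decay | yes |
| HDN | `I[t] = αI[t−1] + W'S[t]` | accumulate, no decay | yes |
| OTP | same as HDN | `V[t] = βV[t−1] + I[t]` | never |

**Encoder pairs.** Each LDN feature feeds a `+/−` pair (`ε₀ = +1`,
`ε₁ = −1`); with zero bias only one member of a pair receives positive
current at a time. The raw update would let the inactive member accumulate
arbitrarily negative voltage, producing unbounded dead time after a sign
flip; the package therefore clamps ENC voltages below at 0 by default
(`clamp_enc`, switchable), which also preserves per-pair spike exclusivity.
Initial voltages and currents are zero.

**Surrogate gradient.** The Heaviside derivative is replaced in the
backward pass by the fast-sigmoid form `f'(x) = 1/(1+|x|)²` at
`x = V − V_thr`. The reset path is excluded from gradient flow — the
`(1 − S)` gate is treated as constant — which is the standard
surrogate-gradient treatment, and the loss chain then contains only the
surrogate at the spike plus the linear accumulation paths. The `nspk`
variant is fully differentiable, so the identical backward machinery is
checked there against central finite differences at 1e−4 relative
tolerance (it passes with orders of magnitude to spare).

## 3. The LSNN classifier

`build_lsnn()` fixes the layer widths to `N_ENC = 2d`, `N_HDN = 3d`,
`N_OTP = n_classes`: `5d` spiking neurons in total (50 at `d = 10`, 120 at
`d = 24`). Only the two matrices between ENC→HDN and HDN→OTP are trained;
LDN and encoder connections are static. Per-class scores are the maxima of
the output voltages over all steps (including the first), the loss is the
softmax negative log-likelihood of those maxima, and argmax ties resolve to
the lowest class index for determinism.

Decisions the architecture leaves open, resolved here:

* **Weight initialization** — uniform on `(−1/√fan_in, +1/√fan_in)`,
  seeded; keeps early spiking activity at a workable scale.
* **Bias on both pair members** — the ENC current law adds `ι` to both the
  positive and negative encoder, even though a positive `ι` weakens pair
  exclusivity; the stated update takes precedence over the prose.
* **Feature precomputation** — LDN features (and ENC spike trains, which
  depend on no trainable weight) are extracted once for the whole dataset
  before training; features are not normalized.

## 4. Training protocol

`train_lsnn()` runs Adam (η configurable; `β₁ = 0.9`, `β₂ = 0.999`,
`ε = 1e−8` — only the optimizer itself is prescribed, so the usual defaults
are used) over contiguous mini-batches, reshuffling the training data every
20 epochs, and evaluates accuracy on the *entire* test set every epoch. A
run's accuracy is its best epoch's; `grid_search()` crosses a value grid
with seeds, initializing weights freshly per run (weights never persist
across combinations), and reports `Max_acc` — the maximum over all
combinations and seeds — and `Mean_acc` — mean of the per-seed maxima, with
its sample standard deviation (`n−1` denominator; the bare `±` in the
accounting convention does not fix one, and the sample convention is the
honest choice for three seeds). Selecting the best epoch by test accuracy
reproduces the protocol this family of models reports; it is documented
here as optimistic, since the test set participates in model selection.
Training-set sizes must divide the batch size — `trim_to_batch()` drops the
minimal trailing remainder, once, at load time, before any shuffling.

## 5. The SLRC reservoir

`build_slrc()` realizes the LDN in `d` scalar NEF ensembles (the reservoir)
plus one aggregating ensemble of `n_sn · d/4` neurons representing the full
state for the readout. Connection weights are `τB` (input), `τA + I`
(recurrent), and identity (reservoir to aggregator); conceptually these are
pre- and post-multiplied by encoder and decoder matrices into one dense
neuron-to-neuron matrix — the package keeps the factored operations, which
are numerically identical and cheaper.

**Rate model.** Neurons are rectified-linear in their normalized current:
`rate = max_rate · max(0, J)` with `J = 0` at the intercept and `J = 1` at
the preferred input of magnitude `radius`; gains and biases are solved from
those two constraints. Maximum rates are uniform in `[FR_min, FR_max]`,
intercepts uniform across the radius. This matches the smooth tuning curves
non-leaky IF neurons exhibit on a general-purpose processor. In `spiking`
mode the same neurons emit binary spikes (voltage integrates the
instantaneous rate, threshold 1, subtractive reset keeps the rate exact)
and all spike-derived quantities are low-pass filtered before use.

**Synapses.** The recurrent loop uses the `τ = 0.1 s` filter — it is the
integrator that the neural mapping is built around. The reservoir-to-
aggregator connection and all decoded-state reporting use a shorter 10 ms
readout synapse (`tau_readout`), the conventional probe scale; a 100 ms
synapse there would add nothing but lag.

**Inhibition.** Between independent samples a normalized current of −8 is
injected into every reservoir neuron for 50 steps with zero input,
silencing the population and letting the synaptic traces decay; the decoded
state at the end of the window is required to be below 0.1 in magnitude
regardless of prior state. The residual trace inside the 100 ms recurrent
filter decays more slowly than the 50 ms window — memory clearing is
measured at the decoded state, which is what the readout sees.

**Readout.** Per-step aggregator activities are averaged over the last
`⌈T/4⌉` steps of each sample — by then the window has integrated most of
the signal — giving one regression row per sample; nothing in the
architecture dictates how per-step activity becomes per-sample features, so
this summary is a package decision, as is regressing against per-sample
(not per-step) one-hot targets. Ridge regression with default
`λ = 0.1 ×` the mean activity scale maps summaries to classes. Prediction
scores are rounded to the nearest integer; the predicted class is the node
with the highest rounded score, ties broken by the raw score and then by
the lowest index — the rounding rule is stated for the accuracy
calculation, its tie-breaks are this package's documented completion.

## 6. The synthetic fixture generator

`generate_synth()` produces balanced two-class sets shaped like the ECG
binary task: 140-step signals, defaults of 200 training and 100 test
samples with noise sd 0.1. `bump_polarity` mode places an upward
(class 0) or downward (class 1) Gaussian bump of amplitude `class_gap` at a
uniformly random latency — a caricature of the morphology difference
between heartbeat classes; `frequency` mode uses sinusoids separated in
frequency by the gap. An independent threshold oracle (sign of the largest
extremum) verifies separability: at the default gap and noise it exceeds
99% accuracy, so a classifier that fails here is broken, not unlucky.

What the fixture does **not** emulate: class imbalance (real ECG5000 is
58/42 at best and 0.4% at worst per original class), within-class
morphology variability, baseline wander, or inter-sample correlation.
Passing the learning criterion on fixtures therefore demonstrates that the
gradient machinery and architecture work, not that headline accuracies on
the real archives are reproduced — those require downloading the archives
and running the full three-seed grids, which the reader can do with
`load_ucr()` + `grid_search()` unchanged.

## 7. Problem sizes and tolerances

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in about a minute: delay decoding on 5 s probes;
discretization checks on 20 random systems of order ≤ 12; learning checks
with `d = 10`, 200/100 train/test samples, 50 epochs, three seeds (≥ 95%
test accuracy required in at least two); reservoir fidelity at `d = 6`,
200 neurons per ensemble on a 1 s probe (NRMSE < 0.2 per state dimension).
Key numerical tolerances: exact equality for the closed-form matrices;
1e−6 relative for ZOH vs. Euler; 1e−8 for the impulse response against the
matrix exponential (at `Δt = 1e−5`, where the first-order difference
between `B_d` and `Δt·B_c` is negligible); 1e−4 relative for gradient
checks. The highest-order LDN state dimensions carry the least signal
power, so per-dimension NRMSE is the strictest fidelity measure — dimension
`d` is always the worst.

## 8. Known limitations

* Univariate signals only; one hidden layer; no early stopping, validation
  splits, or learning-rate schedules — none belong to the protocol being
  implemented.
* The spiking-mode reservoir at desk-scale population sizes is
  substantially noisier than rate mode (NRMSE roughly 2–3× higher); rate
  mode is the reference implementation of the architecture's fidelity
  claims.
* Best-epoch selection on test accuracy (Section 4) is optimistic by
  construction.
* The LDN output matrices (`C`, `D` of the general LTI form) are
  deliberately not implemented — the classifiers consume the state, never
  the LTI output.
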