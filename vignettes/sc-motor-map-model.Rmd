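---
title: "A spiking neural-network model of the superior colliculus motor map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking neural-network model of the superior colliculus motor map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

The deeper layers of the midbrain superior colliculus (SC) hold a topographic
motor map of saccadic eye movements: rostral sites encode small saccades,
caudal sites large ones. In the linear ensemble-coding view, every spike of a
recruited SC neuron contributes a fixed miniature displacement (its *spike
vector*) to the ongoing eye movement, and the saccade trajectory is the
running sum of all spike vectors of the population. `colliculus` implements a
one-dimensional, two-layer spiking instantiation of that idea and the
stimulation protocols used to probe its robustness to spatial and temporal
input variation.

**Layers and geometry.** Both layers hold `n_neurons = 200` adaptive
exponential integrate-and-fire (AdEx) neurons on a uniform 0–5 mm lattice
(`map_grid()`), so neuron index 101 sits at exactly 2.5 mm. A target at
eccentricity $T$ maps to the anatomical image point
$u_T = B_u \ln\!\big((T + A)/A\big)$, with $A = 3$ deg and $B_u = 1.4$ mm
(`afferent_map()`); these constants are not uniquely fixed by the anchor we
adopt ($T = 15^\circ \leftrightarrow u_T = 2.5$ mm), but this is the standard
logarithmic magnification that also keeps 5–45 deg targets inside the 5 mm
map. The exact inverse $R(u) = A(e^{u/B_u} - 1)$ (`efferent_map()`) assigns
each neuron its preferred eccentricity, and its spike vector is
$m(u) = \zeta\, R(u)/N_{\mathrm{ref}}$ with $N_{\mathrm{ref}} = 500$, the
fixed total spike budget of a site-specific saccade. The decoder is defined
only up to the global gain $\zeta$, which the calibration fixes once (below).

**External input.** The cortical input current is separable
(`external_current()`):
$$
I_{\mathrm{ext}}(u, t) \;=\; I_0\,
\exp\!\Big(-\tfrac{(u - u_T)^2}{2\sigma_{\mathrm{pop}}^2}\Big)\cdot g(t),
\qquad
g(t) \;=\; \frac{t^{\gamma} e^{-\beta t}}{(\gamma/\beta)^{\gamma} e^{-\gamma}} .
$$
Two reading conventions matter. First, we take $t$ in ms and $\beta$ in
ms$^{-1}$: with the default $\beta = 0.03$, $\gamma = 1.8$ the current peaks
at $t = \gamma/\beta = 60$ ms and the burst lasts of order 150 ms, the only
reading compatible with the stated burst durations (an s$^{-1}$ reading
would put the peak at 60 s). Second, the gamma factor is normalized to unit
peak so that $I_0$ is literally the maximum current in pA; the raw
$t^{\gamma}e^{-\beta t}$ would otherwise reach values far above $I_0$.

**Neurons.** Each neuron follows the AdEx equations with conductance-based
synapses,
$$
C\dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} - q
          + \textstyle\sum_s g_s (E_s - V) + I_{\mathrm{ext}},
\qquad
\tau_q \dot q = a (V - E_L) - q,
$$
with a spike emitted at $V \ge V_{\mathrm{cut}}$, reset to
$V_{\mathrm{reset}}$, adaptation increment $q \leftarrow q + b$, and an
absolute refractory period $t_{\mathrm{ref}}$. Input-layer neurons receive
the external current through a saturating sigmoid
(`rate_cap_transfer()`, $I_{\mathrm{sat}}\tanh(I/I_{\mathrm{sat}})$,
identity-like below the default 3 pA) and carry $t_{\mathrm{ref}} = 2.5$ ms,
which makes the 400 spikes/s ceiling on input firing a hard guarantee rather
than an asymptotic one. SC neurons carry $t_{\mathrm{ref}} = 1$ ms, an
adaptation increment $b$, and the location gradient
$\tau_q(u) = 60 - 12\,u$ ms.

**Connectivity.** Input neuron $n$ projects only to SC neuron $n$
(topography-preserving one-to-one feedforward) with the gradient weight
$w^{FS}(u) = 10 - 1.2\,u$ nS — strong rostrally, weak caudally. The SC layer
is all-to-all (minus self) with the Mexican-hat pair
$$
w^{\mathrm{exc}}(d) = S_n \bar W_{\mathrm{exc}} e^{-d^2/2\sigma_{\mathrm{exc}}^2},
\qquad
w^{\mathrm{inh}}(d) = S_n \big(1 - \bar W_{\mathrm{inh}}
                      e^{-d^2/2\sigma_{\mathrm{inh}}^2}\big),
$$
$\bar W_{\mathrm{exc}} = 0.16$ nS, $\bar W_{\mathrm{inh}} = 1.15$ nS,
$\sigma_{\mathrm{exc}} = 0.2$ mm, $\sigma_{\mathrm{inh}} = 0.7$ mm, and the
site-dependent lateral gain $S(u) = 1 - 0.04\,u^2$ evaluated at the *source*
neuron (its outgoing weights scale with its own site, matching the published
net-weight profile of the central 15-deg neuron, $+0.2325$ nS at zero
distance; a config flag allows target-side scaling for sensitivity tests).
Within ±0.37 mm the inhibitory expression is negative — net disinhibition —
and conductances cannot be negative, so `route_signed_weights()` adds the
negative part to the excitatory conductance instead; this preserves the sign
of the net drive everywhere and its magnitude near rest.

**Feedforward receptor kinetics.** The feedforward synapse onto SC neurons
uses its own fast decay constant (`tau_syn_ff`, 0.3 ms) distinct from the
slower intra-collicular excitatory kinetics (`tau_syn_exc`, 2.73 ms). This is
a deliberate design choice, not a detail: with a single shared excitatory
time constant the ratio of recurrent to feedforward drive is locked by the
published weight scales, the SC burst then simply tracks the slow input
envelope, and no synchronized population burst forms. Distinct
receptor kinetics per pathway (a fast AMPA-like feedforward component, a
slower recurrent component) are biophysically routine and give the lateral
circuit the gain it needs to act as a soft winner-take-all: the feedforward
volley ignites the population, recurrent excitation synchronizes and
amplifies it, the slow lateral inhibition (`tau_syn_inh`, 32 ms) confines it
in space and, together with spike-triggered adaptation, terminates it.
Because both the lateral gain ($S_n$) and the adaptation memory
($\tau_q(u)$) fall toward the caudal end, caudal populations burst at lower
rates for longer — the substrate of the saturating main sequence.

**Decoding and kinematics.** `decode_trajectory()` accumulates spike vectors
into the eye displacement $S(t)$ (no smoothing on position; the final
amplitude equals $\sum_n m_n N_n$ exactly, independent of spike timing).
Velocity is the Savitzky–Golay first derivative (window 21 samples at 1 ms,
order 3). Saccade onset and offset are the first and last crossings of 5% of
peak velocity — a relative criterion that still behaves for the slow,
near-threshold movements where any fixed deg/s threshold fails. The two
kinematic laws are fitted by `fit_main_sequence()`
($V_{\mathrm{peak}} = V_0 (1 - e^{-\alpha R})$, Levenberg–Marquardt) and
`fit_kinematic_slope()` ($V_{\mathrm{peak}} \cdot D = k\,R$, zero-intercept
least squares).

## Calibration: which constants are free, and how they are fixed

The published structure fixes the stimulus equation, the lateral weight
equations and the three gradients. The individual AdEx constants are not
printed, so they were resolved here, once, against the published firing
statistics, and then frozen as package defaults:

* input layer: $C = 0.048$ pF, $g_L = 0.015$ nS, rest $-70$ mV, threshold
  $-50$ mV — a fast, non-adapting cell whose rate follows the pA-scale
  current near-linearly and saturates under the sigmoid cap and the 2.5 ms
  refractory period;
* SC layer: $C = 12.6$ pF, $g_L = 2.1$ nS, $V_T = -55$ mV,
  $V_{\mathrm{reset}} = -60$ mV, $b = 9.2$ pA, $E_{\mathrm{inh}} = -75$ mV,
  synaptic decays as above.

The statistics used as calibration criteria are: input rates capped at
400 spikes/s; the central SC cell of the default 15-deg stimulation emitting
about 18 spikes with a peak spike-density rate near 550 spikes/s; a total SC
spike count near 500; and main-sequence fits in the vicinity of
$V_0 \approx 1600$ deg/s, $\alpha \approx 0.03$ deg$^{-1}$, $k \approx 2$.

`calibrate_model()` then resolves the two remaining run-time scales from a
documented, deterministic procedure: (i) a joint multiplier on $(C, g_L)$ of
both layers — which preserves every membrane time constant — chosen from a
fixed grid to bring the central cell's peak rate closest to 550 spikes/s
subject to the input cap (the packaged defaults already sit at the optimum,
so the procedure is idempotent); and (ii) the decoder gain $\zeta$, fixed
exactly by one default run since the decoded amplitude is linear in $\zeta$.

```{r calibrate}
library(colliculus)
model <- calibrate_model()
model
```

## Numerical choices

* **Integration.** The membrane equation is advanced by a linearized
  exponential-Euler step: the leak and synaptic-conductance part is
  integrated exactly over the step, the spike-initiation exponential is
  explicit with its argument clamped at $+10$ slope factors. Plain forward
  Euler is not an option here: synaptic conductances (nS) exceed the leak by
  orders of magnitude, the membrane equation is stiff, and the explicit
  update oscillates into runaway firing. Adaptation uses forward Euler;
  conductances decay exponentially. Default `dt = 0.05` ms; halving it
  reproduces early spike times to < 0.2 ms and steady rates to ~1% (a slow
  first-order phase drift over long trains is expected and harmless).
* **Event handling.** Zero axonal delay; a spike is stamped at the start of
  the step in which $V$ crossed $V_{\mathrm{cut}}$ and delivered to its
  targets at the end of that step. A NaN anywhere aborts the run with
  diagnostics.
* **Spike-density estimates** use a Gaussian kernel ($\sigma = 4$ ms,
  config-exposed), each spike's kernel renormalized by its mass inside the
  evaluation window so the trace integrates back to the spike count.
* **The central cell** of a population is the neuron with the maximal spike
  count, ties broken toward the neuron nearest $u_T$.
* **Temporal-sweep calibration** finds, for each $\beta$ in
  $[0.019, 0.030]$ ms$^{-1}$, the amplitude $I_0$ by bisection (at most 40
  iterations, 1% tolerance on the matched spike count; $I_0$ restricted to
  0.2–3.0 pA when matching SC-layer output, 1.2–3.0 pA when matching
  input-layer output). The default amplitude is accepted without search when
  it already matches. Because recruitment is discrete, at some $\beta$ no
  admissible $I_0$ reaches the default SC count within 1%; those conditions
  are reported with `converged = FALSE` and the closest achievable count —
  never silently clipped.
* **Sweep grids.** Population sizes
  $\sigma_{\mathrm{pop}} \in \{0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.4, 0.5,
  0.6, 0.7, 0.85, 1.0\}$ mm with the amplitude ramped linearly from 2 pA at
  0.05 mm to 3 pA at 0.5 mm (the sweep protocol states the range, not the
  law; linear is the simplest reading) and clamped at 3 pA above; twelve
  $\beta$ values, 0.019–0.030 in steps of 0.001; main-sequence sites
  $T \in \{2, 5, 8, 11, 15, 19, 24, 30, 37, 45\}$ deg (the protocol fixes
  ten sites without listing them; these span the map roughly uniformly in
  anatomical coordinates). All config-exposed.

## Problem sizes

Every full-network run integrates 2 × 200 AdEx neurons for 400 ms at
`dt = 0.05` ms (8,000 steps) through compiled code — well under a second per
condition. The packaged experiment suite (calibration, a 12-condition spatial
sweep at three sites, bisection-calibrated temporal sweeps, the ten-site main
sequence) runs in a few minutes on one core.

## What the simulated protocols do and do not show

The stimulation protocols emulate the *study conditions*: noise-free,
single-population Gaussian inputs with gamma-shaped time courses, swept in
spatial extent (microstimulation-like current variation) and in
duration/intensity. They do not emulate several features of the real system,
so passing checks here say nothing about them:

* **No noise.** The model is fully deterministic (identical runs are
  bit-identical). Real SC populations show multiplicative and additive rate
  variability; none of the trial-to-trial statistics of real recordings are
  reproduced or tested.
* **No saccade-offset gate.** There is no omnipause-style termination: every
  SC spike reaches the decoder. Amplitude control rests entirely on the
  input calibration, which is why the temporal sweeps must co-tune $I_0$
  with $\beta$.
* **One dimension.** Only horizontal-meridian amplitudes; no direction
  coding, no component cross-coupling.
* **No prelude or post-saccadic activity**; each cell fires one
  saccade-related burst.

## Known limitations

* With the tuned normalization, the *per-cell* spike count of the central
  neuron stays near its default (~18) when the input population shrinks to
  $\sigma_{\mathrm{pop}} = 0.1$ mm, while the *decoded amplitude* degrades
  (≈13 vs 15 deg). Electrophysiology (and the reference behavior this model
  targets) has the central count dropping to ~11: the soft winner-take-all
  attractor implemented here stereotypes the central burst once ignited.
  Across a broad exploration of the free AdEx constants we found no regime
  that grades the central count at small $\sigma_{\mathrm{pop}}$ while
  preserving the default-condition statistics and full-map site coverage;
  this is the model's main acknowledged deviation.
* The decoded amplitude plateau above $\sigma_{\mathrm{pop}} = 0.5$ mm holds
  to ±10% up to ≈0.6 mm but drifts low (≈ −20%) by 1.0 mm: very wide inputs
  recruit extra rostral (small-spike-vector) activity, shifting the decoded
  centroid rostrally. Likewise, below 0.5 mm the amplitude decline is
  monotone as a trend but jitters by a spike or two per condition (discrete
  recruitment).
* Main-sequence amplitudes compress at the most caudal sites (a 45-deg site
  decodes to ≈20–25 deg), flattening the top of the fitted saturating
  relation; the fitted $V_0$ and $\alpha$ remain within ~25% of the
  reference values, and the kinematic slope $k$ is robust (≈1.9).
* Extreme sensitivity to parameters near attractor boundaries is intrinsic
  to the winner-take-all design: single conditions can shift by one or two
  recruited neurons under sub-percent parameter changes. All defaults are
  frozen exactly, and the model is deterministic, so results are exactly
  reproducible; they are *not* smooth in every parameter.

## Reproducing the experiment suite

```{r suite}
model <- calibrate_model()

spatial <- run_spatial_experiment(model, sites = c(15, 20, 30))
temporal <- run_temporal_experiment(model, "fixed_output_spikes")
ms <- run_main_sequence(model)

ms$main_sequence   # V0, alpha of the saturating amplitude-velocity relation
ms$kinematic       # k of V_peak * D = k R
```

A thin command-line driver over the same functions lives in
`inst/cli/scmodel.R` (subcommands `calibrate`, `simulate`, `sweep-spatial`,
`sweep-temporal`, `main-sequence`, `decode`), and `scripts/acceptance.R`
recomputes the headline quantities from scratch.
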