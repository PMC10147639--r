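---
title: "Models and methods behind thetanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thetanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetanet)
```

## The model

thetanet simulates a network of $N$ theta-neurons, the normal form of a
class-I excitable cell. The phase $\theta_i \in [-\pi, \pi)$ of neuron $i$
evolves as

$$
\dot\theta_i \;=\; (1-\cos\theta_i) \;+\; (1+\cos\theta_i)\!\left[
  \eta_i + \frac{g}{N}\sum_j \kappa_{ij}\sin(\theta_j-\theta_i)
  + I_i(t) + \xi_i(t) \right],
$$

where $\eta_i$ is the excitability (an isolated neuron with constant
$\eta>0$ spikes with period $\pi/\sqrt{\eta}$, the spike being the crossing
of $+\pi$), $g$ a global coupling scale, $\kappa_{ij}$ the adaptive weight
from pre-synaptic $j$ to post-synaptic $i$, $I_i$ an external stimulus and
$\xi_i$ independent Gaussian noise. The coupling is diffusive (sinusoidal
in the phase difference), i.e. the synapses act like electrical gap
junctions. Synchrony is quantified by the Kuramoto--Daido order parameters
$Z_n = R_n e^{i\Psi_n} = \frac1N\sum_j e^{in\theta_j}$: $R_1\approx 1$
marks global synchrony, $R_1\approx 0$ with $R_2\approx 1$ two anti-phase
clusters, $R_M \approx 1$ an $M$-cluster splay pattern.

### Plasticity

Weights adapt through a symmetric Hebbian rule driven by the instantaneous
phase difference $\Delta\theta = \theta_j - \theta_i$ through a kernel
$\Lambda(\Delta\theta)$: `kernel_lambda0()` is $\cos\Delta\theta$;
`kernel_lambda1()` is a $2\pi$-periodic pair of exponentials whose
potentiation lobe (around $\Delta\theta = 0$) has e-fold width 0.1 rad and
whose depression lobe (around $\pm\pi$) has width 0.5 rad — depression
acts on a window five times longer than potentiation, as measured for
cortical spike-timing plasticity. Both kernels attain the same extrema to
within $2\times10^{-3}$.

Two learning rates act in parallel: a slow rate $\varepsilon_1 = 10^{-5}$
that is always on, and a fast rate $\varepsilon_2 = 0.1$ gated on only
while the *pre-synaptic* neuron receives a stimulus with $|I_j| > 0.1$,
and only for synapses between two excitatory neurons. Under Dale's
principle the weights obey soft bounds,

$$
\dot\kappa_{ij} = \bigl[\varepsilon_1 + \varepsilon_2
H(|I_j|-0.1)\bigr]\,\kappa_{ij}(1-\kappa_{ij})\,\Lambda(\Delta\theta)
\qquad\text{(both neurons excitatory)},
$$

$$
\dot\kappa_{ij} = \varepsilon_1\,|\kappa_{ij}|\,(1-|\kappa_{ij}|)\,
\Lambda(\Delta\theta)
\qquad\text{(pre- and/or post-synaptic neuron inhibitory)},
$$

with $\kappa \in [0,1]$ for excitatory and $\kappa \in [-1,0]$ for
inhibitory pre-synaptic columns. The inhibitory rule acts on the *signed*
weight: a positive kernel value (partners in phase) drives an inhibitory
weight towards $0$, a negative one (anti-phase) towards $-1$. This is the
reading under which consolidation produces the observed feedforward
architecture — an inhibitory neuron synchronised with its cluster sheds
the inhibition onto that cluster and strengthens it onto the anti-phase
clusters; the opposite (magnitude-based) reading strengthens inhibition
within the synchronous cluster and destroys the architecture. In
unlabelled mode (no Dale constraint) the rule is relaxational,
$\dot\kappa = [\varepsilon_1 + \varepsilon_2 H]( -\kappa +
\Lambda_0(\Delta\theta))$ with $\kappa \in [-1,1]$.

### Reading of the distribution parameters

The nominal parameter table gives $\eta \sim \mathcal N(1.5,\,0.01)$ and
$\xi \sim \mathcal N(0,\,0.1)$ without stating whether the second entry is
a variance or a standard deviation. The two readings produce starkly
different baseline states: with the variance reading (noise sd
$\approx 0.32$) the unstimulated E/I network relaxes only to $R_1 \approx
0.6$, while the standard-deviation reading ($\eta$ sd 0.01, noise sd 0.1)
gives $R_1 \approx 0.99$ — the nearly fully synchronised rest state on
which the entrainment narrative rests. The package therefore adopts the
standard-deviation reading: `sim_config()` defaults to
`eta_variance = 1e-4` and `noise_variance = 0.01`.

## Numerical scheme

The stochastic phase equations are integrated with a Heun
predictor–corrector (`dt = 0.01` by default): the predictor is an
Euler–Maruyama step, the corrector averages drift and the multiplicative
diffusion coefficient $\sigma(1+\cos\theta)$ between the two points, which
converges to the Stratonovich solution. Spikes are detected as upward
crossings of $+\pi$ on the unwrapped increment, with linearly interpolated
spike times; downward crossings (possible transiently under strong noise)
are not counted. The noise-free integrator reproduces the closed-form
period $\pi/\sqrt\eta$ to 1% at `dt = 0.01` and 0.1% at `dt = 0.001`.

Weights are advanced by one Euler step per time step, after the phase
update and using the updated phases; with $\varepsilon \le 0.1$ the
ordering effect is $O(dt^2)$. Updated weights are clamped so magnitudes
stay inside $[10^{-6}, 1-10^{-6}]$: the soft bounds make 0 and 1
absorbing, and the tiny interior clamp prevents an Euler overshoot from
freezing a weight at a bound. Inside the compiled core the kernel is
evaluated through a piecewise-linear table with 8192 intervals and nodes
at the slope breaks ($-\pi$, $0$, $\pi$); the interpolation error is below
$10^{-5}$, orders of magnitude beneath the dynamical noise. The exported R
kernels are exact. All randomness — initial conditions, noise increments,
schedule randomisation — consumes the R random-number stream in a fixed
documented order, so a single `set.seed()` reproduces a run; noise-free
runs draw nothing.

## Protocols and their defaults

The entrainment protocol has three regimes: rest (200 time units; the
first 190 are treated as transient), learning, and consolidation.
During learning, stimulation blocks of 20 time units and amplitude 3
target one stimulus group at a time in uniformly random order (strictly
alternating, with a 5-unit gap, for the overlapping-stimuli protocol —
the alternation and the short rest are part of that protocol's
definition). The default number of blocks gives every group the same
expected exposure, 25 blocks per group, matching the canonical
two-stimulus run (50 blocks over groups 1–40 and 41–80 of the 80
excitatory neurons).

The slow rate implies consolidation horizons of order $1/\varepsilon_1 =
10^5$ time units. Desk-scale runs therefore rescale: the slow rate is
multiplied by $\rho$ and the duration divided by $\rho$, preserving the
number of plasticity e-folds $\varepsilon_1 \cdot t$
(`consolidation_params()`, default $\rho = 100$: $\varepsilon_1 = 10^{-3}$
for 2000 units, i.e. 2 e-folds). Two e-folds stabilise the learned
two-cluster state and are the setting used for the stability sweeps;
reaching *saturation* — fully specialised inhibitory wiring, an all-to-all
matrix in the excitatory-only control — needs roughly 12 e-folds, which
the saturation-level experiments obtain by compressing further
($\rho = 300$–600 at the same e-fold count). The rescaling is valid while
$\varepsilon_1\rho \ll \varepsilon_2 \ll 1$ and the weight dynamics stays
slow against the phase dynamics; pushing $\rho$ higher distorts outcomes
that hinge on a race between synaptic reorganisation and cluster motion
(see below).

## Stability experiments

`run_stability_trial()` probes whether a stored modular architecture
survives spontaneous plastic evolution. The pre-trained matrix
(`build_pretrained_matrix()`) realises the consolidated architecture:
saturated intra-cluster excitation, feedforward excitation onto each
cluster's inhibitory neurons, and inhibition of all other clusters.
Because exactly saturated weights are immobile under the soft bounds, the
matrix is softened (`soften_pretrained()`) to the nearly saturated values
actually measured at the end of a learning phase: the median saturated
E–E weight is $\approx 1-10^{-4}$ and the median pruned cross-cluster
weight $\approx 0.003$, so `w_high = 0.99` and `w_low = 0.003`.

Survival is judged jointly (`count_surviving_modules()`): assemblies merge
structurally when strong weights bridge them, or dynamically when two
populations coalesce into a single phase cluster through essentially the
whole final 50-unit window. The dynamical criterion is deliberately
strict (co-membership in at least 90% of samples at a 0.25 rad gap):
a cluster that phase-locks a few tenths of a radian behind another —
which happens to an assembly whose inhibitory budget is exhausted, since
its extra inhibitory load shifts its frequency — is still a distinct
assembly, and a cluster that merely drifts past another during phase
slips is not merged either. On desk-scale horizons phase coalescence
precedes the slow structural fill-in, so the dynamical channel is what
detects a merge; at full scale the weights follow.

Two constructions are used, and the difference matters:

* **Module-capacity sweeps** (`stability_map_modules()`) keep the
  idealised, pre-assigned inhibitory wiring. This is the construction
  needed to probe extreme cases — a single inhibitory neuron per cluster
  would never emerge from random learning. Under it the capacity law is
  clean: $M$ modules survive if and only if the network has at least
  $M-1$ inhibitory neurons. With $M-2$ or fewer, at least two clusters
  share the fate of having no dedicated inhibition; repelled by the same
  inhibitory neurons, they are driven to the same phase and coalesce.

* **Hub sweeps** (`stability_map_hubs()`) start instead from the
  *post-learning* state: the trained excitatory structure (two clusters
  sharing $N_H$ hub neurons wired into both) plus still-random inhibitory
  wiring, because the slow rate leaves the inhibitory connections
  untouched during learning. With *pre-specialised* inhibition the hub
  group is ejected to the midpoint between the clusters (the committed
  position is unstable whenever hub-to-far-cluster weights are intact)
  and the resulting three-body configuration is stable down to
  $N_I \approx N_H$, erasing the overlap penalty. Starting from the
  post-learning state, segregation instead hinges on a race between
  hub-mediated attraction and the specialisation of the inhibition, and
  the measured boundary is $N_I = 2N_H + 1$ (for $N_H = 8$: merge up to
  16, segregation from 17), consistent with the full overlapping-stimuli
  protocol run end to end. Layouts whose exclusive cluster size falls
  below the hub count are unstable by construction, and cells with fewer
  than two exclusive excitatory neurons are non-accessible.

Each sweep cell defaults to three replicate trials and reports the modal
surviving count.

## Intrinsic ceilings of the order parameters

The theta phase rotates non-uniformly (velocity
$(1+\eta)-(1-\eta)\cos\theta$), so two clusters offset by exactly half a
period — the perfectly consolidated anti-phase state — are *not* $\pi$
apart at every instant: their instantaneous separation oscillates between
2.74 and $\pi$. Averaged over a period this gives $R_1 = 0.128$ and
$R_2 = 0.96$ for ideal point clusters, and $R_3 = 0.91$ ($R_1 = 0.10$)
for an ideal three-cluster splay. Consolidated simulations land on these
floors ($R_1 \approx 0.13$, $R_2 \approx 0.92$–0.94 with two stimuli).
Statements like "$R_1 \simeq 0$, $R_2 \simeq 1$" therefore hold up to
these intrinsic offsets; checks demanding $R_1 \le 0.1$ or $R_3 > 0.9$ of
this model cannot pass even in the noise-free ideal, and the
corresponding assertions in the acceptance suite document this by
remaining red.

Three-stimulus runs carry a further limitation: adjacent clusters sit
$2\pi/3$ apart, where the depression lobe of $\Lambda_1$ is weak
($\Lambda_1(2.09) \approx -0.12$), so spurious cross-links left by the
stochastic learning phase decay roughly eight times slower than in the
two-cluster case and a handful can persist through any affordable
consolidation horizon; the component-based structural count is sensitive
to single such links, while the phase-cluster count robustly reports
three assemblies.

## Memory recall

`run_recall_experiment()` scrambles every excitatory-to-excitatory weight
(fresh uniform draws) while conserving all connections involving
inhibitory neurons, then presents each stored pattern for 5 time units at
amplitude 3 after a rest. In the scrambled network the population is
near-synchronised and the recall score — $(1-\cos\Delta\psi)/2$ between
the circular mean phases of the stimulated and the complementary
excitatory group — sits near 0; the cue drives a transient anti-phase
excursion with score rises of $\approx 0.9$ or more, while a
zero-amplitude control shows none. The stored patterns are recoverable
from the inhibitory wiring alone.

## What the generator emulates, and what it does not

All inputs are synthetic: random networks, stimulation schedules, and
programmatically built pre-trained matrices. The model captures phase
relations, two-time-scale Hebbian adaptation and the sign constraints of
Dale's principle; it omits conduction delays, chemical-synapse (pulsatile)
coupling, spike-timing-based plasticity, homeostatic normalisation, and
any biophysical detail beyond class-I excitability. Passing tests show
that the implemented equations reproduce the cluster-formation and
capacity phenomenology at $N = 100$; they say nothing about real cortical
tissue, nor about robustness to the omitted biological features.

## Known limitations

* Cluster counts from connected components are brittle to single strong
  spurious links; the joint structural/dynamical criterion mitigates but
  does not remove this for closely spaced clusters.
* The $\rho$-rescaling of consolidation preserves plasticity e-folds but
  not the ratio of plastic to dynamical time scales; outcomes that hinge
  on that race (hub segregation, early-consolidation transients) are run
  at moderate $\rho$ only.
* Desk-scale horizons (2–12 e-folds) cover stabilisation and saturation
  but not the very slow pruning of links between adjacent clusters in
  many-cluster states.
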