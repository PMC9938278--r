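---
title: "The sacwaves model: starburst amacrine cell bursting, TREK1 afterhyperpolarization and cholinergic retinal waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sacwaves model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacwaves)
```

## The biological problem

Before the retina responds to light, starburst amacrine cells (SACs)
generate stage II cholinergic retinal waves: spontaneous depolarizations
that sweep across the developing retina and instruct the refinement of
retinofugal projections. Three features of SAC physiology shape these
waves: (i) each cell bursts spontaneously, driven by channel noise;
(ii) each burst is followed by a slow afterhyperpolarization (sAHP)
lasting tens of seconds, here modelled as calcium-driven cAMP decay that
disinhibits TREK1 two-pore potassium channels; and (iii) SACs release
both acetylcholine (excitatory, wave-propagating) and GABA (in early
development depolarizing, later hyperpolarizing and wave-limiting).

`sacwaves` implements a single-cell stochastic conductance model of this
system, couples it on a 2D lattice through anisotropic transmitter
diffusion, and ships the quantification stack used to summarize such
simulations: spike detection, max-interval burst sorting, 3D wave
segmentation and a parameter-sensitivity sweep.

## The single-cell model

Each cell carries ten dynamical quantities. The membrane equation is a
Morris–Lecar-type conductance sum extended with Hodgkin–Huxley sodium
gating, a TREK1 potassium current, receptor currents and noise:

$$C_m \frac{dV}{dt} = I_{leak} + I_{Ca} + I_K + I_{TREK} + I_{Na}
  + I_{ACh} + I_{GABA} + I_{noise} + I_{app},$$

with every current of the form $I_n = -g_n R (V - E_n)$, $R$ the gating
fraction. Calcium activation is instantaneous,
$M_\infty(V) = \tfrac12(1 + \tanh((V - V_1)/V_2))$; the potassium gate
$N$ relaxes towards $N_\infty(V)$ at a voltage-dependent rate
$\Lambda(V) = \cosh((V - V_3)/(2V_4))$ over $\tau_N = 5$ ms. Sodium
activation/inactivation follow the classic rate functions shifted to
half points at $-40/-65/-35$ mV.

The sAHP cascade is a three-stage low-pass chain. Depolarization drives
calcium,
$\tau_C \dot C = C_0 + \delta I_{Ca} - \lambda C$;
calcium drives the cAMP-decay variable through a fourth-order law,
$\tau_A \dot A = \alpha C^4 (1 - A) - A$ (four calcium ions per
effective cAMP-degradation event); and $A$ gates TREK1 activation,
$\tau_B \dot B = \beta A^4 (1 - B) - B$ (four cAMP per two PKA, two PKA
per TREK1 dephosphorylation). The resulting current
$I_{TREK} = -g_{TREK} B (V - E_K)$ holds the cell hyperpolarized for
15–30 s after each burst, setting the interburst interval.

Release of ACh ($E$) and GABA ($I$) follows the voltage sigmoid
$\Phi(V) = (1 + e^{-V_s (V - V_0)})^{-1}$ with midpoint $-40$ mV; pools
decay with $\tau_{ACh} = 540$ ms and $\tau_{GABA} = 1000$ ms and act
back on the membrane through second-order Hill receptor activation
$\bar H(T) = T^2/(T^2 + K_d)$ with $K_d = 0.1$ treated as the squared
half-activation concentration.

### Noise

Spontaneous bursting is driven by an Ornstein–Uhlenbeck process: the
state $W$ obeys $dW = -(W/\tau_W)\,dt + dB_t$, integrated with its exact
discretisation so the step size never distorts the stationary law
(mean 0, variance $\tau_W/2$). The parameter `sigma` is the *stationary
amplitude of the noise current in pA*: the current injected is
$\sigma W / \sqrt{\tau_W/2}$. We adopt this convention because the
reference value $\sigma = 5$ pA carries units of current, and because
interpreting it instead as a raw gain on $W$ would produce a ~112 pA-SD
current that drives the membrane tens of millivolts outside its
physiological range and abolishes bursting altogether. With the default
$\tau_W = 1000$ ms the noise current has a 5 pA SD and a 1 s correlation
time; suprathreshold excursions (above the ~4.1 pA spiking threshold)
are a minority of the distribution, so bursts initiate sporadically
rather than tonically.

## Excitability analysis

With the slow and synaptic conductances removed
($g_{TREK} = g_{ACh} = g_{GABA} = 0$) the fast $(V, N)$ subsystem has,
at rest, three equilibria: a stable node (the resting state), a saddle,
and an unstable focus around which the spiking limit cycle orbits.
`find_equilibria()` exploits that $\dot N = 0$ forces $N = N_\infty(V)$,
reducing root finding to the one-dimensional steady-state I–V curve
(dense multi-start scan plus bracketed polishing; Jacobian eigenvalues
classify each root). `saddle_node_current()` bisects on the presence of
the node/saddle pair; with the default parameters the fold sits at

```{r isn}
saddle_node_current(sac_parameters())
```

i.e. a threshold current of about 4.08 pA at −56.6 mV. The sodium
current is excluded from the reduced scan by default (it accelerates
depolarization but does not move the fold); `include_na = TRUE` adds a
quasi-steady approximation.

Two notes on conventions adopted here. The gating sigmoid is the
standard Morris–Lecar $\tfrac12(1+\tanh)$ form — a bare
$\tfrac12\tanh$ would take negative values and hence negative
conductances. And $V_1, V_3$ are the half-activation voltages while
$V_2, V_4$ are slope factors, which is what the magnitudes of the
default values imply.

## Lattice coupling and anisotropic diffusion

On an `nx` × `ny` lattice every cell integrates the same equations with
an independent noise stream (one RNG stream per cell, derived from the
master seed and the cell index, so results do not depend on iteration
order). The transmitter pools become shared fields. Diffusion uses a
flux-form biased 5-point stencil: a cell sends mass upward at rate
$D\,dY_U$, downward at $D\,dY_D$, and so on, and receives exactly what
its neighbours send toward it. This conserves mass for *any*
nonnegative weights, reduces to the standard Laplacian in the isotropic
case, and with the GABA default $dY_i = \{1.9, 0.1\}$ transports GABA
preferentially toward +y, producing the asymmetric inhibition tail that
biases wave direction. Boundaries are no-flux: waves terminate at the
edge rather than wrapping, which is the physically sensible choice for
a retina patch.

The diffusion rate constants $D_e = D_i = 0.005$ are applied directly
in the field equation, $\dot E = D_e \nabla^2 E + (\rho_e \Phi(V) - E)/\tau_{ACh}$,
i.e. as a rate in ms$^{-1}$ on the cell-spacing grid. Scaling the
diffusion term by $\tau_{ACh}$ as well (the alternative reading of the
printed equations) would give a neighbour coupling three orders of
magnitude too weak for any wave to propagate — the steady-state ACh one
cell away from a bursting source would activate a ~0.1 pA current,
far below the 4.1 pA threshold — so that reading is rejected on
dynamical grounds.

Time stepping is operator-split: per dt (default 0.05 ms), an
Euler–Maruyama reaction step for every cell (with the exact OU substep),
then a Crank–Nicolson diffusion substep for each field. The implicit
half of Crank–Nicolson is solved by fixed-point iteration; because the
per-step diffusion number $D\,dt \approx 2.5\times10^{-4}$ is tiny,
three sweeps reach machine precision (the test suite verifies agreement
with an exact dense solve). Guards: gating fractions are clamped to
$[0,1]$ and concentrations to $\ge 0$; a non-finite state aborts with
the offending time.

Fixed-step integration replaces an adaptive stochastic solver; the
step-halving tests (deterministic spikelet counts at dt and dt/2 agree
within 10%, stochastic burst statistics within Monte-Carlo error)
justify the default dt = 0.05 ms.

## The quantification stack

* **Spike detection** thresholds each trace at its mean + 4 SD and turns
  maximal supra-threshold runs into spikes; a spike's end is one sample
  past its last supra-threshold sample, so a single-sample spike has
  duration equal to the sampling interval (1 ms default). The threshold
  is affine-equivariant, so spike timestamps are invariant under gain or
  offset changes. Note the detector is designed for sparse bursting
  traces: for a dense 50%-duty oscillation the threshold exceeds the
  trace maximum and no spikes are reported.
* **Max-interval burst sorting** opens a burst at a spike whose
  following inter-spike interval is below `ISI_start` (500 ms), extends
  it while ISIs stay below `ISI_end` (500 ms), merges bursts closer than
  `IBI_min` (1 s), and discards bursts shorter than 100 ms or with fewer
  than 4 spikes. The implementation is a literal three-phase loop and is
  tested for exact agreement with an independently-written chain/merge
  oracle on thousands of random trains.
* **Wave segmentation** labels 6-connected (face-adjacent) components of
  the boolean (x, y, t) burst mask; components confined to one lattice
  site are isolated bursts, not waves. Burst masks mark *full burst
  intervals* on the 1 ms saving grid. For lattice-scale data the
  package segments directly on burst interval tables (equivalent to
  voxel labeling — tested — but without materialising the voxel array).
  Wave duration is last-minus-first time sample; area is the inclusive
  bounding-box extent (a 1-cell-wide path keeps area equal to its
  length); velocity is area per unit time, adopted because the source
  material's verbal definition is circular. A zero-duration wave
  (a single shared sample) has undefined velocity, reported `NA`.
* **Sensitivity sweep**: each scalar parameter is multiplied by 1.1
  (negative parameters grow in magnitude — chosen so that e.g. a
  stronger potassium reversal means stronger TREK hyperpolarization),
  ensembles are re-simulated with common random numbers (same seeds for
  baseline and perturbed runs, which makes zero-perturbation gradients
  exactly 0 and reduces Monte-Carlo variance), and percent changes of
  mean spike duration, burst duration and IBI are reported. Gradients
  are run on isolated cells, where the three metrics are well defined
  without wave coupling.

## What the synthetic data emulate — and what they do not

The package needs no external data: fixture generators
(`make_fixture()`) build spike trains with prescribed group/gap
structure, rectangular-pulse voltage traces, and 3D burst masks with
known component counts, each carrying its ground truth as an attribute.
These exercise every analysis branch (opening, extension, merging,
duration/count filters, single-site exclusion) but are idealised:
real SAC recordings have drifting baselines, finite rise times and
measurement noise, none of which the rectangular fixtures contain.
Passing the fixture tests therefore validates the algorithms' logic,
not their robustness to instrumentation artifacts; the model-derived
traces (noisy, with slow baseline modulation by the sAHP) are the more
realistic test bed and are used for the end-to-end checks.

## Problem sizes and numerical defaults

Reference simulations are 300 s of model time at dt = 0.05 ms with a
1 ms saving interval. The package's end-to-end checks use: 10 seeds for
the TREK1 current, a 100-cell uncoupled ensemble for the isolated-cell
statistics, 12 × 12 lattices over 120–150 s (two seeds pooled) for the
wave-regime contrasts, and 12-trial common-random-number ensembles for
the sensitivity signs — sizes chosen so the full suite runs on a single
CPU while keeping Monte-Carlo error well inside the tolerances being
asserted. The lattice default in the configuration file is 64 × 64,
the scale at which the reference wave statistics were originally
tabulated; per-cell statistics, not lattice totals, are what should be
compared across lattice sizes.

## Known limitations

* Two reference statistics are not reproduced under any reading of the
  published constants, and the package does not tune towards them: the
  trial-mean TREK1 current (the printed −23.3 pA is consistent with the
  current *during* the sAHP — our post-burst peaks are −25 to −30 pA —
  but not with a whole-trace mean at a ~30–40 s IBI, which integrates to
  single-digit pA for any parameterisation tested), and the isolated
  wave/burst ratio (chance coincidences among independently bursting
  neighbours alone produce ~0.05–0.08 under the stated full-interval
  linking rule, far above the printed 0.002).
* The sensitivity-sign pattern of the reference table for gK, gLeak and
  Cm is not recovered; the mean+4·SD threshold couples parameter changes
  to the measurement itself, and the recovered signs follow that
  coupling rather than the printed table.
* Wave recruitment on desk-scale lattices saturates at tens of cells,
  not thousands; the directional contrasts (hyperpolarizing GABA makes
  waves smaller and rarer than excitatory regimes) are reproduced, the
  absolute areas of retina-spanning waves are not.
* The A/B variables are lumped abstractions of the cAMP/PKA/TREK1
  pathway; no explicit kinase/phosphodiesterase species, and no
  temperature corrections.
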