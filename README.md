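# sacwaves

Stochastic simulation and event analysis of stage II cholinergic retinal
waves, for computational neuroscientists and retinal physiologists who
want a self-contained, reproducible model of starburst amacrine cell
(SAC) bursting and wave propagation.

During early development, before photoreceptor signalling matures, SACs
fire spontaneous bursts that propagate across the retina as waves of
depolarization, patterning the visual system's wiring. `sacwaves`
implements a conductance-based single-cell model of this behaviour and
scales it to a 2D network:

* **Fast spiking core** — a Morris–Lecar-type voltage/potassium
  oscillator, `Cm dV/dt = Σ Iₙ + I_app` with `Iₙ = −gₙ R (V − Eₙ)`,
  plus Hodgkin–Huxley sodium gating. A saddle-node bifurcation at
  I_sn ≈ 4.1 pA separates rest from spiking.
* **Slow afterhyperpolarization (sAHP)** — bursts load calcium
  (`τ_C dC/dt = C₀ + δ I_Ca − λC`); calcium degrades cAMP through a
  fourth-order law (`τ_A dA/dt = αC⁴(1−A) − A`), which dephosphorylates
  and activates TREK1 potassium channels
  (`τ_B dB/dt = βA⁴(1−B) − B`). The resulting potassium current holds
  the cell silent for tens of seconds between bursts.
* **Channel noise** — an exactly-discretised Ornstein–Uhlenbeck current
  (amplitude σ = 5 pA, correlation time 1 s) whose rare suprathreshold
  excursions trigger bursts spontaneously.
* **Network coupling** — cells release acetylcholine and GABA through a
  voltage sigmoid; the transmitter fields spread by Crank–Nicolson
  diffusion on a biased 5-point stencil (GABA is transported
  anisotropically, biasing wave direction) and act back through Hill
  receptor activation.
* **Quantification stack** — mean + 4·SD spike detection, three-phase
  max-interval burst sorting, interburst intervals, 3D (x, y, t)
  connected-component wave segmentation with duration/area/velocity,
  and a +10% parameter-gradient sensitivity sweep with common random
  numbers.

## Worked example

```r
library(sacwaves)
p <- sac_parameters()              # reference parameter set

# Excitability threshold of the reduced (V, N) subsystem
saddle_node_current(p)
#> $I_sn
#> [1] 4.08474
#> $V_sn
#> [1] -56.58691

# Five minutes of one noisy cell, then the analysis pipeline
tr <- simulate_cell(p, t_end = 300000, seed = 1)
sp <- detect_spikes(tr)
sp
#> 225 spikes (threshold -36.66 mV)
b <- max_interval_bursts(sp)
head(b, 3)
#>   start   end n_spikes
#> 1  2123  2643       14
#> 2 21643 22202       14
#> 3 38251 38747       14
round(interburst_intervals(b) / 1000, 1)   # seconds
#>  [1] 19.0 16.0 24.7  2.5 33.3  6.8 11.8 27.8 12.3 27.7 34.4 26.1 20.3 11.6
signif(trace_stats(tr), 4)
#> baseline  min_amp  max_amp
#>  -71.000  -80.750   -2.145
```

The cell rests near −71 mV, fires ~0.5 s bursts of brief spikelets that
reach −2 mV, and falls silent for tens of seconds after each burst while
the TREK1 current decays — the sAHP. Coupled lattices are run the same
way:

```r
lat <- simulate_lattice(12, 12, preset = "ach_only", t_end = 120000, seed = 7)
summarize_condition(lat)   # baseline/amplitudes, spike/burst/IBI, wave metrics
```

Presets reproduce the four comparison conditions: `no_nt` (no
neurotransmission — isolated cells), `ach_only`, `depol_gaba`
(E_Cl = −55 mV, GABA excitatory) and `hyper_gaba` (E_Cl = −65 mV, GABA
inhibitory, waves smaller and more directional).

A thin command-line front end with `simulate`, `analyze`, `bifurcate`,
`gradients` and `fixtures` subcommands is installed at
`inst/exec/sacwaves`; configuration files are YAML
(see `inst/extdata/default-config.yaml`, which spells out every model
constant).

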