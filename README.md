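# cerebstdp

Distributed spike-timing-dependent plasticity in a closed-loop spiking
cerebellar model.

The cerebellum is believed to learn motor corrections in two stages: a
fast process at the parallel fiber–Purkinje cell (PF–PC) synapses of the
cortex, and a slow consolidation plus gain-adaptation process at the
excitatory (mossy fiber, MF–DCN) and inhibitory (Purkinje, PC–DCN)
afferents of the deep cerebellar nuclei.  `cerebstdp` implements a
mechanistic spiking model of this scheme — leaky integrate-and-fire
neurons with conductance synapses on a 2 ms clock, a granular-layer
state generator, probabilistic climbing-fiber error coding capped at
10 Hz, and three interacting STDP rules — and embeds it in the two
closed-loop benchmarks used to study it: one-dimensional set-point
tracking and feed-forward torque correction of a simulated three-link
arm carrying a 6 kg payload.  It is aimed at computational
neuroscientists and adaptive-control researchers who want a compact,
fully inspectable testbed for distributed cerebellar learning.

## The learning rules

With `x` a dimensionless lag and all weights non-negative conductances:

* **PF–PC** — eligibility-trace depression on each climbing-fiber spike,
  `k(x) = e^{-x} sin(x)^{20}` summed over buffered parallel-fiber spikes
  with `x = (t_CF − t_PF)/τ_LTD`, plus a fixed potentiation `α` per
  parallel-fiber spike.  `τ_LTD = delay / arctan(20)` places peak
  depression on activity one sensorimotor delay (100 ms) before the
  teaching spike.
* **MF–DCN** — depression on each Purkinje spike,
  `k(x) = e^{-|xβ|} cos(x)^2` over mossy spikes on both sides of it,
  plus fixed potentiation per mossy spike: an activity-dependent gain
  controller and the consolidation pathway.
* **PC–DCN** — inhibitory STDP, either the classical Hebbian pair
  (`+e^{-Δt/τ₁}` for pre-before-post, `−e^{-Δt/τ₂}` otherwise) or the
  symmetric rule `LTP_max e^{-|u|} cos(u)^2 − LTD_max` per presynaptic
  spike.

## A worked example

Learning consolidation in the set-point task (Case A): plasticity at
PF–PC and MF–DCN with the inhibitory weights fixed at their calibrated
value, 2500 presentations of the twin-Gaussian reference.

```r
library(cerebstdp)
net <- build_network(case_config("A", pcdcn_init_mode = "fixed"))
run <- run_case_a(n_trials = 2500, seed = 1, net = net, freeze = "pcdcn")
print(run)
#> <cereb_run> case A - 2500 trials
#>   MAE: trial 1 = 0.3543 ; final = 0.08494
counter_phase_score(weight_profile(run$net, "pfpc", 0),
                    weight_profile(run$net, "mfdcn", 0))
#> [1] -0.9360071
error_reduction_pct(run$log$mae, 1, 2301:2500)
#> [1] 76.09915
```

The per-trial mean absolute tracking error collapses from 0.354 (the
open-loop value, equal to the mean magnitude of the reference) to about
0.085 — a 76 % reduction — and the weight pattern carved into the
PF–PC synapses appears in counter phase at the MF–DCN synapses
(correlation −0.94): the cortical memory has been consolidated into the
nuclear afferents.  `run$log` holds the full per-trial record (MAE,
per-microcomplex averaged gains, climbing-fiber counts);
`run$final` holds the last trial's spike rasters and decoded output.

`run_case_b()` runs the loaded-arm benchmark the same way;
`inst/scripts/cerebstdp-run.R` wraps both runners and the analysis
helpers for shell use.

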