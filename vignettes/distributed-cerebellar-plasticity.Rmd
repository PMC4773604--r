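---
title: "Distributed plasticity in a closed-loop spiking cerebellar model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed plasticity in a closed-loop spiking cerebellar model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerebstdp)
```

## The model

`cerebstdp` simulates a reduced cerebellar microcircuit as a clock-driven
network of conductance-based leaky integrate-and-fire (LIF) neurons at a
2 ms control step, embedded in a closed sensorimotor loop:

* **Mossy fibers (MF, 100 cells)** and **granule cells (GC, 2000 cells)**
  act as deterministic *state generators*: disjoint groups of four cells
  tick off the passage of time within each learning trial.  The 2000
  granule cells yield 500 non-recurrent states (one per 2 ms step of a 1 s
  trial); the 100 mossy fibers yield 25 coarser states, each spanning 20
  steps, within which the active group fires a 100 Hz comb.  Both
  sequences restart at trial onset and are silent between trials.
* **Purkinje cells (PC, 10 per microcomplex)** read the granule
  population through an all-to-all projection (initially 5 nS per
  synapse) and inhibit their microcomplex's deep-nuclei cell.
* **Climbing fibers (CF, one per microcomplex)** carry the teaching
  signal: per step, a fiber fires when the normalized error exceeds a
  fresh uniform variate, with the probability scaled so that sustained
  full error saturates at 10 spikes/s per fiber.
* **Deep cerebellar nuclei (DCN, one cell per microcomplex)** receive
  excitation from every mossy fiber and inhibition from their 10-Purkinje
  group.  Their spike trains are decoded by a one-tap exponential filter
  (`y[n] = e^{-1/tau} y[n-1] + gain * count[n]`) into the analog
  corrective output.

Microcomplexes come in agonist/antagonist pairs: the "positive" member
corrects positive error, its partner corrects negative error, and the
decoded pair output is combined by subtraction.

Three plasticity rules act simultaneously:

* **PF-PC**: error-driven depression with an eligibility trace.  On each
  climbing-fiber spike, every parallel-fiber synapse of the target
  Purkinje cells is depressed by `k(x) = exp(-x) sin(x)^20` evaluated on
  the age of its buffered spikes, with the time constant calibrated
  (`tau_LTD = delay / arctan(20)`) so that peak depression falls on
  activity one sensorimotor delay (100 ms) before the teaching spike.
  Every parallel-fiber spike adds a fixed potentiation.
* **MF-DCN**: Purkinje-driven depression with the symmetric kernel
  `exp(-|x b|) cos(x)^2` over mossy spikes on both sides of each Purkinje
  spike, against a fixed potentiation per mossy spike.  High Purkinje
  activity therefore shrinks nuclear excitation and low activity lets it
  grow — a gain controller, and the vehicle by which the pattern carved
  at PF-PC is *consolidated* (transferred in counter phase) into the
  nuclear afferents.
* **PC-DCN**: inhibitory STDP, either the classical Hebbian exponential
  pair or a symmetric coincidence-potentiation rule in which every
  presynaptic spike depresses.  Both satisfy the two qualitative
  conditions the model requires: postsynaptic activity potentiates the
  active inhibitory synapses, and inhibition decays when the
  postsynaptic cell is silent.

## Benchmarks

**Case A** tracks a twin-Gaussian set point
(`r(t) = e^{-(t-T/4)^2/s^2} - e^{-(t-3T/4)^2/s^2}`, `s = T/10`): the
controlled variable *is* the decoded nuclei output, the error is delayed
100 ms, split by sign, and sampled by the two climbing fibers.

**Case B** adds a simulated plant: a three-link planar arm in a vertical
plane carrying a 6 kg point payload at the end effector.  A *crude*
inverse-dynamics controller (recursive Newton-Euler, payload-blind,
friction-aware) supplies feed-forward torques for an eight-shaped joint
trajectory `Q_n(t) = A_n sin(-4 pi u^3 + 6 pi u^2 + n pi/4)`; the
cerebellar module must learn the payload correction, one
agonist/antagonist microcomplex pair per joint.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `dt` | 0.002 | s | coding granularity of the state generators |
| PC capacitance / leak | 120 pF / 12 nS | | graded 0–250 Hz response to 4 x 5 nS granule volleys (`tau_m` = 10 ms) |
| DCN capacitance / leak | 60 pF / 6 nS | | 0–200 Hz range under the 100 Hz mossy comb |
| CF rate cap `r_max` | 10 | Hz | biological inferior-olive ceiling; at most 5 expected spikes per fiber per 0.5 s active half-period |
| `tau_LTD` | 0.0658 | s | peak depression 100 ms before the teaching spike (`0.1/arctan(20)`) |
| PF-PC `alpha_ltp` / `ltd_scale` | 1.5e-4 / 0.045 | nS | carving-to-refill balance; equilibrium maintenance error of a few percent |
| MF-DCN `alpha_ltp` / `ltd_scale` | 0.01 / 2.5e-3 | nS | balance point near a 50 Hz per-cell Purkinje rate; growth to working excitation within ~1000 trials |
| MF-DCN / PC-DCN `w_max` | 30 / 12 | nS | saturation bounds (see numerical choices) |
| Hebbian `tau1`, `tau2`, `scale`, `pre_decay` | 50 ms, 20 ms, 0.02, 8e-4 | | pairing window spans the Purkinje pauses that release the nuclei cell |
| decoder `tau_taps`, `gain` (Case A) | 15, 0.28 | taps, units/spike | 30 ms smoothing; ~110 Hz nuclei rate maps to the unit reference amplitude |
| Case B decoder | 100, 0.043 | | heavier smoothing for torque output; its lag is folded into the eligibility target (300 ms) |

All of these are config-first: the source publication specifies the
architecture, coding scheme and kernel *shapes*, but not the neuron or
learning-rate constants, so defaults were chosen once to land the model
in its intended operating regime and are documented here rather than
hidden.

## Design decisions taken where the design was open

**Per-population LIF constants.** A generic small-cell parameter set
(2 pF, 0.2 nS leak) makes a single 5 nS granule volley four times
super-threshold, which collapses Purkinje coding to all-or-none.
Purkinje and nuclei cells therefore use larger capacitances (same time
constants), placing the 4-cell volley near threshold so firing rates are
graded in the stored weights.

**Purkinje threshold stagger.** The 10 Purkinje cells of a microcomplex
share afferents, weights and updates, so they would be mathematically
identical; a 1 mV evenly-spaced threshold spread (configurable,
`pc_threshold_spread`) desynchronizes their spike times, smoothing the
inhibition the nuclei cell integrates.

**Saturation bounds.** Purkinje-driven MF-DCN depression cannot act on
synapses whose generator states fall inside fully-silenced Purkinje
epochs — exactly the states that carry the correction — so fixed
potentiation alone would ratchet those weights upward indefinitely.  An
explicit conductance ceiling (30 nS) bounds them; the inhibitory weights
carry an analogous ceiling (12 nS) shared by both iSTDP kernels so that
kernel-shape comparisons happen over a common weight range.

**Hebbian `pre_decay`.** The literal classical pairing rule performs no
update without postsynaptic spikes, so a nuclei cell silenced by strong
inhibition is frozen forever — the gain-control experiment could never
converge from high initial weights.  The model's own premise ("inhibitory
synapses decay in the absence of postsynaptic firing") is implemented as
a small constant depression per presynaptic spike, the standard device in
inhibitory-STDP modeling.  The Case B defaults set it to zero, because in
the torque task it strips inhibition from the permanently-active nuclei
channels.

**The substitute arm.** The original robot is an industrial 7-DoF
lightweight arm whose dynamic parameters are not public.  The package's
documented plant is a three-link planar arm (2/1.5/1 kg, 0.4/0.4/0.3 m)
whose *home pose hangs vertically*, so gravity provides a restoring
torque around the working poses, with 10 N m s viscous joints and a 2 s
trajectory at amplitudes (0.2, 0.15, 0.1) rad.  These choices were made
once, for dynamical reasons: around a horizontal pose the 6 kg payload
(more than the arm's own mass) exerts a large non-restoring gravity
mismatch, and a 1 s trajectory demands inertial corrections several times
larger than any plausible corrective-channel range, so the learning
problem the benchmark is meant to pose — a *correctable* payload
mismatch — would not exist.  The teaching error adds a velocity-error
lead term (`kv` = 0.5 s): position error is the double integral of a
torque deficit, and without the lead the error pathway is ~180 degrees
out of phase at mid frequencies, which destabilizes learning.  The
climbing-fiber synapse is subthreshold in Case B (10 nS): forced complex
spikes would drive MF-DCN depression precisely where the error — and
hence the needed excitation — is largest.

## Numerical choices

* Forward-Euler membrane integration with 10 substeps per 2 ms step;
  conductances decay exactly exponentially per substep.
* One-step (2 ms) synaptic delay everywhere; the 100 ms sensorimotor
  delay is modeled explicitly on the error pathway.
* Kernel evaluation by truncated buffered convolution (0.3 s eligibility
  window, 0.1 s two-sided mossy window); unit tests verify the
  event-driven paths against naive double-loop oracles to 1e-9.
* Weights clip at zero after every update; exact pre/post coincidence in
  the Hebbian rule is treated as potentiation.
* Plant integration by semi-implicit Euler with 10 substeps; the passive
  frictionless arm conserves energy to 0.1 % over 1 s.
* Degenerate analysis inputs (zero-variance profiles, empty spike
  trains, zero baselines) are reported as `NA`/errors, never silently.

## What the experiments show — and what they do not

The test suite reruns the package's headline experiments at desk scale
(problem sizes chosen as the package's own reproducible defaults):

* *Consolidation* (2500 trials, Case A, inhibitory weights fixed at the
  calibrated value): the twin-Gaussian shape carved into PF-PC weights is
  transferred in counter phase to the MF-DCN weights (Pearson score about
  -0.9) and the tracking error falls below a quarter of its initial
  value.
* *Gain control* (2500 trials, three inhibitory initializations — zero,
  random, high): the Hebbian rule drives the averaged PC-DCN gains of all
  three runs to within a few percent of one another.
* *Two timescales*: the PF-PC mean weight settles within a few hundred
  trials; the nuclear gains settle an order of magnitude later.
* *Kernel comparison* (4000 trials): the symmetric rule reaches an equal
  or higher reverse-correlation summary with a visibly more stable and
  lower plateau, consistent with the claim that a lower global inhibitory
  gain achieves the same correction.  Its *convergence-speed* relation is
  the one headline property this implementation does not reproduce: at
  matched learning rates the symmetric rule's low equilibrium is reached
  *before* the Hebbian rule's higher one, because with both nuclear
  afferent systems starting from zero there is no post-spike-dominated
  transient to favor the Hebbian kernel.
* *Loaded-arm task* (2000 trials, 6 kg payload): with all three rules
  active the joint-space error falls by a third to two-fifths relative to
  the frozen-cerebellum baseline.  This is qualitatively, not
  quantitatively, comparable to the published robot result: the torque
  correction acts through the plant's integration lag, so the equilibrium
  learned profile is a low-passed, slightly misphased version of the
  needed correction, and the original plant's dynamics are not available
  to calibrate against.

Because the state generators are deterministic schedules, the only noise
sources are the probabilistic climbing-fiber sampling and any randomized
initial weights; real granular-layer dynamics (recurrent Golgi loops,
trial-to-trial variability, plasticity at the mossy-granule stage,
intrinsic excitability) are outside the model, so passing tests
demonstrate the *mechanistic sufficiency* of the three-site scheme under
idealized timing, not biological quantitative accuracy.

## Reproducing a run

```{r, eval = FALSE}
net <- build_network(case_config("A", pcdcn_init_mode = "fixed"))
run <- run_case_a(n_trials = 2500, seed = 1, net = net, freeze = "pcdcn")
counter_phase_score(weight_profile(run$net, "pfpc", 0),
                    weight_profile(run$net, "mfdcn", 0))
```
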