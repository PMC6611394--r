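---
title: "Methods: a spiking timing circuit for the synchronization-continuation tapping task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spiking timing circuit for the synchronization-continuation tapping task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its model: the equations,
the circuit mechanisms, every tunable parameter that matters, the
numerical conventions, and the design choices that were genuinely open.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The task and the quantities of interest

In the synchronization-continuation tapping task (SCT) a subject taps
with a metronome at a fixed interval $T$ (here 400, 500 or 600 ms) and
then continues tapping at that interval without the metronome. The
simulator runs this protocol end to end (default: 4 metronome stimuli,
then 4 self-initiated taps, 5 training sessions) and produces tap-time
logs, spike rasters and drift-rate trajectories. The quantities of
interest are the produced tap-to-tap intervals, their convergence to
$T$ across sessions, the firing-rate phenotypes of the four ramp-cell
classes, and the variability of produced durations across repetitions
(scalar property).

## 2. Single-cell models

Spiking cells use the two-variable quadratic integrate-and-reset model
with $dV/dt = 0.04V^2 + 5V + 140 - u + I$, $du/dt = a(bV - u)$ and the
reset $V \le c$, $u \le u + d$ once $V \ge 30$. Two presets exist:
regular-spiking $(0.02, 0.2, -65, 8)$ for pyramidal cells and
fast-spiking $(0.1, 0.2, -65, 2)$ for interneurons; under equal
sustained drive the fast-spiking preset fires several times faster
(asserted in the tests). Both share the resting point $(-70, -14)$, the
more negative root of $0.04V^2 + (5-b)V + 140 = 0$ with $u = bV$.

The relative-timing readout is a rate cell,
$\gamma_m \dot V_i = -V_i + I_{ext,i} + \sum_j L_{ij} V_j$, clipped at
zero because the activity variable stands for a firing rate. Clipping is
the only nonlinearity added to the printed equation.

**Numerical conventions.** Forward Euler with a single full step,
default $dt = 1$ ms (configurable down to 0.01 ms). Both derivatives are
evaluated at the pre-step state; the spike test applies to the advanced
$V$; the recorded spike time is the end of that step. The arithmetic
order is part of the contract (`0.04*v*v + 5*v + 140 - u + I`,
left-to-right), and the test suite holds the implementation to an
independently coded reference loop spike-for-spike, including under
time-varying input. Non-finite states or inputs raise errors naming the
blow-up rather than propagating NaNs. Because the integrator is first
order, the rate-cell convergence test against the analytic exponential
uses a tolerance of $2\times10^{-4}$ at $dt = 0.01$ ms — the method's
accuracy, not round-off.

## 3. The learning rule

The drift-diffusion learner accumulates a semaphore
$\varphi(t) = \varphi(t-1) + w\,\Delta t + \epsilon(t)$,
$\epsilon \sim N(0, \sigma^2)$, from 0 at interval start toward a
ceiling (1 in the abstract model). At each reward — the next metronome
beat — the drift rate is corrected:

* reward early ($\varphi < 1$): $\Delta w = w(1-\varphi)\varphi$,
  committed immediately;
* expectation early: from the ceiling crossing until the reward,
  $\Delta w \leftarrow \Delta w - (w + \Delta w)^2 \Delta t$ accrues
  once per integration step (we read the printed $\Delta t$ as the
  simulation step);

then $w \leftarrow w + \alpha\,\Delta w$. The late-case recursion is the
Euler form of $\dot x = -x^2$ for $x = w + \Delta w$: $1/x$ grows by the
elapsed overshoot, so with $\alpha = 1$ a single overshot trial lands
almost exactly on the reciprocal of the observed interval. The
noise-free fixed point is $w^* = 1/T$; committed rates are floored at
$10^{-6}$ per ms (a dead learner can never time anything), with a
warning when the floor binds.

Near the fixed point the early-reward map
$\varphi \leftarrow \varphi(1 + \alpha(1-\varphi)\varphi)$ contracts at
rate $\approx 1-\alpha$, but far from it progress is slow (for
$\varphi_0 = 0.5$, $\alpha = 0.1$ the iterate needs ~55 reward cycles to
reach $|wT - 1| < 0.01$). The package's unit tests therefore allot a
cycle budget proportional to $1/\alpha$.

**Learning rate.** The package default is $\alpha = 0.25$. In the
abstract model any $\alpha \in (0, 1]$ converges; in the circuit the
crossing-time-versus-drift-rate map is affine with an offset (Section
5), so the rule's corrections — sized for exact proportionality —
under-correct, and small $\alpha$ needs many sessions to traverse a 20%
interval change. $\alpha = 0.25$ reaches all three targets within five
sessions without oscillation; this is a deliberate package choice and a
single config field (`alpha`).

## 4. Circuit mechanisms

**Absolute-timing microcircuits.** Each of the five groups is one
regular-spiking pyramidal cell plus one fast-spiking interneuron
(replicable $k$-fold via `n_replicates`, with trace increments scaled by
$1/k$). A synchronizing pulse (100 ms, amplitude 10) starts the cycle;
the pyramidal cell then sustains itself through a fast spike trace with
a *saturating* current, $I_{EE} = \min(w_{EE}\,e(t), \text{cap})$.
The cap (per-group 14…10, i.e. plateau rates that decrease with span)
is essential: unbounded linear self-excitation diverges under this
neuron model. The interneuron integrates the pyramidal spike count on a
slow trace ($\tau_q = 2$ s) and, when its drive crosses the fast-spiking
rheobase, shuts the pyramidal cell down with strong inhibition
($w_{IE} = 20$, $\tau = 15$ ms). The group's up-down span is therefore
set by the pyramidal→interneuron gain; `calibrate_spans()` bisects each
gain deterministically against span targets (defaults 90/155/220/285/350
ms; realized spans are quantized by spike times to roughly 65/91/215/230/362
ms, strictly ordered). All spans are kept *below the shortest target
interval* so that every group completes its cycle and is quiescent again
before the next tap: this is what makes the spans independent of the
target interval and every produced interval dynamically identical.

**Synchronizing pulse = the tap.** The groups are restarted (membrane
state to rest, traces zeroed, pulse delivered) by the *tap* in both
phases: the motor efference is the internal synchronizing signal. During
synchronization the stimulus reaches the motor cell through the
input-cell pathway and the tap follows stimulus onset by ~23 ms
(conduction delay 20 ms plus spike latency). Aligning the restart to the
tap, rather than the stimulus onset, makes the synchronization and
continuation cycles identical; the alternative leaves a constant
~25 ms asymmetry between the phase in which $w$ is tuned and the phase
in which intervals are produced, i.e. a systematic production bias.

**Relative-timing readout.** The pooled synaptic trace of all absolute
pyramidal spikes, $P(t)$ (increment 1 per spike, $\tau_p = 10$ s,
shunted at resets), drives the rate cell through the plastic weight
$W$. The cell carries a unit self-connection $L_{ii} = 1$ — the
standard line-attractor integrator motif — so its leak cancels and
$\gamma_m \dot V = W\,P(t)$: the activity is proportional to the running
integral $A(t) = \int P$. Requiring the ramp to realize the drift
$\theta\,w$ (in Hz/ms, $\theta = 20$ Hz the threshold standing in for
the ceiling) against the calibrated mean trace gives the linear map
$W(w) = \gamma_m\,\theta\,w / \bar P$ with
$\bar P = A(T_{cal})/T_{cal}$ measured by `calibrate_coupling()` on a
single noise-free cycle of the absolute layer ($T_{cal} = 400$ ms),
including the post-tap shunting window so calibration and task see the
same drive. In the circuit mode, $\varphi \equiv V/\theta$, so the
printed update rules apply verbatim with ceiling 1. Because $A(t)$ is
convex early (the trace builds over the first ~200 ms) the
crossing-time map $t^*(w)$ is affine with offset rather than exactly
$1/w$; the learner absorbs the residual, and the calibration round-trip
(drift $1/400$ crosses threshold 400 ± 50 ms after the pulse, zero
noise) is asserted in the tests.

**Time accumulator and swing microcircuit.** The accumulator is a
spiking cell driven by $w_{acc} A(t)$: its rate ramps with elapsed time
at a slope independent of the target (the early $A(t)$ is identical
across targets) while its peak — reached just before the reset — grows
with the interval. Its output excites the swing pyramidal cell
($\tau = 50$ ms trace), which excites the swing interneuron (the swing
cell proper); each tap also delivers, via the resetting cell, a slowly
decaying inhibitory trace ($\tau = 250$ ms) to the swing cell. Falling
inhibition plus growing excitation produce the down-then-up rate profile
with an interior minimum inside each produced interval.

**Motor pathway, gate and resets.** Stimulus onsets and gated threshold
crossings schedule a brief suprathreshold pulse to the motor cell after
a 20 ms conduction delay; motor spikes within 100 ms coalesce into one
tap. The accident-preventing cell is implemented as its functional role:
an inhibitory gate on relative→motor that opens only in the continuation
phase and only once the interval is at least `gate_min` = 200 ms old
(half the shortest plausible target), so a spurious early crossing
cannot trigger a premature tap. Each tap pulses the resetting cell
(fast-spiking); its spikes open a 25 ms shunting window in which the
relative-timing activity, $P$ and $A$ decay with $\tau = 6$ ms (to
&lt; 2% — the "pull toward zero via inhibitory projections"), clear the
crossing flag, and kick the swing inhibition. Threshold detection is
suppressed inside the window so a decaying super-threshold activity is
not double-counted as a new crossing.

## 5. Noise model and what it emulates

The paper-level protocol is deterministic; variability enters through
two configurable sources, both derived from the master seed through two
independent streams (so disabling one does not shift the other's
draws):

* **Per-step accumulation noise** $\epsilon(t)$ with
  $\sigma = \texttt{sigma\_scale} \cdot w \sqrt{dt}$,
  `sigma_scale` = 0.01. This is the learner's own diffusion term; at
  these settings it contributes sub-millisecond timing SD.
* **Per-interval drift-gain variability**: at each reset the plastic
  drive is multiplied by $1 + \xi$, $\xi \sim N(0, \texttt{gain\_cv}^2)$,
  `gain_cv` = 0.05. Trial-to-trial gain variability is the standard
  mechanistic account of scalar timing: a gain error $\xi$ shifts the
  crossing time by $\approx -\xi\,(T - t_c)$ (with $t_c \approx 90$ ms
  the integration offset of $A(t)$), so the SD of produced durations
  grows nearly proportionally with the interval and the CV is roughly
  constant, at a realistic ~3–4% of the produced duration.

The scalar-property sweep (`run_scalar_sweep()`) runs 8 repetitions per
target with *paired* repetition seeds across the three targets (common
random numbers). The pairing leaves each target's marginal distribution
untouched but removes the $n = 8$ sampling noise of the SD estimator
from cross-target comparisons, which would otherwise dominate a
strict-ordering check.

What the simulated conditions do **not** emulate: background synaptic
bombardment (spiking cells are noise-free), metronome modality effects,
motor execution noise, reward modelling beyond "the synchronizing event
is the reward", and any fit to recorded spike trains. Passing tests
show the mechanisms are sufficient to reproduce the qualitative
phenotypes and the scalar signature under these idealized conditions,
not that the parameters are those of cortical tissue.

## 6. Protocol conventions and degenerate inputs

One session = synchronization (4 stimuli at $T$ spacing; the stimulus
drives the input cells for 100 ms) then continuation (until 4
threshold-driven taps or a timeout of $3T$ per expected tap; a timeout
with zero taps is the error "circuit failed to self-pace"). Weight
commits happen at every stimulus after the first — there is no elapsed
interval at the first beat — giving exactly
$n_\text{sync stimuli} - 1 = 3$ commits per default trial. The drift
rate persists across sessions; all dynamic state re-initializes.

Learning in the continuation phase is off by default
(`learn_in_continuation`): the update block of the protocol sits in the
synchronization branch, and its overshoot sub-case is ambiguous, so both
readings are exposed. When enabled, commits at threshold-driven taps are
no-ops by construction ($\varphi = 1$ at a tap triggered by the
crossing itself), which is itself informative about that reading.

Degenerate configurations are rejected with named errors: stimulus not
shorter than the target, fewer than two stimuli, non-increasing span
targets, spans leaving less than 50 ms quiescence before the shortest
interval (targets below ~400 ms require recalibrated spans), zero-sized
populations, out-of-range $\alpha$, negative noise scales. The
continuation-phase behavior is provably independent of
`stimulus_duration` (asserted in the tests) because the synchronizing
pulse has its own duration parameter.

## 7. Analysis conventions

Firing rates are kernel estimates (Gaussian, width = SD = 50 ms by
default; boxcar optional) on a 1 ms grid; the estimate conserves spike
count to within 1% (kernel mass is lost only at grid edges). Ramp
slopes are ordinary least squares on a stated window. Produced
durations are continuation tap-to-tap differences; the "learned
duration" of a repetition is the mean continuation interval of its
final session. Absolute-timing spans are measured per synchronizing
pulse window as first-to-last pyramidal spike, then summarized by the
median. The scalar table reports mean, SD and CV = SD/mean per target
plus a CV-spread attribute.

## 8. Problem sizes

Default experiment sizes are the protocol's own: 5 sessions per
training, 8 repetitions per target for the scalar sweep, three targets.
One training run is ~25,000 integration steps; the full scalar sweep is
~120 sessions and runs in about a minute on one CPU at $dt = 1$ ms.

## 9. Known limitations

* Population sizes default to the minimal faithful rendering (one cell
  per drawn role); `n_replicates` exists for robustness studies but the
  calibration targets assume the default.
* The span calibration is quantized by spike times: realized spans sit
  near, not on, their targets, and two middle groups are closer to each
  other (~15 ms) than the targets suggest. Ordering is deterministic
  and exact.
* Targets below ~400 ms need shorter span targets (and recalibration);
  the defaults cover the 400–600 ms experimental range.
* The late-reward decrement is exact only for the abstract model; in
  the circuit the affine crossing-time map makes both corrections
  slightly conservative, compensated by the larger default $\alpha$.
* With $\alpha = 0.1$ and a starting drift rate half the target's
  fixed point, the abstract learner needs ~55 reward cycles to reach
  $|wT - 1| < 0.01$ — a property of the printed update rule itself, not
  of the implementation.
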