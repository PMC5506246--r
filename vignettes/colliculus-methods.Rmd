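---
title: "A spiking-map model of collicular saccade commands: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking-map model of collicular saccade commands: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(colliculus)
```

## The model in one paragraph

The superior colliculus (SC) issues saccade commands from a topographic
motor map: *where* the recruited population sits encodes the desired eye
displacement, and *how* its cells fire encodes the trajectory and its
kinematics. `colliculus` implements a one-dimensional, fully
deterministic spiking model of this transformation. Two layers of 200
adaptive exponential integrate-and-fire (AdEx) neurons sit on a 5-mm map
midline. The input layer (a stand-in for the frontal eye fields, FEF)
receives a translation-invariant spatial-temporal current centred on the
afferent image of the target and relays spikes one-to-one to the SC
layer, whose cells have location-dependent biophysics and recurrent
Mexican-hat connectivity. A linear ensemble decoder sums a fixed,
site-specific minivector per SC spike to produce the eye trajectory.

## Map geometry

The afferent mapping is log-polar along the rostral-caudal axis:
`u = B_u * log((r + A)/A)` with `B_u = 1.4` mm and `A = 3` deg, so the
5-mm midline covers amplitudes from 0 to ~104 deg. The efferent mapping
is its inverse scaled by the ensemble-coding factor `kappa`: one spike
at site `u` displaces the eye by `kappa * A * (exp(u/B_u) - 1)` degrees.
The exponential magnification makes caudal movement fields broad in
degrees and rostral fields narrow — this single geometric fact carries a
large share of the model's explanatory weight.

Neurons are placed on an endpoint-inclusive uniform grid
(`u_n = 5 n / 199`, n = 0..199). The placement convention (endpoints vs.
cell centers) is not dictated by the science; endpoints make the rostral
pole and the caudal limit exactly representable, and the alternative is
available via `build_grid(convention = "center")`.

## Input drive

Each input-layer neuron receives
`I0 * exp(-(u_n - u_T)^2 / (2 sigma_pop^2)) * t^gamma * exp(-beta t)`
with `sigma_pop = 0.5` mm, `gamma = 1.8`, `beta = 0.03` and `I0 = 3` pA.
We read `t` in milliseconds, making `beta` 1/ms; the temporal factor
then peaks at `gamma/beta = 60` ms and produces input-layer bursts
lasting tens of milliseconds, the physiological regime. Because the
drive has decayed below 1% of its peak by 350 ms and all bursts complete
well before that, trials default to a 300-ms horizon (`sim_config()`
exposes it).

The drive depends on position only through `u_n - u_T`: every target
evokes the same population profile, merely shifted. All spatial
differentiation of the output therefore comes from the SC layer itself.

## Neurons and synapses

Both layers use the AdEx equations

```
C dV/dt = -g_L (V - E_L) + g_L eta exp((V - V_T)/eta) - q + I_inp
tau_q dq/dt = a (V - E_L) - q
```

with reset `V -> V_r`, `q -> q + b` at the practical threshold
`V_peak`. The input layer uses a regular-spiking preset
(`V_r = -55 < V_T = -50` mV). The SC preset is intrinsically bursting:
`V_r = -45` mV lies *above* `V_T`, so after every reset the exponential
term re-drives the cell and only the accumulated adaptation current `q`
(jump `b = 80` pA per spike, decay `tau_q`) can terminate the burst.
`tau_q` is the critical location-dependent parameter: it sets how fast
adaptation drains away and thereby the burst's duration, peak rate, and
inter-spike-interval structure.

SC synapses are conductance-based: `I_syn = g_exc (E_e - V) + g_inh
(E_i - V)` with `E_e = 0`, `E_i = -80` mV. Conductances jump instantly
by the synaptic weight on each presynaptic spike and decay exponentially
(`tau_e = 5`, `tau_i = 10` ms). The printed conductance ODE multiplies
the spike impulses by the decay constant; with the delta-function
convention used here that normalisation makes each spike add exactly its
weight, which is the reading we implement ("increase instantly by the
synaptic strength").

Lateral connectivity is a difference of Gaussians of anatomical
distance: excitation `w_exc = 160` pS over `sigma_exc = 0.4` mm,
inhibition `w_inh = 50` pS over `sigma_inh = 1.2` mm, zero diagonal. The
net short-range-positive / long-range-negative profile implements a soft
winner-take-all in which the central (most active) cell entrains the
burst shapes of its neighbours. `mexican_hat_params()` deliberately
accepts parameter sets outside the `w_exc > w_inh` hat regime — the
characterisation scans and the genetic algorithm must explore them — and
the strict regime check is applied where it belongs, when a
configuration file is loaded for a production run.

## Numerical scheme

* Forward Euler at `dt = 0.01` ms, the step size of the reference
  simulations; the scheme itself is the convention of the simulator
  family this model descends from. The test suite verifies first-order
  error contraction under refinement.
* Conductance decay uses the exact per-step factor `exp(-dt/tau)` rather
  than an Euler update — the homogeneous solution is closed-form, so
  there is no reason to discretise it.
* Spikes are delivered with a one-step (0.01 ms) delay: state update
  first, then threshold test and reset; increments from spikes land at
  the next step. This is the minimal causal convention for a recurrent
  network; the model is silent on same-step recurrence.
* The exponential argument `(V - V_T)/eta` is clamped at
  `(V_peak - V_T)/eta + 5`. Beyond the clamp the spike fires regardless,
  so the guard cannot alter spike times; it only prevents overflow.
* Initial conditions: `V = E_L`, `q = 0`, conductances 0. Rest is the
  only neutral choice; nothing in the model description pins it down.
* A per-neuron spike-count guard (default 200) aborts runs with
  unbalanced lateral weights, naming the runaway neuron: strong
  uncompensated excitation spreads activity across the whole map.

Two accuracy caveats are worth knowing. First, late spikes in a long
burst accumulate phase drift under Euler (milliseconds at `dt = 0.01`
for the ~34-spike input-layer burst); the error contracts linearly with
`dt` and count-level results are step-stable, but individual late spike
times should not be over-interpreted. Second, burst spike *counts* are
integer-valued functions of continuous parameters, and near a count
boundary the iso-count sets fragment at the sub-0.1-nS scale — see the
tuning discussion below.

## Tuning the motor-map gradient

The single-neuron brute-force grid (`brute_force_grid()`) drives an
SC-preset neuron with the spike train of the most active input-layer
cell and maps burst spike count and peak rate over
`tau_q` in [10, 80] ms x `w` in [5, 16] nS. The default resolution (36
x 45; 2 ms and 0.25 nS steps) is not prescribed by the science; it is
chosen so the 20-spike contour is sampled by >= 30 points. The pairs
yielding the 20-spike target are fitted with a least-squares quadratic
`w(tau_q)`; `assign_map_parameters()` then sets `tau_q` linearly from 80
ms (rostral) to 10 ms (caudal) and takes each neuron's feedforward
weight from the quadratic, which rolls off from ~15 nS to ~6.5 nS. The
result: every cell emits close to 20 spikes for its optimal saccade
while peak rate falls and burst duration grows from rostral to caudal.

The quadratic cannot hold the count at exactly 20 everywhere: the exact
20-spike set per `tau_q` is a fragmented union of sub-0.1-nS slivers
(a marginal tail spike appears or disappears under tiny weight changes,
with terminal inter-spike intervals of 3-15 ms, so no burst-window
criterion separates it). Re-simulating at the fitted pairs gives 20
spikes at the large majority of contour points and 19 or 21 at the
rest; in the full network the central-cell counts for optimal saccades
span 20-23, which is the level at which the model makes claims.

## Tuning the lateral weights

`tune_lateral_weights()` implements a small genetic algorithm over the
`(w_exc, w_inh)` plane (spatial ranges fixed — they are set by the
recruited-population size, not by dynamics). Ten candidates per
generation; the two best are elites; eight children are bred from
distinct parent pairs out of the top six by single-point crossover with
5% per-gene mutation; the search stops when the top two are unchanged
across successive generations. The genome is the pair's pS values
written as 4 decimal digits each — any encoding supporting single-point
crossover and per-gene mutation would do; this one is simple and
loggable. Initial candidates are uniform on [10, 500] pS squared, wide
enough to bracket every regime from no-op to runaway.

Fitness is a weighted sum of RMSEs over seven probe amplitudes
(2-35 deg): central-cell peak rates against the closed-form main-sequence
rate model `F_peak(r) = 800/sqrt(1 + 0.07 r)` spikes/s, central-cell
spike counts against 20, and burst-profile correlations of recruited
cells with the central cell against 1, weighted 0.1 / 10 / 1000 to bring
the three terms to comparable magnitudes. The probe rates span ~750 to
~430 spikes/s, so the model's rate gradient, count constancy and
population synchrony all constrain the same two weights. Because the
landscape is flat near the optimum, exact converged weights are not
reproducible quantities; what is reproducible — and what the tests check
— is determinism given a seed, monotone elite fitness, and the kinematic
optimum of the inhibitory strength (see below).

## Analysis conventions

Spike densities are unit-mass Gaussian kernel sums evaluated on a 0.5-ms
grid (finer than any kernel; the grid is not prescribed). Kernel widths
follow the use: 8 ms for peak firing rates, 5 ms for the synchrony
cross-correlations, 3 ms for burst-shape comparisons. Burst-profile
similarity is the zero-lag normalised inner product over a window from
10 ms before to 40 ms after saccade onset, with both profiles
peak-normalised first; onset is the central cell's first spike (a
single cell's profile is aligned to its own first spike). The analysis
radius is 0.65 mm around the population center, beyond which firing
vanishes; silent cells inside the radius have no profile and are
excluded from correlation summaries.

## Decoding and kinematics

`decode_trajectory()` turns SC spikes into a cumulative minivector sum —
a step function whose endpoint is exactly
`kappa * sum_n count(n) * A (exp(u_n/B_u) - 1)`, independent of spike
timing. `kappa` is not a free constant of the implementation: for any
network configuration it is calibrated so the decoded 21-deg saccade
lands exactly on target (`calibrate_kappa()`), and it is recalibrated
per configuration when configurations are compared. With 200 map
neurons the calibrated value is of order 1e-3 deg/spike; the much
smaller figure sometimes quoted for the biological map assumes the real
neural density, and only the product of density and `kappa` is
constrained.

For kinematics the step positions are linearly interpolated to a 1-ms
grid and smoothed/differentiated with a Savitzky-Golay filter (order 3).
The filter window defaults to 35 ms. This is a considered choice: the
window must be long enough to average over the spike-level staircase
*and* over sub-burst volley transients — with windows near 15 ms the
"peak velocity" of a strongly inhibited, stretched burst is set by a
<10-ms synchronized onset volley rather than by the velocity profile,
which inverts the kinematic comparison the measure exists for — while
staying well below the 50-100 ms saccade durations it must resolve.
Ratio scans are stable for windows of roughly 25-41 ms. The series is
padded with its physical rest values (fixation before the trial,
stationary eye after it) before filtering, which removes the filter's
startup transient; without the padding the velocity integral misses the
endpoint by about 2%. The saccade offset reported in `eye_trace` (first
post-peak drop below 5% of peak velocity) is a reporting convenience
only.

The peak-velocity ratio (`peak_velocity_ratio()`) — lateral connections
on versus off, each with its own calibrated `kappa`, for a 21-deg
saccade — characterises a connectivity scheme in one number: the
balanced default hat yields ratios well above 1, the optimum over
inhibitory strength sits at 50-70 pS, and overwhelming inhibition
(~300 pS at `sigma_inh = 1.2` mm) stretches the bursts until the saccade
is slower than the unconnected baseline.

## What the model does and does not emulate

Everything is deterministic: there is no input noise, no channel noise,
no trial-to-trial variability. The only randomness in the package is
the genetic algorithm's search, governed by an explicit seed. Passing
tests therefore certify the mechanism — map geometry, adaptation-driven
burst shaping, soft-WTA synchronisation, ensemble decoding — not any
statistical property of real recordings. The map is one-dimensional
(horizontal saccades only; the direction coordinate is carried in the
efferent formula but evaluated at zero); there is no oculomotor plant,
no brainstem feedback, no microstimulation or blink-perturbation
modelling, and no head movement. Those are boundaries of the modelled
system, not simplifications of it.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` use the model at its native
size (200 neurons per layer, `dt = 0.01` ms, 300-ms trials): trials cost
well under a second each, so nothing needs to be scaled down. The
standard analyses use seven optimal amplitudes spanning 3-63 deg, the
three reference populations at 5/15/25 deg, and an 8-point inhibitory-
strength scan; the genetic-algorithm tests run two generations at a
single probe amplitude with a 200-ms horizon (bursts are complete well
before 200 ms), which exercises selection, breeding and determinism
without the multi-minute cost of a converged search.
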