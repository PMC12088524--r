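---
title: "larvaCPG: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{larvaCPG: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the neuron and synapse model, the circuit motifs, the numerical scheme, the
parameter-scale calibrations the implementation required, the
event-classification conventions, and the limits of what the simulations
can show.

## The neuron model

Every neuron in the network is an identical non-spiking single compartment
(sphere, diameter 10 µm; membrane area taken as π·d²). Three channel
families carry current, each Ohmic with an instantaneous conductance
`g_x = m_x · g_x,max`:

- **Leak**: fixed, 0.35 mS cm⁻² toward −60 mV. The passive time constant
  is C_m/g_leak ≈ 2.9 ms, so the membrane follows its synaptic conductances
  almost instantaneously; all slow dynamics come from gating and calcium.
- **Voltage-gated Ca²⁺ channel**: non-inactivating, maximal density
  0.08 mS cm⁻², logistic steady-state activation with half-activation at
  −40 mV and slope 7.5 mV, first-order kinetics with τ_m = 50 ms. Its
  reversal potential is recomputed from the Nernst relation (z = 2,
  Ca_e = 2 mM, T = 294 K) every step as intracellular calcium changes.
- **Synaptic and optogenetic channels** (below).

Intracellular calcium integrates inflow against first-order clearance,

    dCa_i/dt = B_eff · max(0, −I_Ca) − (Ca_i − Ca_min)/τ_clr ,

with τ_clr = 400 ms and floor 0.1 nM; the `max(0, ·)` keeps outward current
from depleting the pool below the clearance path. Calcium has two roles:
its channel supports regenerative plateau potentials (the membrane is
bistable over a narrow band around the activation threshold, ≈ −45 mV, and
the plateau self-terminates as accumulating Ca²⁺ pulls the Nernst potential
down), and it gates graded transmitter release.

Membrane potential integrates the current balance
`C_m dV/dt = −Σ I_x + I_stim` by exponential Euler: with conductances held
over the step, V relaxes toward the conductance-weighted reversal plus
`I_stim/g_total` with time constant `C_m·area/g_total`.

Initial conditions are rest-consistent: V at the leak equilibrium, the Ca
gate at its steady state for that voltage, Ca_i at its stated initial value
(20 nM), and E_Ca from the Nernst relation. Note that the *network* resting
potential settles near −54 mV rather than −60 mV: at the stated channel
densities the Ca channel's resting activation (m∞(−60) ≈ 0.065) is strong
enough to depolarise the cell a few millivolts before a stable fixed point
is reached. "Silent at rest" therefore means: the unstimulated network
relaxes to a fixed resting state (drift < 0.5 mV) with negligible synaptic
tone, not literally V = −60 mV; the tests assert the former.

## The graded synapse

Release rate is a sigmoid of presynaptic calcium with slope 15 nM; cleft
transmitter `T` integrates release against clearance (τ_T = 250 ms); the
postsynaptic conductance control factor is the upper-half sigmoid
`m_syn = 2/(1+exp(−T/S_bind)) − 1` with S_bind = 0.5, multiplied by the
maximal density (1 mS cm⁻²), the postsynaptic area, and a per-connection
gain (1 everywhere except 2 on the inhibitory outputs of the detector
neurons). Reversals are −10 mV (excitatory) and −70 mV (inhibitory). Each
directed connection owns an independent cleft state. The exponent sign in
the receptor gate is implemented so the gate is 0 at T = 0 and saturates
toward 1, which is the only reading under which it is an "upper-half
sigmoid".

## Parameter-scale calibrations

Two nominal parameter scales had to be reconciled with the rest of the
parameter set; both are exposed as explicit unit-conversion fields with
calibrated defaults, never hidden.

**Release-rate unit (`r_unit`, default 1e-3).** The nominal maximum release
rates (80, and 20 for midline-coordination synapses) combined with
τ_T = 250 ms would put the cleft-transmitter scale at r_max·τ = 20,000,
yet the receptor gate half-activates at T ≈ 0.55 (S_bind = 0.5). The gate
would then saturate at ~10⁻⁴ of maximal release and the release midpoints
(185/200 nM Ca) could never matter. Reading the release rates as
per-second (effective 0.08 ms⁻¹) puts the transmitter scale at 20, on the
order of S_bind, so the presynaptic calcium sigmoid actually governs the
synapse's operating range. `r_unit` multiplies r_max at network-compile
time; the module-level functions keep the literal per-ms contract.

**Calcium-inflow scale (`B_scale`, default 0.012).** The nominal inflow
factor B = 1000 (mM s⁻¹ nA⁻¹ as printed) drives intracellular calcium to
millimolar levels at which every synapse saturates permanently. B is
therefore kept at its nominal value and multiplied by a conversion
`B_scale` (nM ms⁻¹ nA⁻¹ per unit B), calibrated **once** by bisection
against the two scenarios that bound it: sustained oscillation of the
single hemisegmental oscillator under tonic command drive requires
B·B_scale ≤ 13 nM ms⁻¹ nA⁻¹ (above this the excitor–inhibitor pair locks
in a depolarised equilibrium), and full-chain metachronal propagation
requires ≥ 12 (below this, relay excitation attenuates and waves die
mid-chain). The default is the intersection, B_eff = 12 nM ms⁻¹ nA⁻¹.
At this scale plateau calcium (~100–180 nM) works on the lower limb of the
release sigmoid rather than crossing its midpoint; crossing the midpoint
and oscillating are not simultaneously attainable in this implementation,
and oscillation was taken as the binding requirement.

**Release-midpoint assignment.** The two sources for the midpoints
disagree on which value (185 vs 200 nM) is excitatory. The package
defaults to excitatory = 185 nM, inhibitory = 200 nM: under the calibrated
calcium scale this is the only assignment for which both the single
oscillator and chain-wide propagation function (the converse assignment
weakens relay coupling so that forwards waves die three to four segments
up the chain at every workable B_scale). Both values are plain arguments
of `synapse_parameters()`.

## Circuits

`hemisegmental_oscillator()`: forwards excitor E_F, backwards excitor E_B,
one shared inhibitor I with reciprocal graded connections identical for
both excitors, plus command neurons C_F → E_F and C_B → E_B. The
oscillator is conditional: silent without command input, cycling at
~0.2–0.4 Hz under tonic drive, and producing a single cycle that outlasts
a brief command pulse.

`abdominal_chain()`: one oscillator per segment A1–A8; metachronal
progression by feed-forwards excitation from the active excitor to the
next segment's excitor *and* inhibitor (E_F anteriad, E_B posteriad); C_F
drives E_F in A6–A8, C_B drives E_B in A1–A2. Initiation detectors
(D_IF/D_IB) are command-driven inhibitors of the opposite program's
initiating excitors. Wave detectors (D_WF/D_WB) sum excitor activity
chain-wide and inhibit the initiating excitors at *both* chain ends (the
exact fan-out is not enumerated in the source material; this choice
reproduces the ablation phenotypes). All detector outputs carry gain 2.

`thoracic_circuit()`: bilateral T1–T3 oscillator pairs; head-sweep
commands C_HL/C_HR excite the ipsilateral E_Bs; intersegmental links run
posterior→anterior only; head-sweep detectors D_HL/D_HR are excited by
ipsilateral E_Bs and inhibit contralateral E_Bs (half-centre).

`full_model()`: the abdominal chain duplicated bilaterally with midline
excitatory coupling between counterpart excitors at the reduced release
rate (20); the thoracic circuit joined at T3↔A1; a chiasm from each A1 E_B
to the contralateral A2 E_B (excitatory, midline class); thoracic E_Fs
feeding D_WF and E_Bs feeding D_WB; and the backwards command replaced by
C_HL/C_HR, which drive both sides' D_IB. Design choices where the source
is silent: head-sweep commands fan out to all three ipsilateral thoracic
E_Bs; no forwards-command drive to thoracic segments; detectors are
duplicated per side.

## Stimulus protocols and study conditions

Poisson pulse trains deliver brief current pulses (defaults 100 ms,
0.01 nA) whose onset intervals are i.i.d. exponential with mean MSI; each
(episode, cell) pair derives an independent stream from the protocol seed,
so one cell's train is unchanged by another's. MSI-bias conditions are
written posterior:(anterior-left:anterior-right) as percentages of a base
MSI, anchored at 1 s (50 halves the interval, doubling the average drive).

Sizes used by the tests and the acceptance script (chosen for precision at
desk scale and stated here as the package's own conditions): oscillator
sweeps run 60–80 s per grid point; chain phenotype censuses run 10 min per
detector configuration; full-model event budgets run 30 simulated minutes
per condition with three seeds; the graded-disinhibition runs use 60 s
light windows inside 3-minute runs.

A note on pulse amplitude: Poisson trains at 0.01 nA recruit cycles
through calcium summation across near-coincident pulses, but a *lone*
0.01 nA, 100 ms pulse sits just below the plateau threshold in this
implementation; the single-pulse demonstration uses 0.02 nA.

## Event classification

`detect_peaks()` segments excursions above a prominence threshold
(fraction of the channel's dynamic range above baseline; channels share
the largest channel's range by default so silent channels contribute no
peaks), merges excursions closer than a refractory separation, and places
onset/offset at 20% of the rise and 80% of the fall of each peak — the
same crossings used for wave duration (initiating-segment 20% rise to
last-segment 80% fall) and event intervals (equivalent-point onsets).

`classify_events()` traces candidate waves from each initiating-segment
peak through the chain by depth-first search (earliest valid peak first,
with backtracking): peak times must be non-decreasing along the chain
within a tie tolerance, except inside the initiating group (the three most
posterior segments for forwards waves; the T3–A1 region for backwards),
which may co-peak within the near-synchrony window (`sync_window`, default
500 ms — the sources give no number, so it is an explicit parameter).
Candidates from both directions are accepted greedily in seed-time order,
and each peak belongs to at most one event. Remaining peaks are clustered
by the synchrony window: clusters confined to the posterior (anterior)
initiating group are posterior (anterior) bursts; whole-chain synchrony is
flagged separately. Waves must span the full provided chain — blocked-wave
analyses pass the intact chain explicitly.

Head sweeps are suprathreshold excursions of the left−right difference at
a thoracic segment. For ΔF/F input the biological 5% criterion applies;
for model voltages the reference scale is the larger channel's
peak-to-peak range and the default threshold is 0.5 of it, because the 5%
criterion on voltage (~2.5 mV) scores every minor asymmetry of two
independently cycling sides as a sweep. Anterior bursts that coincide with
a detected sweep are scored as the sweep (asymmetric anterior activity),
mirroring the symmetric/asymmetric split in the imaging analysis.

Same-program overlap is scored when a second same-direction wave's
initiating peak falls before the previous wave's final peak (two
concurrent waves in the same direction); opposite-program concurrency uses
the 20%-band event spans of the two programs' events. Transition matrices
row-normalise counts of consecutive event kinds; the bilateral asymmetry
profile is a Gaussian KDE of all difference-trace samples with the
rule-of-thumb bandwidth multiplied by 4.

## Numerics

Fixed-step exponential Euler at dt = 1 ms, staggered explicit scheme per
step: synapse states advance from presynaptic calcium at step start; then
per cell the gate (from V at step start), the calcium pool (from the
updated gate and the previous step's E_Ca), the Nernst potential, and
finally the membrane potential (using the updated conductances and E_Ca).
The compiled and pure-R engines implement the identical scheme and agree
to 1e-10; trajectories converge as dt shrinks, and halving dt changes the
oscillator period by under 2%. Non-finite state aborts with the step index
and cell. Calcium is floored at Ca_min; the gate is confined to [0, 1] by
construction of the exponential update. Pulse onsets are real-valued; the
delivered train is sampled onto the integration grid so that the delivered
charge is exactly amplitude·width·count when the width is a multiple of
dt.

## What passing tests do and do not show

The generator emulates the *fictive* preparation: no muscles, no sensory
feedback, no neuromodulation, no spiking — so tests exercise the network
mechanisms (conditional oscillation, metachronal relay, motif-specific
segregation, disinhibition responses), not behaviour of real larvae. Model
voltages are much faster than GCaMP calcium signals; classification
criteria are shared, but time courses are not comparable.

Known limitations, found and kept honestly:

- Under **tonic** drive, rhythmicity of the chain depends on the wave
  detectors: without D_W (or with both commands held on) the network
  settles into a stable depolarised standing pattern after the first
  wave/collision instead of cycling. The detector-ablation phenotypes are
  therefore assessed under Poisson command input, the regime the switching
  experiments use anyway, and the post-block phase-advance contrast
  compares blocked vs unblocked wave intervals under Poisson drive.
- The full model is more eventful than the biological budget: total
  fictive-event rates run ~13–17 per minute across every MSI base tested,
  versus the 2–4 per minute the original model operated at; activity
  reverberates semi-autonomously once triggered. Directional MSI-bias
  effects are nevertheless reproduced, and per-program instantaneous
  frequencies stay within the 0–0.4 Hz envelope.
- The deterministic block-sweep coupling of wave duration and cycle period
  is *cleaner* than the printed fits (R² ≈ 0.98–0.99 in both directions);
  no noise is injected to manufacture scatter.
- Silencing the hemisegmental inhibitors suppresses bursting by roughly
  80% rather than abolishing it; the residue rides on the still-intact
  detector inhibition.
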