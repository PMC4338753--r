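---
title: "A multicompartmental Purkinje-cell model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multicompartmental Purkinje-cell model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The package implements a conductance-based multicompartmental model of the
cerebellar Purkinje cell (PC) with an explicit axon, and packages the
standard PC electrophysiology experiments as scriptable protocols.  This
vignette is the methods account: the model, its numerical treatment, the
parameters that matter, the choices made where the design was genuinely
open, and the known limitations.

## The model

Each compartment obeys the current-balance equation

$$C_m \frac{dV}{dt} = -\sum_i g_i\,(V - E_i) \; - \; I_{\mathrm{axial}} \; + \; I_{\mathrm{inj}},$$

with the axial term coupling neighbouring compartments through cylindrical
half-resistances, $g = 1/\big(R_a L_1 / (2\pi r_1^2) + R_a L_2 /(2\pi
r_2^2)\big)$.  Fifteen voltage- and calcium-dependent conductances are
distributed over nine regions (soma, three dendritic orders, AIS, paraAIS,
myelinated internodes, nodes of Ranvier, collateral).  The densities are
the canonical distribution table returned by `pc_channelome()`: Na
channels concentrated in the AIS (0.5 S/cm²) with a substantial somatic
complement (0.214 S/cm²); K channels spread over soma, axon and dendrites
with the paraAIS carrying only Kv1.1; HVA (P-type) and LVA (T-type) Ca
channels mostly dendritic; myelin bare.

### Channel kinetics

Gating uses Hodgkin–Huxley gates for eleven channels and Markov schemes
for Nav1.6 (thirteen states: five closed, open, blocked, six inactivated —
the resurgent scheme, which produces transient, persistent and resurgent
current components) and KCa2.2 (six states with Ca-dependent forward
binding).  KCa1.1 (BK) uses the Purkinje $m^3 z^2 h$ description in which
$z$ is a two-state Ca-binding gate (half-activation 1 µM); KCa3.1 uses a
joint voltage/Ca activation gate.  Each model was implemented from its
source description; `pc_clamp_channel()` exposes any channel under
voltage clamp for inspection, and the test suite regression-pins the
steady-state curves, the bounds, and the Nav1.6 transient/persistent/
resurgent phenotype.

All rates are corrected from the source-data temperature to 37 °C with
$Q_{10} = 3$ (`q10_scale()`).  The correction matters quantitatively: the
P-type activation time constant measured at room temperature (≈ 0.27 ms at
0 mV) would otherwise be too slow for the channel to open during a
fast spike, starving the Ca-activated K channels.

### Reversal potentials and calcium permeation

Fixed reversals: Na +60, K −88, HCN −34.4, TRP 0 mV.  The calcium reversal
is updated every step from the submembrane concentration through the
single-ion GHK (Nernst) form; the default extracellular concentration
(≈ 1.33 mM) is back-solved so that the reversal is 137.5 mV at the 45 nM
resting concentration.  Ca-channel permeation is ohmic against this
updated reversal.  A constant-field (GHK flux) permeation mode is also
implemented (`pc_calcium_params(permeation = "ghk")`, densities then read
as permeabilities in cm/s); it is not the default because, with the
canonical density table, the constant-field subthreshold currents
destabilise the dendrites.

### Calcium dynamics

Every compartment that carries Ca channels gets a stack of submembrane
shells (outer depth 0.1 µm, up to four shells, adapting to the
compartment diameter), with radial diffusion of free Ca and of the mobile
buffers, two diffusible buffers, and a generic Michaelis–Menten extrusion
pump whose maximal rate is the region-wise pump-density table times a
single rate constant; a constant leak balances the pump at rest so 45 nM
is a fixed point.  The buffers are calbindin (160 µM, effective
K_D 0.82 µM) and parvalbumin (80 µM) with a deliberately slow effective
on-rate standing in for its Mg occupancy.  These numbers are the package's
own calibration within the literature ranges: with a much higher-affinity,
faster buffer pair the submembrane transients cannot reach the 0.045 → 1.6
µM range over which the KCa channels are documented to operate, and the
model cannot pace.  The pump rate constant (default `pump_rate = 1e5`) was
likewise fixed once at the fastest clearance that preserves pacemaking.

## Morphology

The axon is deterministic and fully specified: AIS (17 × 0.97 µm), paraAIS
(4 × 0.97), four myelinated internodes (100 × 0.73) alternating with three
nodes (4 × 0.73), and a two-section collateral (100 × 0.6 each) branching
at the second node.  The soma is a single 29.8 × 29.8 µm cylinder
(lateral area only, the NEURON convention).

The dendritic reconstruction behind the reference aggregates is not
published as coordinates, so the tree is a **seeded surrogate**
(`generate_surrogate_dendrites()`) constrained to the printed facts: a
total cell area of 70,000 µm², diameters within 0.67–9.22 µm, three branch
orders, and soma-measured passive aggregates of 14 MΩ and ≈ 1090 pF.  The
architecture is: a short thick trunk (≤ 4 sections, 9.2 → 7.5 µm), a
compact smooth "principal" core (18 % of sections, 5–15 µm lengths), and
thin terminal branchlets (1.1–2.6 µm) that carry most of the membrane
area.  Terminal lengths are drawn in the printed 1–10 µm band and rescaled
by a common factor to hit the area target, so a reduced tree trades
section count for branchlet length at fixed area.  The default desk-scale
tree uses 400 dendritic sections (~1500 compartments after λ-rule
discretisation); the full-scale 1599-section tree is available by
argument.  This architecture is what makes the surrogate electrically
PC-like: the thin spiny layer low-pass-filters the somatic spike (distal
dendrites see only spikelets) while remaining DC-coupled, which is
essential — with long chained branchlets (as in very small trees) the
model either fires doublets from dendritic back-discharge or locks into a
depolarised block.

Passive parameters: $R_a$ = 122 Ω·cm; somatic $C_m$ 0.77 µF/cm²; the
dendritic membrane uses an effective spine-corrected capacitance
(1.81 µF/cm² for the default tree) and a leak scaled by the same spine
factor, with the leak base calibrated once so the assembled model measures
14 MΩ / ≈ 1090 pF from the soma, then locked.  The leak reversal is
−61 mV.  Myelin capacitance (0.09 µF/cm², a thin multi-wrap sheath) is
the one axonal constant calibrated against function: it sets the
AIS → third-node conduction delay (≈ 0.86 m/s; much lower values give
implausibly fast conduction, and values above ~0.12 µF/cm² turn the
distal axon into a secondary pacemaker that fires ahead of the AIS).

## Numerics

Fixed step $dt = 0.025$ ms at 37 °C.  Voltages advance by backward Euler
with a direct tree solve (leaf-to-root elimination in Hines order,
root-to-leaf back-substitution); channel conductances enter the linear
solve frozen at their post-gate-update values.  HH gates use exponential
Euler with rate tables (0.05 mV grid) except Ca-dependent gates, which are
evaluated directly; Markov schemes use implicit Euler on the master
equation (dense 13×13 / 6×6 solves) with renormalisation.  The calcium
stacks advance by two explicit sub-steps per voltage step with a
non-negativity guard.  Initialisation: −65 mV everywhere, gates and
occupancies at steady state, calcium at rest; every run discards a 500 ms
settling window by default.  A divergence guard aborts if |V| reaches
200 mV.  Determinism: runs are bitwise reproducible; the only randomness
in the package is the seeded morphology generator.

Convergence was checked by dt-halving (spike-time shifts over 500 ms are
asserted in the suite) and the passive solver is validated against the
analytic RC charging curve, the sealed-end finite-cable input resistance
(1 %), and exact discrete charge balance.

## Protocols and analysis

`protocol_spontaneous()`, `protocol_fi()` (steps and double ramp),
`protocol_burst()`, `protocol_bistability()`,
`protocol_hyperpolarization()`, `protocol_ko()` (six-knockout battery),
`protocol_variants()` (Z⁻ via dendritic TRP leak, CF-PC via −40 % Cav2.1,
P-PC via HCN1 −50 % / Kv3.4 +8 % / Kv4.3 −50 %),
`protocol_dendritic_injection()` and `robustness_scan()` encode the
standard experiments with their pass/fail verdicts; all model edits are
applied to copies, so a protocol can never leave the model mutated.
Analysis operators (spike detection with a 1 ms refractory default, spike
shape at half AHP-to-peak amplitude, greedy spike matching for
transmission reliability, median-delay conduction velocity, ISI-gap burst
segmentation with a 3× gap factor, F/I linear-range fitting) are
independent of the solver and are unit-tested on constructed traces.
Burst-resolving contexts use a 0.25 ms refractory because the model's
intra-burst intervals can be sub-millisecond.

Problem sizes used by the shipped tests and the acceptance script: 1.5–3 s
per condition for rates and verdicts, 10 s for the spontaneous
characterisation, five-point step series, and a 0.1 nA-resolution sweep
around 2 nA for the burst threshold.

## Design decisions on open points

* **Cav2.1 activation**: implemented as a single gate with the printed
  per-gate Boltzmann (−29.5 mV, slope −8.5 mV).  The printed gate
  exponent 3 was also implemented and rejected: it collapses the per-spike
  Ca entry and the model cannot sustain firing.
* **Dendritic Nav1.6**: restricted to the trunk (the "main dendritic
  trunk" of the source description) rather than all dendrites.
* **Soma area**: lateral cylinder only (≈ 2790 µm²).
* **Tagging**: terminal < 3.5 µm, trunk = sections joining the soma,
  everything else principal.
* **Kv4.3** uses the source model's $a^3 b$ (the printed exponent 2 is a
  typesetting casualty).
* **E_leak** is not printed anywhere; −61 mV, configurable.

## What the surrogate shows — and what it does not

The surrogate reproduces the *structure* of PC electroresponsiveness:
AIS-led spikes that attenuate into the dendrites and propagate along the
axon, regular intrinsic pacemaking bounded by 75 Hz, silencing
by dendritic P-type knockout, paradoxical acceleration and spike growth
after dendrite removal, sag and rebound under hyperpolarisation, a
and one-for-one axonal transmission at low rates with K-dependent
filtering.  The AHP-to-peak spike amplitude (~80 mV), the conduction
velocity (~0.86 m/s), the somatic input resistance (14 MΩ) and
capacitance (~1090 pF) match the reference values quantitatively.

Several reference numbers are **not** reproduced, and the package reports
them honestly rather than tuning them in: the spontaneous rate stabilises
near 16 Hz (reference 35.5 Hz), the AHP trough is ≈ −78 mV (−62 mV), the
half width ≈ 2.5 ms (0.23 ms), the step F/I is shallow (tens of Hz at
1.6 nA rather than ~300 Hz), no tonic-to-bursting transition emerges —
the driven response stays tonic at ~25 Hz at every step amplitude tested,
so the burst threshold and burst rate simply do not exist for this
parameterisation — the AIS spike peak lead over the soma is below the
time-step resolution (reference 0.1 ms), and AIS Nav1.6 knockout alone
does not silence the model.  The root cause is a consistent one: with the kinetics
reconstructed from the cited source models and the canonical density
table, the somatic persistent Na current (−2 to −3 nA at subthreshold
voltages) exceeds what the somatic KCa complement can oppose, so the fast
Na–K pacemaker limit cycle of the reference implementation is not
reachable; the model instead paces on a slower SK/Ca relaxation cycle
whose period is set by submembrane Ca clearance.  All of the quantities
above are emergent (none is assigned), and the acceptance script
recomputes every one of them from scratch at run time.

Passing the shipped tests therefore demonstrates internal consistency
(solver, kinetics, calcium bookkeeping, analysis) and the qualitative
physiology listed above on the *surrogate* morphology; it does not
demonstrate that this parameterisation reproduces a real PC recording, nor
that results transfer to a reconstructed morphology with different
proximal load.

## Known limitations

Synaptic receptors and network context are out of scope; dendritic current
injection stands in for synaptic drive.  The Z⁻ variant's dendritic TRP
leak raises the basal rate (16 → ~26 Hz at the default density) but cannot
reach the ~100 Hz of real Z⁻ cells, for the same reason the F/I curve is
shallow: the firing rate is clamped by the SK/Ca relaxation cycle.  No axial (longitudinal) Ca
diffusion.  Calmodulin-dependent modulation (Cav2.1 CDF/CDI, PKC-dependent
Kv3.4 phosphorylation) is absent.  The robustness scan at full grid
resolution is computationally heavy and is shipped with reduced defaults.
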