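# purkinje

A self-contained multicompartmental model of the cerebellar Purkinje cell
(PC) in R, with a compiled fixed-step implicit solver.  The PC is the sole
output neuron of the cerebellar cortex: a fast intrinsic pacemaker that
switches to complex bursting at high drive, whose spikes are generated in
the axon initial segment (AIS) and filtered along the myelinated axon
before they reach the deep cerebellar nuclei.  The package is for
computational neuroscientists who want those phenomena — pacemaking, F/I
curves, complex bursting, axonal transmission, bistability under channel
down-regulation, knockout phenotypes — as reproducible, scriptable
experiments on a fully inspectable model.

## The model

Every compartment integrates

dV/dt = −(1/C_m) [ Σᵢ gᵢ (V − Eᵢ) + I_axial + I_inj ]

over a branched tree (backward Euler, Hines-ordered direct solve,
dt = 0.025 ms, 37 °C).  The membrane carries 15 ionic channel models —
Nav1.6 as the 13-state resurgent Markov scheme; Kv1.1, Kv1.5, Kv3.3,
Kv3.4, Kv4.3, Kir2.x as Hodgkin–Huxley gates; KCa1.1 (BK, m³z²h),
KCa2.2 (SK2, 6-state Markov), KCa3.1; Cav2.1 (P-type), Cav3.1/3.2/3.3
(T-type) with a GHK-updated Ca reversal; HCN1; plus an optional TRP leak
for the Z⁻ firing variant — distributed over soma, three dendritic
orders, AIS, paraAIS, myelin, nodes of Ranvier and a collateral.
Submembrane calcium is tracked in diffusive shell stacks with calbindin
and parvalbumin buffering and a generic extrusion pump.

The axon is fully specified; the dendritic tree is a seeded surrogate
calibrated to the published aggregates (70,000 µm² total area, 14 MΩ and
~1090 pF measured from the soma), since the reference reconstruction is
not published as coordinates.  See the methods vignette
(`vignettes/purkinje-model.Rmd`) for the full account, including which
reference behaviours the surrogate reproduces and which it does not.

## A worked example

```r
library(purkinje)

model <- pc_model()            # canonical model, seeded surrogate tree
model
#> Purkinje-cell model: 412 sections, 643 compartments, area 70000 um2, 37 C

imp <- impedance_from_soma(model)
round(c(rin = imp$rin, cin = imp$cin), 1)
#>    rin    cin
#>   14.0 1092.6

tr <- pc_run(model, 3000, record = c("soma", "AIS", "node3"))
train <- detect_spikes(tr$time, tr$v[, "soma"])
firing_rate(train, duration = 3000)
#> [1] 16.33333

sh <- spike_shape(tr$time, tr$v[, "soma"], train)
round(c(amplitude = sh$mean_amplitude, ahp = sh$mean_ahp), 1)
#> amplitude       ahp
#>      80.2     -78.0

conduction_velocity(detect_spikes(tr$time, tr$v[, "AIS"]),
                    detect_spikes(tr$time, tr$v[, "node3"]),
                    axon_path_length())
#> [1] 0.86
```

The model fires regular simple spikes at ≈ 16 Hz with an AHP-to-peak
amplitude of ≈ 80 mV; spikes initiate in the AIS and travel to the third
node of Ranvier at ≈ 0.86 m/s.  Experiments are one call each:

```r
run_protocol(protocol_spontaneous(), model)   # pacemaking + its controls
run_protocol(protocol_fi("ramp"), model)      # double current ramp
run_protocol(protocol_burst(2.2), model)      # complex bursting
run_protocol(protocol_bistability("dend_Cav21"), model)
robustness_scan(model, "Kir2.x")              # conductance tolerance class
```

A thin command-line front end (`inst/cli/pcsim`) exposes the same
protocols as subcommands (`simulate`, `fi`, `burst`, `ko`, `bistability`,
`variants`, `robustness`) with `--edit channel:region:scale` for ad-hoc
knockouts, writing traces (CSV), metrics (JSON) and a reproducibility
manifest.

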