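# aisx — axon initial segment geometry and neuronal excitability

In most vertebrate neurons the action potential starts in the axon initial
segment (AIS), a stretch of proximal axon a few tens of µm long with a high
Nav channel density. The AIS moves and resizes across cell types, during
development and with activity, and experiments disagree on what that does
to excitability. `aisx` is for computational and cellular
neurophysiologists who want to put numbers on this question: it implements
a spike-threshold theory for the soma–AIS system together with the passive
cable formulas, conductance-based compartmental models, and measurement
protocols needed to derive and test it.

## The theory in brief

When the somatodendritic compartment is large compared to the axon
(*resistive coupling* regime), the soma acts as a current sink and spike
initiation is a fold bifurcation of the axonal membrane with the somatic
potential as control parameter. For Nav channels with Boltzmann slope *k*,
half-activation V½ and reversal E_Na, a point AIS at axial resistance R_a
with available conductance G has somatic threshold

    Vs = V½ − k − k·ln( R_a·G·(E_Na − V½)/k )

For a spatially extended AIS (start Δ, length L, density g, diameter d)
the static cable equation V'' ∝ −g·e^(V/k) solves in closed form, and the
threshold separates into independent logarithmic contributions

    Vs = const − k·ln g − k·ln L − k·ln x½ + k·ln d,        x½ = Δ + L/2

i.e. the extended AIS behaves like a point AIS with the same total
conductance at its midpoint, up to a corrective term k·F(Δ/L) ≤ 0.9 mV. A
static axonal current I shifts the somatic threshold by −R_a·I (a
hyperpolarizing current at the AIS *raises* the somatic threshold, which
can reverse the usual effect of distal AIS displacement). All slopes are
in mV per e-fold; natural logs throughout.

## Worked example

```r
library(aisx)

mem <- passive_membrane()          # Rm 15000 Ω·cm², Ri 100 Ω·cm, EL −75 mV
axon <- cable_geometry(d = 1)
space_constant(mem, axon)          # 612.37 µm
axial_resistance(mem, axon, 100)   # 127.32 MΩ for 100 µm of 1 µm axon

# analytical threshold of the default AIS (5–35 µm, 3500 S/m²)
nav <- nav_theory_params(k = 5, V_half = -35, ENa = 70)
extended_ais_threshold(nav, mem,
                       ais_geometry(delta = 5, L = 30, d = 1, g = 3500))
#> $Vs_soma  -65.03   $Vs_ais_end  -59.14   $kF  0.837 (mV)

# what a 10→15 µm AIS displacement with a 40 µm AIS does (midpoint 30→35):
threshold_shift_geometry(x_ratio = 35 / 30)   # -0.77 mV (more excitable)

# measured geometry changes from a deprivation study (L 9.6→19.5 µm,
# x½ 13.3→18.4 µm): predicted threshold shift
predict_geometry_shift(9.6, 13.3, 19.5, 18.4) # -5.17 mV (observed: -4)

# the same number from the packaged study table
table2_predictions()$dVs_theory_mV[1]         # -5.17

# simulate the biophysical model and measure its threshold
cm <- compile_model(build_biophysical_neuron())
res <- measure_voltage_threshold(cm)
res$rheobase           # 806.8 pA
res$V_threshold_soma   # -56.17 mV (max somatic V in a non-spiking trial)
res$V_threshold_ais    # AIS-end threshold, ~5-8 mV above the somatic one
```

The simulated threshold sits above the analytic −65 mV because the
biophysical model keeps what the theory drops: Nav inactivation at the
−75 mV holding potential, Kv1, leak and capacitive currents. The *slopes*
of threshold against ln g, ln L and ln x½ are what the theory predicts
(within 1–2 mV per e-fold), and those are what the test suite checks.

`repro("<name>")` regenerates the package's reference analyses
(`"fig1"`–`"fig13"`, `"table2"`) as CSV files; `exec/aisx` is a thin
command-line wrapper (`aisx passive`, `aisx theory`, `aisx table2`,
`aisx fixture`, `aisx repro <name>`).

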