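---
title: "AIS geometry and excitability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AIS geometry and excitability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aisx)
```

## The problem

In most vertebrate neurons the action potential starts in the axon initial
segment (AIS), a short stretch of proximal axon with a high density of Nav
channels. The AIS moves and resizes — across cell types, during
development, and with activity — and a natural question is what such
geometric changes do to excitability. `aisx` implements a theory of this
relationship together with the numerical models needed to test it: passive
cable closed forms, an analytical spike-threshold theory, and a
multicompartment conductance-based simulator with measurement protocols.

## Resistive coupling

The starting point is a passive observation. With membrane resistivity
$R_m$, axial resistivity $R_i$ and axon diameter $d$, the space constant is
$\lambda = \sqrt{R_m d / 4 R_i}$ (about 612 µm for the default parameters)
while the AIS sits within a few tens of µm of the soma. Over such distances
the axonal membrane resistance ($R_m/\pi d x \approx$ GΩ) dwarfs the axial
resistance ($r_a x$, with $r_a = 4R_i/\pi d^2 \approx 1.3$ MΩ/µm), so a
current entering the AIS flows essentially ohmically toward the soma. When
the somatodendritic compartment is large compared to the axon — which the
4/3 diameter scaling law (`electrical_equivalence_scaling()`) suggests is
the generic situation — the soma acts as a current sink: the *killed-end*
boundary condition. `input_resistance_sealed()`, `input_resistance_killed()`
and `input_resistance_finite_soma()` give the corresponding closed forms,
and `build_passive_neuron()` the simulable counterpart.

Two caveats worth knowing:

* The finite-soma form $R^{-1} = (r_a x + R_{soma})^{-1} + (r_a\lambda)^{-1}$
  neglects membrane leak along the proximal path. It agrees with the
  discretized cable to better than 2% proximally, but beyond roughly one
  space constant it can exceed the exact sealed-end value; the closed forms
  are proximal-axon tools.
* The distal axon is treated as semi-infinite ($R_{distal} = r_a\lambda$),
  with an optional `axon_length` argument applying the sealed-stub coth
  correction. The default axons (≥ 500 µm ≈ λ) are near the semi-infinite
  regime.

## Threshold theory

Near threshold the Nav current grows as $e^{V/k}$, with $k$ the Boltzmann
slope (5 mV by default). Balancing it against the ohmic current to the soma
gives, for a *point* AIS at axial resistance $R_a$ with available
conductance $G$,

$$V_s = V_{1/2} - k - k\,\ln\!\big(R_a G\,(E_{Na}-V_{1/2})/k\big),$$

a fold bifurcation: the somatic potential above which the axonal fixed
point disappears (`point_ais_threshold()`). The driving force is
approximated by $(E_{Na}-V_{1/2})$, as in the derivation; an
`exact_driving_force` flag solves the fold with the full Boltzmann current
instead (the two differ by under 2 mV at typical parameters). For very
proximal or weak AISes the fold does not exist — there is no threshold, and
the package signals a typed `aisx_no_bifurcation` condition rather than
returning a number. All logarithms here and below are natural: the theory
is built on $e^{V/k}$, so "per e-fold" is the unit in which slopes equal
$k$.

For a *spatially extended* AIS (start $\Delta$, length $L$, density $g$)
the static cable equation $V'' \propto -g\,e^{V/k}$ on the AIS with a
no-flux distal end and a resistive proximal stretch rescales to
$U'' + e^U = 0$. Its solution family is
$U(y) = \ln(2z^2) - 2\ln\cosh(z(y-1))$, and the fold condition is

$$(1+\Delta/L)\,z\tanh z + (\Delta/L)\,z^2(1-\tanh^2 z) = 1,$$

solved by bracketed root finding plus Newton polish to residual $<10^{-12}$
(`solve_bifurcation()`; the root is unique on $(0,10)$ for all
$\Delta/L \ge 0$). At $\Delta = 0$ this gives $z \approx 1.2$, a rescaled
somatic threshold $U_0 = \ln(2z^2) - 2\ln\cosh z \approx -0.13$, and an
AIS-end threshold $U_1 = \ln(2z^2) \approx 1.06$ — the AIS end sits about
$1.2k$ above the somatic threshold. Relative to a point AIS with the same
total conductance placed at the AIS end, the extended AIS threshold is
higher by $(1+U_0)k = 0.87k$; equivalently, the extended AIS behaves like a
point AIS placed at $e^{-0.87}L \approx 0.42L$, close to its midpoint. The
residual error of the midpoint rule is $k\,F(\Delta/L)$ with
$F(\rho) = U_0(\rho) + 1 + \ln(\rho + 1/2)$, which decreases monotonically
from $0.177$ at $\rho = 0$ to $0$ in the point limit
(`corrective_term_F()`): at most ~0.9 mV for $k = 5$ mV. The upshot is the
separable formula

$$V_s = \text{const} - k\ln g - k\ln L - k\ln x_{1/2} + k\ln d,$$

with $x_{1/2} = \Delta + L/2$, implemented as ratios in
`threshold_shift_geometry()` and, for measured (L, x_half) pairs, in
`predict_geometry_shift()` / `table2_predictions()`.

A static axonal current $I$ at the AIS start shifts the somatic threshold
by $-R_a I$ without moving the AIS-site threshold
(`threshold_shift_from_current()`); a conductance instead combines with
$R_a$ in parallel (`effective_Ra()`). Currents at the AIS end or spread
uniformly have no closed form, so `bvp_threshold()` solves the boundary
value problem numerically: backward shooting from the AIS end with
`deSolve`, locating the fold as the maximum of the implied somatic
potential over the end voltage. For end-injected currents the somatic
threshold is close to, but not exactly, the linearized $-R_a I$ (both are
returned; no tighter bound is asserted because none is known). The distal
axon acts like such a conductance with reversal at rest, raising the
threshold by $(R_a/R_{distal})(V_a - E_L)$ — about 2.4 mV for the default
parameters, halved by myelination since $R_{distal} \propto \sqrt{R_m}$
(`distal_load_threshold_shift()`).

## Channel kinetics

Gates use the minimal three-parameter rate forms whose equilibrium is a
Boltzmann with half voltage $V_{1/2}$ and slope $k_x$, and whose time
constant is a bell peaking at $V_{1/2}$ with value $\tau^*_x$
(`rate_alpha()`, `rate_beta()`). The removable singularity at
$V = V_{1/2}$ is evaluated by series expansion within
$|V - V_{1/2}| < 10^{-6} k_x$. The packaged set
(`build_paper_channels()`): Nav with one activation gate $m$ and one
inactivation gate $h$ ($k = 5$ mV; AIS curves 5 mV hyperpolarized relative
to the soma; $\tau^*_m = 150$ µs and $\tau^*_h = 5$ ms measured at 23 °C and
Q10-corrected by $2.8^{(33-23)/10}$ to 53.6 µs and 1.8 ms), and Kv1 as
$n^8$ ($V_{1/2} = -70$ mV, $k = 20$ mV, $\tau^* = 1$ ms, uncorrected since
it was fit at 33 °C). The eighth power makes the K⁺ current activate with a
delay, keeping Na⁺ and K⁺ currents temporally separated at initiation.

Kv7: no published parameter set is printed for the reference model, so the
kinetic variant (single non-inactivating gate, $V_{1/2} = -30$ mV,
$k = 9$ mV, $\tau^* = 100$ ms) is an assumption, and the default
representation of a hyperpolarizing AIS conductance is *static* (ungated,
reversal −90 mV, `static_conductance()`): at spike-initiation time scales
only the standing current matters, which is what the threshold predictions
use. Conclusions drawn from the kinetic Kv7 variant should be treated as
qualitative.

## The simulator

`compile_model()` flattens a soma + section tree into per-compartment
arrays; `run_sim()` advances them with a theta-method (backward Euler by
default, Crank–Nicolson via `theta = 0.5`) in which the branched linear
system is solved exactly per step by leaf-to-root elimination — the
standard ordered (Hines-type) factorization, unconditionally stable for
the passive subsystem. Gates are operator-split and relax exactly
(exponentially) toward $x_\infty(V)$ within each step, which is stable for
time constants as short as 54 µs at the default $dt = 5$ µs. The soma is a
single isopotential sphere; its axial resistance to each child is the
child's first half-compartment only. Voltage clamp is ideal (zero series
resistance, Dirichlet constraint at the soma) and reports the electrode
current.

Default discretization, chosen by refinement study (halving both $dt$ and
$dx$ moves the measured threshold by well under 0.1 mV): $dx = 1$ µm on the
proximal axon (out to the AIS end + 15 µm, at least 100 µm) and 10 µm
elsewhere; $dt = 5$ µs for active models, 100 µs ($dx = 2$ µm) for passive
ones. Everything is deterministic; the only randomness anywhere is the
seeded noise of the synthetic trace fixtures.

Morphologies: `build_biophysical_neuron()` (30 µm soma, 6 µm × 1 mm
dendrite, 1 µm × 500 µm axon, AIS at 5–35 µm by default) with variants —
`big_axon` (3 µm axon, soma scaled to $30 \cdot 3^{3/4}$ µm by the
equivalence law, AIS rescaled by $\sqrt 3$), `long_axon`, `myelinated`
($R_m \times 4$, $C_m / 4$ beyond the AIS end), `branched_32`/`branched_52`
(distal branch point at 100 µm — the reference description does not print
the branch location — with daughter diameters from
$d^p_{main} = d_1^p + d_2^p$), and `axon_dendrite` (2 µm stem splitting
after 7 µm per the 3/2 rule, one daughter carrying the axon).
`build_simplified_neuron()` is the reduced model for voltage-clamp checks:
a passive 1 µm × 300 µm axon with all Nav conductance at one site, a single
non-inactivating gate with fixed $\tau_m = 53.6$ µs.

## Protocols and their numerics

`find_rheobase()`/`measure_voltage_threshold()`: the soma is first held at
−75 mV under voltage clamp until equilibrium; the equilibrium electrode
current becomes the holding current after release (this pins the initial
Nav inactivation state across conditions). A current step (default 100 ms;
50 vs 200 ms moves the threshold by < 0.3 mV) is bisected between
non-spiking and spiking amplitudes to 0.1 pA. A spike is an AIS-end
crossing of −20 mV — unambiguous given the > 60 mV spike amplitude, and
insensitive to the criterion within [−30, 0] mV.

One numerical point deserves emphasis. The threshold voltage is defined as
the maximal somatic potential in a non-spiking trial, but near the fold the
trajectory shadows a saddle, and the trial maximum approaches the threshold
like $\sqrt{I_{rheo} - I}$. Reading it from "the largest non-spiking
bisection trial" therefore jitters by several tenths of a mV depending on
where the bisection happens to stop. The package instead reads the
voltages from a non-spiking trial at a declared amplitude gap below the
measured rheobase (`readout_gap_pA`, default 1 pA): the readout becomes
reproducible to ~0.02 mV, at the cost of a small bias that is common to
all conditions and cancels exactly in the differences and regression
slopes the theory predicts. Setting `readout_gap_pA = 0` recovers the
literal reading.

A related subtlety affects the prediction that the soma–AIS threshold
difference equals $-k - \Delta V_{rest}$ (with $\Delta V_{rest}$ the
AIS-minus-soma resting difference set up by a standing axonal current).
The relation treats the axial resistance as fixed, but any conductance
standing at the AIS — here the point AIS's Kv1, whose $n^8$ open fraction
is a few percent near threshold — shunts part of the axial path, so the
measured slope of the threshold difference against $\Delta V_{rest}$ is
about $-0.88$ rather than $-1$. Within physiological resting gradients
(a few mV) the residuals stay below 1 mV; at extreme modulations
(|ΔV| ≳ 10 mV, currents of several hundred pA) they reach ~1.3 mV. This
is the shunt correction the theory itself prescribes for conductances
(`effective_Ra()`), not a solver artifact.

`voltage_clamp_spike_threshold()` raises the somatic command until half
the point-AIS Nav gates open, with a 0.05 mV staircase and 20 ms settling
per level (drift ≪ resolution); a 1 mV coarse pass brackets the threshold
first, which is exact because gate opening is monotone in the command.
`step_response_resistance()` implements the early-time statistic (median
over 200–400 µs minus the 5 ms pre-pulse baseline, divided by the
current). `log_slope()` regresses thresholds on natural-log parameters so
slopes are in mV per e-fold, directly comparable to $k$.

## What the reproductions use, and what passing shows

`repro()` regenerates the reference analyses with scaled-down grids: 4–6
points per sweep (e.g. $g \in \{3500, 5000, 7000, 9000\}$ S/m²,
$x_{1/2} \in \{20, 25, 30, 35\}$ µm, $L \in \{15, 20, 30, 40\}$ µm at the
default density; leak sweep over 1–4× the default somatic leak; axonal
currents 0 to −400 pA). Two regime notes:

* At small total AIS conductance ($G \lesssim 200$ nS with the default
  kinetics) the model leaves the spiking regime — the AIS "spike" barely
  reaches −20 mV and inactivation collapses — and the measured threshold
  departs from the log law. The sweep grids stay inside the operating
  regime; the theory itself makes no claim outside it.
* The somatic threshold's insensitivity to somatic leak is exact only in
  the idealized separation of time scales; in simulation the measured
  value drifts by ~1 mV if the somatic leak is pushed to 16× its default.
  Over the 1–4× sweep used here the variation stays below 0.3 mV.

The synthetic trace fixtures (`generate_trace_fixture()`) emulate only the
features the protocol statistic consumes — step onset, two exponential
charging time constants, additive Gaussian noise. They do not emulate
electrode artifacts, bridge imbalance, drift, or spike waveforms, so tests
passing on them validate the statistic's arithmetic, not its robustness on
real recordings.

Passing the packaged checks shows the implementation reproduces the
theory's printed constants and its own simulator's agreement with that
theory under the stated conditions; it does not by itself validate the
biological assumptions (cylindrical AIS, no tapering, inactivation state
held fixed by the holding protocol, no extracellular effects).

## Known limitations

* Sections are cylinders; tapering near the soma is not represented. For
  non-uniform proximal axons, distances should be read as axial
  resistances (the `axon_dendrite` variant illustrates this).
* The analytical theory ignores Nav inactivation beyond the initial
  available fraction, time-varying K⁺ currents, and capacitive terms; the
  biophysical model includes them, which is why its conductance slope
  (~8–9 mV per e-fold) exceeds the theoretical $k$.
* Kv7 kinetics are placeholders (above); frequency-dependent input
  impedance and stochastic channels are out of scope.
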