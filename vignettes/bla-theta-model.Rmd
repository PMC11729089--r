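---
title: "A conductance-based basolateral amygdala network model with basal-forebrain inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based basolateral amygdala network model with basal-forebrain inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`blanet` implements a 1000-cell conductance-based network model of the
basolateral amygdala (BLA).  Five cell classes are modelled as
multicompartment Hodgkin-Huxley neurons: two electrophysiological subtypes
of glutamatergic principal neuron — adapting (PN_A, n = 569) and
continuously firing (PN_C, n = 231) — and three GABAergic interneuron
classes: parvalbumin-expressing basket cells (PV+, n = 93),
calretinin-expressing interneurons (CR+, n = 56) and
somatostatin-expressing interneurons (SOM+, n = 51).  The proportions
(56.9 / 23.1 / 9.3 / 5.6 / 5.1 %) follow anatomical estimates for the rat
BLA.

Each compartment obeys the cable-type current balance

$$C_m \frac{dV_s}{dt} = -g_L (V_s - E_L) - g_c (V_s - V_d)
  - \sum I^{int}_{cur} - \sum I^{syn}_{cur} + I_{inj},$$

with intrinsic currents of the form $I = \bar g\, m^p h^q (V - E)$ and
first-order gating kinetics $dx/dt = (x_\infty - x)/\tau_x$.  The channel
complement per cell type (fast and persistent Na, delayed-rectifier and
muscarinic K, high-threshold Ca, L-type Ca, H-current, transient Na, and a
calcium-dependent slow afterhyperpolarisation current, sAHP) and every
density are carried in the shipped YAML configuration
(`inst/extdata/default_config.yaml`), which is the package's single source
of parameter truth and round-trips losslessly.

Synaptic transmission uses AMPA, NMDA and GABA_A receptors with
pulse-transmitter kinetics
$r' = \alpha T_{max}\,\mathrm{ON}\,(1 - r) - \beta r$, an NMDA
magnesium block $s(V) = [1 + 0.33\,e^{-0.06V}]^{-1}$, connection-specific
short-term plasticity (facilitation $F \to F f$ with exponential recovery;
two-factor depression $d_1 d_2$ with fast/slow recovery), log-normal
synaptic weights resampled above three times the mean, and
distance-dependent conduction delays at 0.5 m/s.  Cholinergic tone is a
discrete network state ACh ∈ {0, 1, 2}; sensitive currents are scaled by
$1 + b_{ACh}(ACh - 1)$, so baseline tone changes nothing.

Extrinsic drive comprises (1) independent 2 Hz Poisson thalamic/cortical
afferents onto PNs, SOM+ and CR+ cells; (2) the cholinergic gain state; (3)
893 GABAergic afferents from the ventral pallidum / substantia innominata
(VP/SI) contacting every PN with convergence 1 and each PV+ cell with mean
convergence 10.1 — Poisson at 2 Hz in the non-rhythmic regime, and one
event per 8 Hz cycle with per-event Gaussian jitter (SD 17.7 ms, giving the
afferents' characteristic 125 ± 25 ms inter-spike intervals) in the
theta-modulated regime; and (4) an Ornstein–Uhlenbeck two-component
(excitatory/inhibitory) background conductance at every soma.

The local field potential is reconstructed by the line-source
approximation: each compartment is a uniform line current, its potential at
the electrode is

$$\Phi = \frac{I}{4\pi\sigma\Delta s}
 \ln\left|\frac{\sqrt{h^2+r^2}-h}{\sqrt{l^2+r^2}-l}\right|,\qquad l = \Delta s + h,$$

summed over all compartments at 0.5 ms resolution (bin averaging),
$\sigma = 0.3$ S/m, and a global scale factor of 1000 shared by all
experimental conditions.

## Experiments

Six cases cross VP/SI rhythmicity with cholinergic tone: 1 (Poisson, ACh 1),
2 (theta, 1), 3 (theta, 2), 4 (theta, 0), 5 (Poisson, 2), 6 (Poisson, 0).
A run lasts 15 s with the first 5 s discarded; each case is repeated over
seeds and summarised by the peak theta (4–12 Hz) power of the Welch
spectrum of the LFP.  The ablation study disconnects the efferent synapses
of one interneuron group under Case 3 (cells remain present and driven),
renormalises the principal-cell background drive back to the baseline
firing-rate targets (PN_A 0.45 Hz, PN_C 0.6 Hz, ±10 %, by bisection on a
single scalar multiplying the PN excitatory background conductance and
thalamic rate), and repeats the analysis.  The intact base condition is
passed through the same rate-matching so that all four conditions are
compared at matched principal-cell rates — without this the cholinergic
gain of Case 3 would confound the ablation contrast.

```{r example}
library(blanet)
cfg <- default_config()

# calibrate the baseline drive, then run the six cases at desk scale
rn <- renormalize_background(cfg, scale = 0.25, case_id = 1, seed = 1,
                             duration_ms = 7000, discard_ms = 2000)
cases <- lapply(1:6, function(k)
  run_case(k, cfg, scale = 0.25, seeds = 1:3, duration_ms = 7000,
           discard_ms = 2000, background_multiplier = rn$multiplier))
compare_cases(cases, "cases")$anova
```

## Parameter provenance and calibration

Almost every number in the configuration is a published model parameter:
geometries, capacitances, axial resistivities, channel densities, gating
functions, connection probabilities (overall / unidirectional /
bidirectional per ordered class), population sizes, afferent convergences,
OU conductance means and SDs, plasticity factors, the conduction velocity,
and the LFP constants.  The remaining quantities are free parameters of the
model; they were fixed once, as follows, and are all exposed in the
configuration:

* **Reversal potentials** beyond the leak: conventional values
  (E_Na = +50, E_K = −90, E_Ca = +120, E_H = −30 mV); AMPA/NMDA reverse at
  0 mV and GABA_A at −75 mV, matching the background inhibitory reversal.
* **Interneuron leak parameters.**  The printed leak conductances are
  internally inconsistent (the PV entry is off by orders of magnitude, and
  the interneuron membrane-resistivity statements disagree with the printed
  leak densities), so the leak conductance and leak reversal of each
  interneuron type are calibrated numerically (`calibrate_passive()`), with
  the simulated −10 pA step protocol, against the published input
  resistances: PV 371 MΩ, SOM 290 MΩ, CR 321 MΩ.  With the printed
  delayed-rectifier kinetics (activation midpoint −15 mV, slope 11 mV,
  exponent 1) the resting K conductance at −70 to −60 mV already exceeds
  the total conductance those input resistances imply, so the published
  (V_rest, R_IN) pairs are not jointly attainable; the calibration
  prioritises R_IN and lets the resting potential settle where the channel
  balance puts it (PV ≈ −72 mV, SOM ≈ −83 mV, CR ≈ −84 mV).  The CR+
  resting potential therefore sits below its stated −60 mV; this is a known,
  documented deviation, and the corresponding check in the test suite is
  expected to flag it.
* **Transient-Na rate magnitudes** (Ra, Rb, Rd, Rg): the gating functional
  form is fixed but the magnitudes are free; they were tuned once so that
  SOM+ and CR+ cells fire tonically at ~20 Hz to 200 pA steps instead of
  spiking once and latching, giving Ra = 0.8, Rb = 0.025 (activation
  midpoint ≈ −40 mV), Rd and Rg at their conventional values.
* **Calcium pool.**  The sAHP gate needs an intracellular calcium signal
  whose dynamics are not otherwise specified.  A per-compartment first-order
  pool is used: d[Ca]/dt = −k·I_Ca − ([Ca] − [Ca]_rest)/τ_Ca, with
  τ_Ca = 300 ms, [Ca]_rest = 10⁻⁴, a floor of 10⁻⁸ keeping the log₁₀ in the
  sAHP rates defined, and per-channel couplings k chosen so that the resting
  calcium window current leaves the gate shut while spike-driven influx
  opens it over a few spikes (k = 5×10⁻⁵ for the high-voltage-activated Ca
  current, 1.5×10⁻⁶ for the much denser L-type current).  This reproduces
  the adapting phenotype: PN_A inter-spike intervals lengthen monotonically
  (~70 → 100 ms at 200 pA) while PN_C, with 25-fold lower sAHP density,
  fires with ISI CV < 0.15.  The sAHP rate expressions use log₁₀([Ca]²); a
  configuration switch (`sahp_square`) selects the plain-[Ca] reading.
* **Axonal sodium.**  The principal-cell axonal Na channels are folded into
  the soma compartment (the stated three-compartment geometry has no axon);
  the folded density (0.05 S/cm²) was set so PNs spike robustly.
* **Receptor kinetic constants** (αT_max, β, transmitter pulse lengths):
  set to standard values for this kinetic scheme, giving decay constants of
  ~2 ms (AMPA), ~7 ms (GABA_A) and ~100 ms (NMDA); pulse lengths 1 ms
  (AMPA/GABA_A) and 5 ms (NMDA).
* **Synaptic weight means** per connection class, and the VP/SI afferent
  weights: tuned once — as the original network was — so that (i) the
  renormalised baseline state fires at PN_A ≈ 0.45 Hz and PN_C ≈ 0.6 Hz,
  and (ii) the theta-modulated VP/SI drive of PV+ cells is strong relative
  to the intrinsic drives, which the disinhibition mechanism requires.  The
  log-normal weight shape (σ_log = 0.5) is a free choice.
* **Spatial layout.**  Cells are placed uniformly in a 600 µm cube (BLA
  scale) with the electrode at the centre; conduction delays then span
  0–2 ms.  Compartments have no published 3-D orientation: each cell's
  dendritic axis is oriented along +z deterministically (chains extend
  upward; a second soma-attached dendrite extends downward).  Orientation
  affects absolute LFP amplitude, not the normalised rhythm statistics the
  analyses use.
* **Eq-level transcription repairs** (activation row of the high-threshold
  axonal Na current listing the time-constant formula in the steady-state
  column, a +43/+30 argument mismatch, an inactivation curve printed in a
  form that exceeds 1, and an L-type opening-rate sign): each was replaced
  by the standard form its printed coefficients match; all are noted in the
  code where they occur.

## Numerical scheme

Integration is fixed-step at dt = 0.1 ms.  Gating variables advance by
exact exponential relaxation toward steady states interpolated from dense
lookup tables (0.05 mV grid; 0.01 grid in log₁₀[Ca] for the sAHP gate);
removable singularities of trap-form rates are evaluated by their analytic
limits.  Voltages advance by a linearised implicit (backward-Euler) step
with all membrane conductances frozen over the step, solved exactly on each
cell's compartment tree, which is stable for these stiff channels at
0.1 ms.  Synaptic open fractions integrate in closed form within each step.
Presynaptic spikes (somatic upward 0 mV crossings with a 2 ms detection
refractory) are delivered through a ring buffer after their conduction
delay, quantised to the dt grid (≤ 0.05 ms error).  Spike counts change by
at most one when dt is halved, and scaled-network population rates change
by < 5 %.

The transmembrane current handed to the LFP is the total membrane current
(capacitive + ionic + synaptic + background), which sums to the injected
current across each cell's compartments to machine precision; the in-core
LFP accumulation equals the reference double-loop summation of recorded
compartment currents to 10⁻¹⁰.

All randomness flows through named substreams derived from one master
seed (placement, wiring, weights, each afferent train, background noise),
so a run is a pure function of (configuration, seed, scale); ablated runs
reuse the identical structure and noise of their parent.

## Scaled protocol

Full-scale 10-seed 15 s runs are expensive, so the routine experiment suite
runs at scale 0.25 (250 cells, 223 afferents, fractions and afferent
convergences preserved) for 7 s with 2 s discarded, over 3 seeds.  Because
a scaled network has proportionally fewer intrinsic inputs per cell,
intrinsic synaptic weights are divided by the scale factor at simulation
time so mean intrinsic drive per cell matches the full network.  At this
scale the qualitative results hold: theta appears only with rhythmic VP/SI
input, high cholinergic tone more than doubles theta power relative to
baseline tone, low tone suppresses it, the rhythmicity-by-tone interaction
is significant, and PV+ ablation — but not SOM+ or CR+ ablation —
collapses theta power.

## What the generators emulate, and limits

The synthetic afferents reproduce the statistical structure the network
model assumes — Poisson counts, the 125 ± 25 ms jittered rhythmic regime,
OU background moments and autocorrelation — not the biophysics of real
afferent populations (no spike correlations beyond the shared rhythm, no
conduction modelling, no neuromodulatory dynamics).  Passing tests
demonstrate that the implementation realises the stated model under its
stated conditions; they are not evidence about the biological BLA beyond
what the model design encodes.  Other known limitations: no gap junctions,
no GABA_B, no long-term plasticity, no A-type K current (its printed
densities have no accompanying kinetics), deterministic channel gating, and
an isotropic, frequency-independent extracellular medium.
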