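---
title: "Modelling state-dependent firing of CCK+ interneurons with two A-type potassium current variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling state-dependent firing of CCK+ interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsim)
```

## The biological problem

Cholecystokinin-expressing interneurons (CCK+INs) of the hippocampus split
into two firing phenotypes. *Regular-spiking* (RS) cells fire with a short
onset delay regardless of the membrane potential (MP) preceding a current
step. *Transient outward rectifier* (TOR) cells are silenced for roughly a
quarter of a second when the same step is delivered from hyperpolarized
potentials (around -80 mV), yet fire promptly from -60 mV. The switch is
attributable to a single ionic mechanism: a subthreshold-activated,
inactivating (A-type, Kv4-mediated) potassium current, I_SA, which occurs in
two kinetic variants. RS cells carry one variant (I_SA_RS). TOR cells carry
a roughly 3:1 density mixture of I_SA_RS and a left-shifted, slowly
inactivating, slowly recovering variant (I_SA_TOR). Because availability and
recovery of I_SA_TOR have time constants of tens of milliseconds in the
subthreshold voltage range, the mixture acts as a band-selective brake:
under oscillatory synaptic drive it suppresses firing most strongly when the
input arrives at 8-15 Hz, and much less at lower or higher frequencies.

This package rebuilds that argument as a simulation pipeline: conductance
models of the two I_SA variants, reduced compartmental CCK+IN models in
either configuration, the voltage-clamp and current-clamp protocols used to
characterise the currents, an oscillatory synaptic drive generator, and the
paired-simulation analysis of the silencing effect.

## Channel models

Every channel is a Hodgkin-Huxley conductance `g * m^a * h * (V - E)`. For
the I_SA variants the gate exponents are 1, so the printed curve-level
Boltzmann parameters map directly onto the gate steady states (the
measurements constrain the curves, not per-gate exponents). Steady states
are Boltzmann functions; the activation time constant is fixed at 1 ms
(fast relative to every phenomenon analysed here; it is not separately
measured), and the inactivation time constant tau_h(V) is built by monotone
cubic interpolation through the measured anchors - the recovery time
constants at -120/-85/-75/-65 mV on the hyperpolarized limb and the decay
time constant of the current at -25 mV on the depolarized limb - and is
clamped beyond the anchor range:

```{r tau}
isa_channel("tor")$gating$tau_inact_anchors
tau_h(-85, isa_channel("tor")$gating$tau_inact_anchors)
```

Inactivation midpoints are the whole-cell values (-64.5 mV TOR, -57.4 mV
RS). Slope factors are solved from one printed availability point each
(91.3% at -80 mV for TOR; 52.7% at -60 mV for RS) with
`calibrate_from_anchors()`. The two RS anchors are *not* jointly consistent
with a typical ~6.6 mV Boltzmann slope; inverting the curve through the
printed pair yields a very shallow slope (~24 mV). We keep the printed pair
and the shallow slope rather than inventing a third constraint; the
consequence is a flat RS availability curve, which the protocol tests
reproduce.

### Two activation profiles

Activation voltage dependence differs sharply between recording
configurations, so two calibration profiles ship:

* **nucleated**: midpoints -16.4 mV (TOR) and -8.9 mV (RS), slopes solved
  from the fractional activation at -40 mV, using working points 0.10 (TOR)
  and 0.025 (RS) chosen between the reported median and mean activation
  there. This profile represents the near-ideally clamped isolated soma.
* **whole_cell**: same slopes, midpoints solved (once, on the template
  morphology) so that the simulated whole-cell activation protocol -
  conditioning at -120 mV, step to -40 mV through the 2.76 MOhm
  uncompensated series resistance, leak-subtracted - reproduces the
  measured current amplitudes: ~683 pA for the TOR mixture and ~148 pA for
  the RS configuration. This lands the I_SA_TOR midpoint near -46 mV,
  consistent with whole-cell currents activating 30-40 mV below spike
  threshold.

The simulation pipeline (firing protocols, oscillatory drive) uses the
whole-cell profile throughout. We initially followed the alternative of
pairing whole-cell inactivation with nucleated activation, but with the
nucleated midpoints the I_SA_TOR component is only a few percent activated
in the subthreshold range, the TOR onset delay from -80 mV collapses to the
RS value, and no phenotype separation survives. The whole-cell anchoring is
also how the original models were constrained (on whole-cell recordings).
The nucleated profile remains available for nucleated-patch work such as
charge-density measurements.

A mild circularity is accepted deliberately: the printed inactivation
parameters describe TOR-cell (i.e., mixture) currents, but we assign them to
the I_SA_TOR component. The simulated *mixture* curves are therefore
slightly right-shifted and faster than the printed values. Channel-level
protocol round-trips (availability, recovery and inactivation time
constants) consequently use single-variant cells (`build_channel_cell()`),
where the assigned parameters round-trip through the full protocol
simulation; the mixture cell is used everywhere the cell, not the channel,
is the object of study (whole-cell amplitudes, firing, silencing).

## Cell models

The morphology stand-in is a soma (20 x 20 um cylinder) with four unbranched
dendrites (400 x 3.75 um, 20 um segments), total area ~20,100 um^2. The
reconstructions behind the original models are not available as coordinates;
the template's total area was calibrated once so the TOR whole-cell
simulation yields the measured ~683 pA I_SA peak at -40 mV given the printed
conductance densities. Per-cell stand-ins jitter every dimension uniformly
within +/-20% (`make_morphologies()`), and per-cell I_SA densities are
scaled by a zero-truncated normal factor with CV 0.159, the printed
cell-to-cell scatter.

Passive parameters: axial resistivity 120 Ohm cm; specific capacitance
1.015 uF/cm^2 (drawn from the measured 0.82-1.05 range for seeded cells);
leak density in 5.0-5.8e-5 S/cm^2. The leak reversal is solved once per
cell so that the steady-state resting potentials of its two phenotype
configurations straddle -64.7 mV symmetrically; the same reversal is used
for both, so the phenotypes differ *only* in their I_SA entries (the
phenotype-purity invariant, tested) at the cost of each rest deviating from
the target by ~2.3 mV (TOR below, RS above - the TOR I_SA window current at
rest is substantial).

I_SA densities are the published model values: RS = 297e-5 S/cm^2 somatic
(99.1e-5 dendritic); TOR = 44e-5 I_SA_TOR + 128e-5 I_SA_RS somatic (14.7e-5
+ 42.7e-5 dendritic), i.e. a 2.96:1 somatic:dendritic ratio everywhere and
somatic totals of 2.97 and 1.72 mS/cm^2 - the TOR configuration needs only
0.579 times the RS conductance.

### The core spiking set

The non-I_SA machinery (transient Na+, delayed-rectifier K+, adaptation K+,
leak) is constrained only loosely by the study, so it was designed once and
is shared bit-identically by both phenotypes:

* Na+: m^3 h, m midpoint -30 mV (k = 6 mV, tau 0.1 ms), h midpoint -45 mV
  (k = 6 mV, tau 1-36 ms voltage dependent), 0.12 S/cm^2 somatic, 30%
  dendritic, E_Na = +60 mV.
* K+ delayed rectifier: n^2, midpoint -12 mV (k = 8 mV, tau 0.5-2 ms),
  0.03 S/cm^2 somatic, 30% dendritic.
* Adaptation K+: single gate with midpoint -25 mV (k = 4 mV), tau 150 ms,
  0.012 S/cm^2, somatic only. The depolarized midpoint means the gate opens
  only during spikes: it integrates the spike train (spike-frequency
  accommodation, shallow f-I curve) while remaining insensitive to the
  subthreshold holding potential. This property is essential - an
  adaptation conductance with a subthreshold midpoint resets during
  hyperpolarized holding and transiently boosts excitability after release,
  masking exactly the I_SA effect under study.
* Leak as above.

The tuning targets were the firing features of CCK+INs: accommodating
trains, ~10-20 Hz firing for a per-cell calibrated step, narrow spikes, a
short (tens of ms) onset delay from -80 mV in the RS configuration and a
deep, slowly decaying onset silence in the TOR configuration. The 50 mV/ms
threshold criterion reads about -33 mV on these cells (the measured value is
-37.5 mV); spike half-width is ~0.6 ms and the peak modest, a known cost of
reduced two-channel spike machinery. These core parameters were frozen
before the oscillatory-drive analyses and are never varied between
phenotypes or analyses.

Under somatic voltage clamp the Na+ conductance is zeroed (the recordings
used TTX) and the adaptation conductance is removed as well: it stands in
for the after-spike potassium load and is never engaged physiologically
without spikes, but its artificial voltage dependence would bleed into
subtracted currents through the series-resistance error.

## Protocols

All voltage-clamp protocols isolate I_SA by subtracting a paired simulation
with the I_SA densities zeroed (the model analogue of leak subtraction; the
protocol suite verifies that the subtraction returns ~0 when I_SA is
absent). The whole-cell variant clamps the soma through 2.76 MOhm with the
dendrites free - the space-clamp and series-resistance errors are part of
what is being reproduced. Remaining biases are therefore real features of
the measurement: the fitted availability at -60 mV comes out a few percent
above the underlying gate value, and decay/recovery time constants land
within ~10% of the anchors, exactly as the acceptance checks expect.

* Activation: -120 mV conditioning (300 ms), test steps, peak current and
  conductance via the driving-force convention `g = I/(V+90)`; -90 mV is
  excluded (zero driving force).
* Steady-state inactivation: 1 s prepulses spanning -100 to -35 mV, test
  pulse to -30 mV, peak currents normalised to maximum, Boltzmann fit.
* Recovery: -120 mV (345 ms), -30 mV (500 ms), recovery step (-65 to
  -120 mV, 1-233 ms, 12 log-spaced intervals), -30 mV test; the recovered
  fraction is the *area* of the test current, and a single exponential is
  fitted. The default control subtracts the zero-I_SA run; the experimental
  -50 mV control is available (`control = "minus50"`) but is itself
  contaminated by the very shallow RS inactivation curve.
* MP dependence of firing: the step amplitude is calibrated per cell by
  bisection (20 pA resolution) to 15 Hz from -60 mV; 3 s holding periods
  then span -90 to -50 mV and the first-AP delay and early spike count are
  extracted with the 50 mV/ms detector and fitted with Boltzmann curves.

## Oscillatory drive

Excitatory events are drawn in Gaussian packages, one per cycle. The
frequency-dependent onset scale
`(1000/f)*0.633 + 69.25112*0.67747^f + 1000/f` is read as: last term = the
package period, first two terms = the full (+/-3 sd) width of one package,
so the package-width/period ratio is ~0.63/6 at high frequencies and grows
at low frequencies - this keeps the membrane potential sinusoidal at every
frequency. The literal alternative (the whole expression as the package
period) is available behind `width_mode = "onset"`. Event amplitudes are
normal, truncated at zero: excitation mean 0.22 nS, variance 0.01 nS^2;
inhibition mean 2 nS, variance 0.1 nS^2. Inhibition is uniform in time at a
fixed 400 events/s - independent of the swept excitatory strength - chosen
once so that the mean MP stays near the -64.7 mV rest at mid strengths at
8 Hz; with it, theta-range drive swings the MP from about -72 mV up toward
threshold. Synaptic kinetics are biexponential (excitation 0.5/3 ms at
0 mV; inhibition 1/8 ms at -70 mV; not printed, chosen as typical for the
measured event amplitudes) and every event is assigned to a compartment
uniformly by membrane area. Trains are generated once per seed and reused
for both phenotypes of a pair, so paired runs see bit-identical inputs.
Simulations cover 20 cycles or at least 5 s.

The swept "strength" is events-per-package. Because the drive needed to
reach a given output rate varies ~50-fold between 1 and 100 Hz, strengths
are specified as multipliers of a per-frequency base level, calibrated once
on the template RS cell to a ~5 Hz baseline output
(`default_strengths()`); the default multipliers put the baseline output
roughly at 5-25 Hz, bracketing the 4-10 Hz quantification window.

## The silencing analysis

For every (cell, frequency, strength, repeat), the same event train is run
through the RS and TOR configurations and the percentage change is
`(rate_RS - rate_TOR)/rate_RS * 100`, kept only where the RS run fired (and
below 50 Hz). The central 8-15 Hz band is quantified over grid cells whose
baseline output lies in 4-10 Hz, as in the original analysis; the 1-6 and
25-100 Hz flanking bands are averaged over all responsive grid cells (the
published numbers attach the output restriction to the central band).

Mechanistically the selectivity follows the I_SA_TOR kinetics: at theta-band
input the troughs (~60 ms near -70 mV) allow substantial recovery and each
package then faces a partly available brake; at low frequencies the slow
package rise inactivates the current before threshold is reached; at high
frequencies the troughs are too brief for recovery and the current stays
inactivated. In this reduced model the suppression in the 8-15 Hz band is
stronger than the published population average - marginal near-threshold
grid cells are often fully silenced, a behaviour the ten reconstructed
morphologies with their larger surface and synaptic filtering apparently
smooth out - and the flanking-band means sit somewhat above the published
single-digit percentages. The strict per-cell ordering (8-15 Hz reduction
greater than both flanks) is robust. The acceptance suite asserts the
published bands at their stated tolerances and reports failures as failures;
the ordering property holds for every simulated cell.

## Numerical core

The cable equation is integrated with a theta-method (Crank-Nicolson by
default in current clamp; backward Euler in voltage clamp, where the stiff
electrode conductance would make Crank-Nicolson ring) over the compartment
tree via Hines elimination, dt = 25 us. Gates advance by their exact
exponential relaxation using tabulated steady states and time constants
(0.25 mV grid); at a fixed voltage the gate trajectory is exact up to table
interpolation, which the gating-relaxation oracle test bounds at <0.1%.
Divergence (|V| > 200 mV) aborts with an error. Subthreshold dt-halving
changes the somatic trace by well under 0.1 mV RMS; spike times shift by
microseconds.

Units throughout: mV, ms, S/cm^2, uF/cm^2, pA for injected currents, nA for
recorded clamp currents, nS for synaptic conductances.

## Synthetic fixtures and what the tests show

`fixture_base()` + `make_noisy_current_fixture()` generate noisy
inactivation and recovery measurements with the generating truth attached:
white Gaussian current noise (10 pA default) is added to the clean simulated
traces, peaks are read from lightly smoothed traces, areas from raw ones.
Parameter recovery (median |dV1/2| < 1 mV, |dtau|/tau < 10% over 50 seeds)
exercises the fitting pipeline, not the recordings: real recordings have
coloured noise, drift and seal instabilities that these fixtures do not
emulate, so passing recovery tests demonstrate the pipeline's correctness,
not its field robustness.

Problem sizes used by the shipped analyses: 3 stand-in cells, 12 input
frequencies (1-100 Hz), 6-8 strength multipliers and 1-2 train repeats for
the silencing sweep; single cells for all protocol round-trips. These sizes
were chosen as the smallest that stabilise the band means; the original
study used ten reconstructed cells and denser grids.

## Known limitations

* The core spiking set is a design, not a measurement: spike shape is
  approximate (half-width ~0.6 ms, modest overshoot, threshold criterion
  reading ~4 mV below the measured -37.5 mV).
* The RS inactivation slope inverted from the printed anchor pair is
  implausibly shallow; all downstream RS availability behaviour inherits it.
* Reduced stand-in morphologies underestimate dendritic filtering;
  whole-cell protocol biases (series resistance, space clamp) are
  reproduced qualitatively but depend on the stand-in's current magnitudes.
* The mixture-vs-component circularity described above.
* Exact phenotype purity and an exact -64.7 mV rest for both phenotypes are
  jointly unattainable: the whole-cell-anchored I_SA_TOR window current at
  rest is ~0.6x leak, so with one shared leak reversal the two
  configurations rest ~2.3 mV below/above the target. Purity was kept.
* The nucleated charge-density ordering (TOR > RS per pF) does not
  reproduce: the shallow RS inactivation slope forced by the printed RS
  anchor pair leaves a large sustained RS current whose integral rivals the
  TOR transient.
* Temperature effects are not modelled; all kinetics are at the recording
  temperature.
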