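---
title: "From sliding gratings to spike trains: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sliding gratings to spike trains: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanospike)
```

This vignette explains the science behind the package: what each stage
models, which parameters matter and why their defaults were chosen, what
the synthetic data do and do not emulate, and where the design was
genuinely open.

## The problem

A person exploring a ridged surface with a fingertip receives, through
slowly-adapting type-1 (SA1) afferents, a temporal spike pattern locked to
the passage of ridges. Neuroprosthetic texture feedback reproduces that
pattern artificially: a sensorized fingertip slides over a grating, its
signal is converted in real time into spike events by an artificial
mechanoreceptor model, and each event triggers a current pulse injected
into the median nerve. The package implements that
mechano-neuro-transduction (MNT) chain end to end at desk scale, together
with the analyses that ask *which* neural code carries the texture
information, a three-alternative forced-choice (3AFC) discrimination
protocol with a synthetic observer, and a simplified biophysical model of
how needle microstimulation compares with an implanted intrafascicular
electrode (TIME).

## Stimuli and protocol

Gratings alternate ridges and grooves with spatial period SP (ridge onset
to ridge onset); the ridge width is fixed at 0.25 mm so the groove widens
with SP. The stimulus set pairs two half-surfaces per trial:

| label | first half SP (mm) | second half SP (mm) | ΔSP (mm) |
|-------|-----|-----|-----|
| Δ0.0  | 1.5 | 1.5 | 0   |
| Δ1.0  | 2.0 | 1.0 | 1.0 |
| Δ2.0  | 3.0 | 1.0 | 2.0 |
| Δ2.5  | 3.0 | 0.5 | 2.5 |

with a `"-"` order that swaps the halves. One trial indents the first
half at 400 mN for 4 s, slides it at 10 mm/s for 2 s, holds 2 s, and
repeats for the second half after a 3 s gap; the sensor samples at
380 Hz per channel. Sessions hold 16 trials (4 per surface, 2 per
order), randomized. All of these values are the protocol constants of
the experiments the package reproduces, exposed in `sliding_protocol()`
and `build_session()`.

## The synthetic sensor model

The original sensor data are not redistributed with the package, so a
generative stand-in (`synth_sensor_trace()`) produces two-channel traces
with the structure the encoder cares about. The model deliberately skips
continuum skin mechanics; it asserts only the facts the downstream
analyses rely on:

* at constant sliding velocity v, ridge onsets pass at a constant
  temporal spacing SP/v;
* each ridge crossing injects one shear transient into the differential
  channel (S<sub>x+</sub> − S<sub>x−</sub>);
* coarser gratings (wider grooves) produce longer and somewhat larger
  transients, because the fingertip sinks further into the groove;
* static phases carry only a common-mode indentation transient (which
  cancels in the differential), baseline and noise.

The transient kernel is a raised-cosine attack of 4 ms followed by a
raised-cosine release that fills the rest of the pulse width — the snap
off a ridge edge is fast, the relaxation into the groove slow. A fully
symmetric raised cosine was considered first; at coarse gratings its slow
rise delays the first spike ~25 ms after the geometric crossing, which
destroys the time-locking between bursts and ridges that the analyses
measure, so the asymmetric kernel was adopted. Width and amplitude scale
as power laws of groove/0.25 (exponents 0.6 and 0.52).

Three stochastic elements emulate features of real sessions:

* additive Gaussian channel noise (sd 3×10⁻⁵ sensor units, small enough
  that the encoder is silent during static phases);
* a per-trial lognormal gain jitter (sd 0.03) for contact-force and skin
  condition variability;
* a uniformly random initial ridge phase per half (`phase_jitter`): the
  alignment between the first ridge and slide onset is not controlled in
  a physical rig. This is statistically important: with the phase
  random, the expected number of crossings in the 2 s slide is exactly
  `2 v / SP` for every SP, so gratings whose period does not divide 2 s
  are not systematically favoured in spike counts.

Raw sensor amplitudes and noise levels are not quantified anywhere, so
the calibration is pinned instead by the published downstream properties: a
single spike per ridge at SP 0.5 mm, duplets/triplets at 1.0–1.5 mm,
bursts of ≥4 at 2.0–3.0 mm, near-constant average firing rate across
gratings, and burst onsets locked to ridge crossings. The defaults of
`sensor_calibration()` were fixed once against those properties and
frozen.

What the generator does **not** emulate: friction stick–slip, force-servo
dynamics, sensor hysteresis, skin viscoelasticity, or any amplitude
information beyond the groove-width power law. Passing tests therefore
show that the encoder and analyses behave as published *given* periodic,
ridge-locked sensor transients — not that these transients are an
accurate mechanical model of the MEMS fingertip.

## The encoder

`encode_trial()` chains the three published operations: channel
difference, half-rectification with gain K = 15 000, and an Izhikevich
neuron,

$$\dot v = 0.04 v^2 + 5 v + 140 - u + I, \qquad \dot u = a(bv - u),$$

with the regular-spiking parameter set a = 0.02, b = 0.2, c = −65 mV,
d = 8, spike threshold 30 mV, in the canonical millisecond/millivolt
convention. The printed unit annotations of those constants (e.g. "0.04/sV",
"C_m = 1 F") do not form a consistent dimensional system; since the
numbers are exactly the canonical dimensionless set and R·C_m = 1 makes
the input term numerically I, the canonical convention is implemented.

Integration is explicit Euler with dt = 0.1 ms under a zero-order hold
of the 380 Hz input; each 2.63 ms sample interval takes 27 sub-steps
with the remainder absorbed in the last. Whether the original real-time
system sub-stepped is unstated, so accuracy is guarded by convergence
tests instead: spike counts at dt and dt/2 agree within 2 % on encoded
traces, and constant-input runs match a 10× refined reference within one
spike. The initial state is the resting fixed point v₀ = −70 mV,
u₀ = b·v₀ (the root of the subthreshold system), which avoids spurious
onset transients. Divergence (non-finite state) raises an error naming
the offending sample.

## Temporal-code analysis

A **burst** begins at any spike whose preceding inter-spike interval
exceeds 25 ms (`segment_bursts()`). The threshold sits between the
largest intra-burst ISI the encoder produces (~16 ms at SP 3.0 mm) and
the smallest inter-burst interval in the stimulus set (50 ms at SP
0.5 mm); it is exposed for other regimes. The **IBI** is the interval
between consecutive burst onsets, summarised per trial by the median —
robust to clipped bursts at the slide edges. The **AFR** is the spike
count over the fixed 2 s slide. The instantaneous rate is the inverse
ISI assigned to the right edge of each interval.

For periodic sliding the IBI equals SP/v, so ΔIBI between the halves of
a pair is proportional to ΔSP (slope 100 ms/mm at 10 mm/s); the package
reproduces the published contrast in which ΔIBI regresses on ΔSP with
R² ≥ 0.997 while ΔAFR carries almost no information, because more
intense bursting compensates longer intervals.

The **spatial modulation index** quantifies how strongly firing is
modulated at the ridge frequency f = v/SP. No formula is published for
it, so the package defines one: spikes are binned at 5 ms, smoothed with
a fixed Gaussian kernel (σ = 15 ms, a receptor-like temporal integration
window), and the index is twice the Fourier amplitude of the smoothed
rate at f over its mean. The fixed smoothing window is what produces
the published monotone rise of the index with SP: fine gratings modulate
at frequencies the window suppresses, coarse gratings modulate well
within it. Without smoothing, a bare Fourier index is instead maximised
by the single-spike-per-ridge comb of the finest grating, the opposite
trend. The index is 0 for unmodulated firing and approaches 2 for firing
fully concentrated at f (at periods long relative to σ).

## The synthetic observer and behavioural statistics

`ideal_observer()` closes the loop without a human: it reads the ΔIBI of
a presentation, adds Gaussian decision noise, answers "same" when the
noisy value is within ±τ and otherwise names the half with the larger
IBI coarser. τ defaults to 50 ms, half the smallest nonzero |ΔIBI| in
the stimulus set, maximising the margin between "same" and "different".
With zero decision noise the four ΔIBI values (0, ±100, ±200, ±250 ms)
are perfectly separable and the observer scores 100 %; rising noise
degrades performance monotonically. The observer is a decoding
benchmark, not a model of human perception: it has no lapses, no bias
and no learning.

Behavioural statistics follow the published procedures: exact
Clopper–Pearson binomial intervals (implemented by root-finding on the
binomial CDF; the beta-quantile closed form serves as an independent
oracle in the tests) compared against the 1/3 chance level, and logistic
psychometric fits by binomial GLM on the one-dimensional |ΔSP| axis with
R² taken as the squared Pearson correlation between observed and fitted
fractions. Complete separation (a perfect observer) is reported with
capped coefficients and a convergence flag rather than an error.

## The nerve recruitment model

The published comparison of needle microstimulation with an implanted
TIME used a finite-element volume conductor of a segmented median nerve
coupled to MRG axon models. The package replaces the FEM stage with an
analytic point-source potential in an unbounded anisotropic medium,

$$V = \frac{I}{4\pi\sqrt{\sigma_y\sigma_z\,\Delta x^2 + \sigma_x\sigma_z\,\Delta y^2 + \sigma_x\sigma_y\,\Delta z^2}},$$

with the published conductivities (endoneurium 0.0826/0.0826/0.571 S/m,
fibers along z) and a scalar attenuation of 0.3 per perineurium sheet
crossed between source and fiber (within-fascicle sources cross none,
adjacent sources one, shielded sources two — the shield fascicle's two
sheets). The attenuation value is not published; it is a configurable
default validated only through relative properties. Absolute voltages
and charges are consequently **not** claimed; the quantities the model
is used for — threshold orderings across placements, monotone
recruitment, and the needle-vs-TIME equivalence — are relative and
survive the simplification. A finite-difference Poisson solve on a
small grid cross-checks the analytic field in the tests.

Axons are 21 nodes of Ranvier (internodal spacing 100·D, nodal length
1 µm, nodal diameter D/3, axon diameter 0.7·D) with MRG-style fast
sodium, persistent sodium, slow potassium and leak currents at the
nodes; myelin is treated as perfectly insulating, so nodes couple only
through internodal axial resistance (ρᵢ = 70 Ω·cm). The membrane
equation advances by backward Euler with a tridiagonal solve
(conductances frozen within a step, exponential-Euler gates), 1 µs steps
during the biphasic pulse and 5 µs after, over a 3 ms horizon. A fiber
is recruited when its last node fires (depolarisation past 0 mV), the
published criterion; thresholds come from a doubling bracket plus
bisection to 1 % in amplitude. The model reproduces the standard cable
properties the comparison depends on: thresholds fall with fiber
diameter and rise with electrode–fiber distance.

Fiber populations emulate anatomical uncertainty: 100 touch/pressure
afferents per fascicle (diameters Gaussian, mean 9 µm, sd 2 µm,
truncated at 3 µm — the published source cites a distribution without
printing parameters; these are declared defaults), placed uniformly in
nested discs from full-fascicle spread (population 1) down to tight
clusters (population 9 in large fascicles, 5 in medium, 1 in small),
with random centroids and a random axial offset of the node grid.
The simulation plan crosses 3 placements × (9+5+1) populations, one
case per cell for the needle and two for TIME (mirrored left/right
sites, ±0.2 mm), giving the published 45 and 90 cases. Equivalence is
assessed, as published, by the Kruskal–Wallis test on the charge at 10 %
recruitment (linear interpolation on each curve) at α = 0.05.

## Numerical and scale choices

* Sub-second quantities are held in seconds in spike trains and in ms in
  burst/IBI summaries, matching how each is discussed in the field.
* The acceptance analyses run at deliberately reduced problem sizes
  chosen as the package's own defaults for desk-scale work: 10 seeded
  repetitions of the four stimulus pairs for the regression contrast,
  5 sessions (80 trials) for the behavioural loop, and 20 fibers per
  fascicle across the full 135-case plan for the recruitment comparison.
  The statistical conclusions they support (R² contrast, rank-test
  equivalence, threshold orderings) are stable at these sizes.
* The recruitment charge grid is fine (1 nC) up to 100 nC and coarser
  (3 nC) up to 1500 nC, so intrafascicular thresholds are resolved
  without making shielded placements unreachable.
* Ties in burst segmentation cannot occur (spike times are strictly
  ordered); an empty train segments to an empty result rather than an
  error, and undefined IBIs (fewer than two bursts) are flagged and
  propagated, never silently zeroed.

## Known limitations

* The sensor model is phenomenological; amplitude-level conclusions
  about the MEMS device cannot be drawn from it.
* The observer decodes ΔIBI only; it cannot exhibit the training effects
  or lapses that separate real amputee and intact-subject performance.
* The volume conductor is unbounded and homogeneous outside the
  perineurium attenuation; bounded-domain effects (the saline cylinder
  of the original model) and finite electrode geometry are not
  represented, so absolute recruitment charges are indicative only.
* EEG-level validation of the stimulation (cortical responses) is out of
  scope entirely.
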