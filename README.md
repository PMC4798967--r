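# mechanospike

Neuromorphic tactile encoding, temporal spike-train analysis, and
peripheral-nerve recruitment modelling in R.

## The problem

Restoring texture sensation through a hand neuroprosthesis requires
turning the signal of an artificial fingertip into electrical spike
trains that the nervous system can interpret. When a ridged grating
slides under a fingertip at constant velocity v, each ridge passage
evokes a burst of afferent spikes, so the inter-burst interval (IBI)
encodes the grating's spatial period SP as

    IBI = SP / v,

a temporal code that survives even though the *average* firing rate
(AFR) barely changes across gratings — coarser surfaces fire larger
bursts at longer intervals. `mechanospike` implements this
mechano-neuro-transduction (MNT) chain and the analyses around it, for
researchers in neuroprosthetics and tactile neuroscience who want a
desk-scale, fully reproducible counterpart of the published pipeline:

* **Synthetic touch** — a generative model of a two-channel MEMS
  fingertip (380 Hz) sliding over gratings (SP 0.5–3.0 mm, ridge width
  0.25 mm, 10 mm/s, 400 mN) under the full indentation/slide/hold
  protocol.
* **MNT encoder** — differential shear signal S_x = S_x+ − S_x−,
  half-rectified drive I_x = K·max(S_x, 0) with K = 15 000, and an
  Izhikevich regular-spiking neuron
  (dv/dt = 0.04v² + 5v + 140 − u + I, du/dt = a(bv − u);
  a = 0.02, b = 0.2, c = −65 mV, d = 8, v_th = 30 mV) emitting the
  spike train (C++ core).
* **Spike coding** — burst segmentation, IBI/AFR/instantaneous-rate
  metrics, spatial modulation index, ΔIBI- and ΔAFR-vs-ΔSP regressions,
  ANOVA with Tukey–Kramer contrasts.
* **Psychophysics** — randomized 16-trial 3AFC sessions, an
  ideal-observer decoder on ΔIBI, confusion matrices, exact
  Clopper–Pearson intervals against the 1/3 chance level, logistic
  psychometric fits.
* **Nerve recruitment** — analytic anisotropic volume conductor,
  21-node myelinated axons with active nodes of Ranvier (C++ core),
  fiber populations, recruitment curves, and the Kruskal–Wallis
  equivalence test between needle microstimulation and an implanted
  intrafascicular (TIME) electrode across 45 + 90 simulated cases.

## Worked example

```r
library(mechanospike)

# one trial: grating pair D2.0 (first half SP 3.0 mm, second 1.0 mm)
pair  <- make_stimulus_pair("D2.0", "+")
trace <- synth_sensor_trace(pair, seed = 42)
enc   <- encode_trial(trace)

m1 <- compute_metrics(enc$halves[[1]], slide_duration = 2)
m2 <- compute_metrics(enc$halves[[2]], slide_duration = 2)
c(ibi_first = m1$ibi_median, ibi_second = m2$ibi_median,
  afr_first = m1$afr, afr_second = m2$afr)
#>  ibi_first ibi_second  afr_first afr_second
#>      300.0      100.0       21.0       20.5
```

The first (coarse, 3.0 mm) half bursts every 300 ms, the second (fine,
1.0 mm) every 100 ms — the IBIs are SP/v exactly — while the average
firing rates are nearly identical: the interval code separates the
textures, the rate code does not.

The full behavioural loop, with the ideal observer standing in for the
subject:

```r
report <- run_pipeline(default_config(n_sessions = 5), seed = 1)
report
#> Pipeline report (seed 1): 5 sessions, 80 trials
#>   proportion correct: 1.000 (95% CI 0.955-1.000; chance 0.333)
#>   delta-IBI ~ delta-SP: slope 100.0 ms/mm, R^2 = 1.0000
#>   delta-AFR ~ delta-SP: slope -0.12 sp/s/mm, R^2 = 0.0158
#>   psychometric logistic fit: R^2 = 1.000
```

ΔIBI tracks ΔSP essentially perfectly (R² ≥ 0.997, slope 100 ms/mm at
10 mm/s) while ΔAFR explains almost nothing — the contrast at the heart
of the temporal-coding argument.

A reduced nerve-recruitment comparison (20 fibers per fascicle over the
full 135-case plan; a few minutes):

```r
res <- run_recruitment_plan(seed = 3, n_fibers = 20)
compare_devices(res)
#> Charge at recruitment level: needle median 22.50 nC (n=45), TIME median 23.50 nC (n=90)
#> Kruskal-Wallis p = 0.74 (not different at alpha = 0.05); 0 case(s) excluded
```

Needle and intrafascicular stimulation need statistically
indistinguishable charges for 10 % recruitment, the model result that
justified moving from acute needle experiments to the implanted
interface.

A command-line front end over the same functions lives in
`inst/cli/mechanospike.R` (subcommands `simulate`, `encode`, `analyze`,
`session`, `recruit`, `pipeline`).

## Package layout

* `R/stimuli.R`, `R/sensor.R` — gratings, stimulus pairs, protocol,
  synthetic sensor traces
* `R/encoder.R`, `src/izhikevich.cpp` — the MNT encoder
* `R/coding.R` — bursts, IBI/AFR/SMI, coding statistics
* `R/psychophysics.R` — 3AFC sessions, observer, behavioural statistics
* `R/recruitment.R`, `src/axon.cpp` — volume conductor, axon model,
  recruitment curves, device comparison
* `R/io.R` — raster bundles, configuration, the end-to-end pipeline
* `vignettes/methods.Rmd` — models, assumptions, parameter rationale,
  limitations
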