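---
title: "Methods: the microbump cascade model and noise analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the microbump cascade model and noise analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`microbump`: the stochastic cascade model and its calibration, the
statistical conventions, the composite-response and noise machinery,
and the places where a design was genuinely open and a choice had to be
made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The single-microvillus cascade model

One photon activates one metarhodopsin (M\*) at `t = 0` in a microvillus
holding a pool of ~50 Gq proteins, ~70 PLC molecules, ~3000 PIP~2~
substrate lipids and 25 TRP channels. The reaction scheme is a compact
rendering of the published Drosophila microvillus models:

* M\* catalyses GDP→GTP exchange on Gq at the control rate 333 s^-1^
  (the per-encounter rate scales with the remaining free-G fraction);
* free Gα finds PLC at a diffusion-limited encounter rate
  (`k_bind = 1000` s^-1^ at control PLC density) to form the active
  Gα·PLC complex;
* each complex hydrolyses PIP~2~ to DAG at the control rate 1428 s^-1^
  (scaled by substrate depletion);
* TRP channels open at a rate driven by a steep Hill function of the
  DAG count (exponent 8, half-drive at `dag_k / sensitivity` with the
  control sensitivity 0.34) and close at a basal 30 s^-1^;
* a single deterministic calcium variable integrates the open-channel
  current and feeds back *saturably* (`Ca/(Ca_half + Ca)`): positively
  on channel opening (fast regenerative rise) and negatively on channel
  closing, DAG removal, complex turnoff and M\* shutoff (bump
  termination).

**Integration.** The simulator advances on a fixed 0.1 ms grid, drawing
per-molecule binomial transitions with exact per-step hazards
`1 - exp(-rate * dt)`. For constant within-step hazards this is exact
per molecule, at any copy number, so no separate exact-SSA branch is
needed — this is the one deliberate deviation from the "tau-leap with
SSA fallback" sketch: binomial stepping already has the correct
low-count statistics, and the dominant error (hazards frozen across
0.1 ms) is identical in both schemes. Trajectories end early once the
cascade is extinct (all species zero, M\* off), which roughly triples
throughput.

**Calibration.** The five activation parameters and the channel count
are fixed by their printed control values (333 s^-1^, 100%, 100%,
1428 s^-1^, 0.34, 25 channels). The remaining rate constants are not
printed anywhere; they were calibrated *once* so the control ensemble
matches three anchors — mean bump amplitude ≈ −70.8 pA, median 10%
latency ≈ 30 ms, latency scatter ≈ 6.6 ms — and then frozen in
`default_kinetics()`. `single_channel_current = -5.85` pA converts the
mean peak open-channel count (~12 of 25) into the amplitude anchor. The
calibrated control ensemble additionally shows the expected qualitative
structure: ~95% bump probability per photon, fewer than half the
channels open in most trials, amplitude CV ≈ 0.4, and the
within-ensemble correlation fingerprint (amplitudes correlate with the
molecular maxima but not their times; latencies correlate with the
times, increasingly so towards the channel-facing stage).

**PKC.** Light-adapted termination is modelled by
`pkc_activity_factor`, which multiplies the *Ca-dependent* termination
terms only (channel closing, DAG removal, complex and M\* shutoff
accelerations). Applying the factor to the basal activation-phase rates
instead abolishes all bumps at 100× activity, contradicting the
physiological picture in which strong PKC activity yields small, narrow
— but present — bumps.

**Known limitations of the cascade.** (1) Across the parametric sweep
the half-width CV does not cluster near the experimental 0.23; it spans
roughly 0.2–1 and grows in slow cascades, whose ragged, low-amplitude
bumps are measured at their outermost 50% crossings. Analyses that need
the experimental half-width dispersion therefore take CV 0.23 as an
*input* (as the original analysis also does). (2) The within-run
size-vs-time correlation for DAG is weakly negative rather than
non-significant. (3) The 10%-Gq setting has a bump probability of only
~0.3 at the −7 pA threshold, below the ~0.65 floor of the reference
runs; criterion tests raise the trial count so every setting still
yields ≥ 60 bumps.

## 2. Statistical conventions

Latencies are summarized by a lognormal fit in closed form
(`μ = exp(mean(log x))`, `σ = sd(log x)`), with the dispersion reported
as the scatter `μ·sinh σ`. The scatter interval `[μ/e^σ, μe^σ]` holds
`Φ(1) − Φ(−1) ≈ 2/3` of the probability for every `(μ, σ)`; at the
dispersions typical of bump latencies (`σ ≈ 0.22`) the scatter and the
plain sample SD agree within ~10% and are used interchangeably (the
extraction algorithm consumes the SD). A binned-density fit is provided
as a cross-check and agrees with the log-moment fit within a few
percent on `σ`. Amplitudes, half-widths and rise slopes use mean ± SD
(their distributions are approximately normal). Rank correlations use
average-rank ties, with exact permutation p-values (full enumeration)
for n ≤ 10 and the t approximation above.

## 3. Composite responses, flicker and the corner frequency

Composite responses are sums of latency-shifted QBs. Flicker frequency
responses replicate a waveform at the stimulus period and sum *to exact
steady state* — every copy overlapping a central ≥ 3-period window is
included, so the "one more copy changes nothing" criterion is satisfied
by construction — and read the signal as `(max − min)/max` over that
window. The construction matches the closed-form Poisson-summation
(Fourier-series) oracle for Gaussian pulses to < 0.1%.

**The 3 dB convention (a deliberate deviation).** The corner frequency
is read off a three-parameter decreasing Hill fit
`S(f) = S0 / (1 + (f/f_h)^n)`. Two readings of "3 dB" are possible:
the amplitude convention `S0/√2` and the signal-halving convention
`S0/2` (which for the Hill form is exactly `f_h`). With the `S0/√2`
reading, the reciprocal bandwidth constant fitted across the standard
composite grid comes out near 620 Hz·ms; with the `S0/2` reading it
comes out near 730 Hz·ms, the literature value, with Hill exponents of
5–6 on these waveforms. `fit_hill_corner()` therefore defaults to
`ref = "half"` and keeps `ref = "sqrt2"` as an option. This overrides
the original "amplitude 1/√2" design sketch because the implementation
showed that reading to be irreconcilable with the published constant.

**Composite half-width relation.** The half-width `b` of a composite
exceeds the mean QB half-width `x` because of the latency SD `a`; the
sum rule `b ≈ x + a` holds for `x/a ≥ 4` (the plateau of `(x+a)/b` is
≈ 1.07, constant to a few percent) and underestimates `b` below that.
`composite_halfwidth_relation()` calibrates polynomial maps in both
directions on dense, noise-free convolutions of lognormal QBs with
lognormal latency densities; the degree is chosen by leave-one-out
cross-validation, and the fitted coefficients are derived artifacts
stored with the calibration object. The latency-density family fixes
scatter/median at 0.22, the pooled experimental proportionality. When
the relation is built for inverting impulse responses generated by
*variable-width* QBs, the calibration optionally bakes in the
half-width mixture (normal time-dilation factors at the table's CV):
a mixture of dilated waveforms is wider than the waveform of the mean
width, and ignoring that inflates the recovered half-width by ~50% at
CV 0.23.

## 4. Noise, SNR and information capacity

The signal is the area under the average composite; the noise is the
area under the pointwise SD trace across ≥ 50 (typically 100–150)
members; their ratio is the SNR. Half-width variability is implemented
as time-axis dilation with amplitude preserved — member areas then
covary with width, which is the reading adopted for "bumps with varying
shapes but same amplitudes"; area-preserving dilation is the
undocumented alternative. Amplitude factors are normal, truncated at
0.05 to avoid sign flips. Photon noise draws the per-member QB count
from a Poisson distribution; zero-QB members contribute flat traces and
are counted, not dropped. In the no-variability limit the measured SNR
at mean count n equals √n within Monte-Carlo error; with any
transduction variability it is strictly smaller.

The relative strengths of the noise sources depend on the ratio of QB
half-width to latency scatter. At the control-anchored geometry
(~13 ms bump against a 6.6 ms scatter) latency dispersion alone
suppresses the 100-QB SNR more than half-width (CV 0.23) and amplitude
(CV 0.3) variability combined, and adding either on top of latency
costs < 20% — for wide bumps (x/a ≳ 3) the ordering can invert, which
is why the test suite pins the bump geometry it uses. The three sources
are non-additive in all regimes probed.

`capacity_surface()` maps SNR, corner frequency and
`IC = B log2(SNR + 1)` over a grid of mean half-width × latency SD,
taking half-width CV 0.23 and amplitude CV ∈ {0, 0.3} as inputs, the
corner from the reciprocal law applied to the measured composite
half-width (constant 730 Hz·ms by default, re-derivable via
`fit_reciprocal()`), and the median latency co-varying with the
dispersion through the 0.22 proportionality unless fixed explicitly.

## 5. Extraction of QB statistics from impulse responses

`calibrate()` fits five relations on a calibration table (a cascade
sweep or a synthetic-population family): r1 maps the impulse 10%
latency to the median (and mean) QB latency, through the origin — with
no latency dispersion a composite starts where the aligned average QB
starts; r2 maps median latency to scatter (and mean latency to SD),
through the origin; r3 is the composite half-width relation above; r4
maps mean half-width to half-width SD through the origin; r5 is a free
linear map from median latency to amplitude CV, the model-side
association that experiments only partly support — extraction therefore
returns both the r5 value and the fixed fallback CV 0.3 (the
group-average experimental value), and downstream SNR analyses accept
either. `extract_from_impulse()` applies the stages in order and aborts
with the stage identifier on any non-positive intermediate; stage-3
inputs outside the calibrated `b/a` range are flagged as extrapolation.
Closed-loop validation (`roundtrip_validate()`) recovers all five
statistics of a control-anchored synthetic population within 10% when
the extracted values are averaged over a handful of 100-QB responses
(a single 100-QB response carries ~10% Monte-Carlo noise of its own);
the systematic component of the error is ≲ 4%. Accuracy degrades, as
expected, once `x/a` drops below 1.

## 6. The synthetic-data generators and what a green test establishes

The generators emulate exactly the statistical structure the analysis
assumes: lognormal latencies (median + scatter, with
`σ = asinh(scatter/median)`), normal half-width dilation factors,
normal amplitude factors truncated at 0.05, Poisson photon counts, and
the "paper-like" family convention scatter = 0.22 × median latency
(which reproduces the 6.6/29.6 ms anchor; a convention, not a printed
constant). Generated QB waveforms are lognormal with peak time 1.5 ×
half-width by default, and the shape width solves the requested
half-width in closed form, `w = asinh(h/2t_p)/√(2 ln 2)`. The
generators do **not** emulate recording-noise floors, electrode
artifacts, membrane nonlinearities beyond a single-pole RC filter, or
multi-microvillus adaptation — so a green test establishes fidelity of
the analysis chain on clean, correctly-distributed inputs, not
robustness to real recording conditions.

## 7. Numerical choices and reproducibility

* Simulation step 0.1 ms; waveform/flicker grids 0.1 ms; composite
  grids 0.5 ms (0.1 ms where half-widths are measured to sub-percent).
* Threshold crossings by linear interpolation between samples; the
  half-width of a multi-crossing profile uses the outermost 50%
  crossings around the global peak and warns.
* Hill and lognormal-waveform fits run Nelder-Mead on log-scaled
  parameters from data-driven starts; non-convergence is an error, not
  a silent fallback.
* Every stochastic entry point takes an explicit integer seed;
  per-trial sub-seeds come from a counter-based linear scheme kept
  below 2^31. Identical seeds reproduce results bit-for-bit; the RNG
  state of the caller is always restored.
* Test-suite Monte-Carlo sizes are scaled down (60–250 trials or
  members) relative to full-scale runs (200 trials, ~120 members);
  the acceptance criteria state where.
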