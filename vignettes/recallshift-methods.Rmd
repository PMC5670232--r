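---
title: "Methods: baseline-shift analysis of ECoG free recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline-shift analysis of ECoG free recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and design decisions
behind `recallshift`: what each stage computes, which parameters matter,
what the synthetic generator does and does not emulate, and where the
design was genuinely open.

## The measurement model

High-frequency broadband amplitude (HFB, 60–160 Hz; "high gamma") tracks
local population firing. The package treats a recall-period electrode trace
as a non-negative amplitude process whose logarithm is approximately
Gaussian; all sustained effects are expressed as multiplicative amplitude
gains, reported in decibels with the amplitude-ratio convention
`dB = 10·log10(ratio)` (so +0.5 dB multiplies amplitude by ~1.122). Medians
are the primary location statistic during recall blocks because they are
invariant under the monotone dB transform and robust to transient bursts —
which is precisely the contrast the burst/shift discrimination exploits.

## Preprocessing

* **Notch bank.** Band-stop Hamming FIR designs (order 500, ±2 Hz about
  each harmonic of the line frequency below Nyquist) applied zero-phase.
  Zero-phase filtering is realized as forward–backward application, so the
  effective attenuation is the square of the single-pass design; the bank
  is applied as one composite magnitude-squared frequency response per
  channel (mathematically identical for linear-phase FIRs, one FFT round
  per channel). Passband ripple stays below 0.1 dB; each harmonic is
  attenuated far beyond the 20 dB the analyses require.
* **Bad channels.** A channel is rejected when the mean of |V| over the
  samples above that channel's own 99th percentile exceeds 500 µV. The
  criterion is applied to absolute voltage: a raw-voltage reading is
  sign-ambiguous, and the absolute value is the conservative choice.
* **Transient artifacts.** A sample is an outlier event when at least 10%
  of channels exceed 5 SD of their own voltage or a 30 µV/ms gradient
  (first difference × rate; the boundary sample reuses the forward
  difference). A **centered** 200-ms window (±100 ms — the symmetric
  reading of "around" the event) is marked per event. Masked samples are
  excluded from every downstream statistic but stay in the time base, so
  event alignment never shifts. Per-channel SDs are computed over the whole
  recording in a single pass; no iterative re-masking is attempted.

## HFB extraction

Five contiguous 20-Hz bands (60–80 … 140–160 Hz), each band-passed with an
order-138 zero-phase Hamming FIR, enveloped by the magnitude of the FFT
analytic signal, divided by its own mean (this equalizes the bands against
the 1/f spectral decay), averaged, and rescaled by the mean band amplitude
so the output is in volts. Decisions:

* The per-band mean of step 3 is taken over the full recording excluding
  artifact-masked samples; this makes step 5's "mean across bands"
  well-defined, and any per-electrode scale cancels later in the
  rest-normalization anyway.
* One cosine taper of one filter length (139 samples, ~0.28 s) is applied
  at each recording edge before the Hilbert step. Without it, the filter
  edge transients bleed through the *global* analytic transform into bands
  that carry little power, corrupting their normalized envelopes. The taper
  touches only the outermost 0.28 s, which no analysis window reaches.
* Viewing epochs span −0.5…+1.75 s inclusive (1126 samples at 500 Hz), and
  are re-expressed as fractional change with **one scalar divisor per
  electrode per run** — the −400..−100 ms pre-stimulus mean averaged over
  all that run's trials. Recall-period traces are normalized by the
  geometric mean (`exp(mean(log))`) of the unmasked rest samples of their
  own run; for log-normal amplitudes the geometric mean equals the median,
  so the normalized rest median is 1 (0 dB) by construction.

## Electrode classification

Responsiveness: per-trial 100–500 ms response vs per-trial −400..−100 ms
baseline, paired two-tailed t, with all electrodes' p-values pooled into a
single Benjamini–Hochberg correction at α = 0.01. Latency: the same pairing
applied at every post-stimulus sample; the latency is the first sample of a
p < 0.05 run lasting ≥ 50 ms (25 consecutive samples at 500 Hz). Category
selectivity: two-sample t on per-trial dB responses with FDR over the
responsive set (the correction scope is stated only as "corrected" in the
field's convention; pooling over the tested set is the standard reading);
classic equal-variance t by default with Welch behind a flag. The CSI
normalizer — "the maximal stimulus response" — is taken as the electrode's
largest single-item mean response, because the CSI inputs are item-level
means; the normalizer cancels in the CSI ratio, so only its positivity
matters. Groups: V1/V2 need both the anatomical label and latency ≤ 180 ms;
face/place labels apply outside V1/V2; intermediate retinotopic electrodes
without category selectivity keep their anatomical label; the rest are
`other`. Item ranking pools both runs (each run shows a different picture
set, and the preferred/non-preferred contrast wants the electrode's overall
favourites); ties break by item id so rankings are reproducible.

## Baseline-shift analysis

The block median (per electrode × recalled category, masked samples
dropped, averaged over runs) is the core quantity; selectivity is
preferred-minus-non-preferred. "Preferred category" is defined only for
face-/place-selective electrodes, so selectivity is computed for those; V1,
V2 and intermediate electrodes enter the overall recall-vs-rest contrasts
instead. The exclusion control removes 2 s before each recall onset through
its offset (all recall events, including intrusions). Stages are the three
50-s thirds of each block. The recall-order analysis renormalizes each
run's recall session by its own mean amplitude before taking medians, which
removes run-to-run baseline differences and isolates the first/second
targeting effect; the result feeds the mixed model.

## Burst vs shift discrimination

The simulation models operate on a measured (or synthetic) dB trace:

* *burst*: rectangular pulses (default 1 s) totalling the occupancy
  fraction, placed uniformly at random without overlap, smoothed by a 3-s
  Gaussian window before addition. The Gaussian has sd = 0.5 s (support ±3
  sd = the stated 3-s width) and **unit area**: unit area preserves the dB
  amplitude of a sustained burst and makes the mean added component equal
  occupancy × amplitude, which is the arithmetic the percentile analysis
  relies on.
* *shift*: a constant gain added to a coverage fraction of samples (a
  random subset below full coverage — occupancy in distribution is all the
  percentile statistics see, and a subset is simpler than contiguous
  spans).

Percentile profiling bins each trace into 10 equal-probability deciles of
its own distribution and differences the bin means. The cohort
classification calls a set of electrodes *baseline-shift-like* when the
signed-rank test on per-electrode overall gains is significantly positive
while the Kruskal–Wallis across deciles is not (both at α = 0.05 — the
published analyses report the two p-values without declaring a rule, so the
conventional level is used), and *burst-like* when the deciles differ with
an increasing trend. Per-electrode gains are computed first and then
aggregated (matching SEM-style error reporting), not pooled across samples.
One numerical guard: gains are snapped to 10⁻⁹ dB before the across-decile
rank test so that an exactly constant injected gain remains an exact tie
under floating-point bin arithmetic.

## Event-locked machinery

Traces are smoothed with a 1000-ms unit-area triangular window (edges
renormalized over the valid support), epoched at −5…+7 s, converted to dB,
and averaged within electrode; onsets closer than 5 s to the previously
retained onset are dropped in sorted order. The cluster statistic is the
sum of |t| over a maximal run of samples with p below the 0.05
cluster-forming threshold ("cluster mass" — the common default for the
"successive t-test" family); the null distribution of the maximum mass
comes from shuffling condition labels over electrodes (sign flips for
paired contrasts, label permutations for two-sample ones). Intrusion and
prompt contrasts are two-sample because their event sets need not co-occur
within an electrode. Prompt analyses normalize each epoch by its own
−5..−1 s pre-prompt mean and keep only prompts ≥ 7 s before the next
recall; ROI analyses normalize by −5..−3 s and summarize each electrode by
the baseline vs −1..+1 s transient bin pair. Triangular smoothing can bias
a step-onset estimate by up to half the kernel width; cluster onset times
are interpreted with that caveat rather than deconvolved. Repeated
recollections of the same item count as separate events, subject only to
the separation filter.

## Multitaper spectra

Slepian tapers are computed from the symmetric tridiagonal formulation
(dense eigendecomposition up to n = 1024; longer windows use spline
interpolation from an n = 801 solution followed by Gram–Schmidt
re-orthonormalization, accurate to ~10⁻⁴ in taper amplitude — far beyond
what power averaging can resolve). `NW = (K+1)/2` is the standard relation
behind the stated taper counts: 5-s segments with 7 tapers give a 0.8-Hz
half-bandwidth (the "1 Hz resolution" of common usage rounds this), and
25-s segments with 4 tapers give exactly 0.1 Hz. Segments are demeaned,
zero-padded to 2¹² (raw LFP) or 2¹⁴ (HFB fluctuations), and averaged over
tapers then segments with one-sided density scaling (the convention cancels
in all reported gains). Raw-LFP conditions: rest, continuous-viewing cuts
(the spectra are not stimulus-locked), 5-s windows centered on recall
onsets, and inter-recall intervals running from each recall offset to 2 s
before the next onset. HFB-fluctuation epochs overlapping the artifact mask
are dropped whole — interpolating inside a 25-s epoch would distort exactly
the ultra-slow band of interest.

## The mixed-effects contract

Group analyses fit `response ~ fixed factors (crossed) + (1 | patient /
electrode)` by REML with Type-III F tests and Kenward-Roger degrees of
freedom (Satterthwaite as fallback). Random slopes are omitted — with per
electrode × condition medians as observations they over-parameterize the
model. The contract targets the direction and significance of effects;
exact F values depend on the particular cohort.

## The synthetic generator

Each channel is `carrier_uv · exp(z(t)) · g(t) · c(t) + noise_uv · b(t)`:

* `z` — AR(1) Gaussian log-envelope, sd 0.4 (≈1.7 dB), autocorrelation
  time 1 s, innovated at 50 Hz and interpolated to the signal rate. The
  envelope of band power is a slow signal; an AR(1) innovated at the full
  500 Hz would carry a white modulation floor to Nyquist and smear carrier
  sidebands across the whole spectrum. Log-normality of HFB amplitude is
  the one distributional fact the analyses lean on; AR(1) is the minimal
  temporal structure that also produces realistic ultra-slow fluctuations.
* `c` — unit-RMS random-phase carrier spanning 60–160 Hz, synthesized in
  the frequency domain at exactly the trace length (truncating a longer
  periodic synthesis would leak an f⁻² floor across the spectrum).
* `b` — 1/f background with PSD slope −2.5.
* `g` — the task-locked multiplicative gains: per-item viewing gains
  (~2.5× preferred / 1.2× non-preferred at selective electrodes, 50-ms
  raised-cosine onset at the group's latency, sustained to offset), a
  sustained preferred-category recall-block gain (default 0.5 dB, the size
  seen in strongly selective electrodes), signed ±0.17-dB recall-locked
  transients spanning −1.5…+2 s around onsets, optional sporadic bursts,
  a transient collapse of the shift over −2…+1 s around intrusion onsets,
  and a pre-prompt decline with post-offset recovery for preferred-category
  prompts.
* Amplitudes: carrier 4 µV mean envelope against 12 µV background RMS.
  These proportions mirror real recordings, where high gamma is a small
  rider on the low-frequency LFP; a hotter carrier would itself trip the
  30 µV/ms artifact gradient rule, and with the −2.5 background slope the
  in-band background power is ~5% of carrier power, so injected dB gains
  survive the filter bank with ≲0.03 dB compression.

Task-structure defaults follow the protocol exactly: 200-s rest, 14
pictures × 4 repetitions at 1500 ms + 750 ms ISI per run, 40-s distraction,
two 150-s recall blocks per run with the category order counter-balanced
across the two runs, 11.5% intrusion rate. Recall onsets follow an
inhomogeneous Poisson process whose rate halves every 75 s (initial rate
0.08/s, ~6–7 events per block), with uniform 2–6-s durations and a 1-s
minimum onset gap, so the early recall stages contain more events than the
late ones and the 5-s separation filter has work to do. Inter-recall
interval distributions are not published per patient; these defaults are
plausible rather than fitted. The default cohort is one synthetic
"patient" of 24 electrodes (2 V1, 2 V2, 2 intermediate, 6 face-selective,
6 place-selective, 2 other, 2 frontal, 2 parietal) — enough selective
electrodes for the dynamics classification, small enough to run in
minutes.

**What the generator does not emulate:** spike trains, realistic
epileptiform morphology (only the threshold rules are exercised),
anatomically realistic forward models or volume conduction, cross-electrode
correlation beyond the common task structure, non-stationary background,
or behaviourally realistic recall content. Passing parameter-recovery
tests therefore shows the *analysis code* is correct and calibrated under
the stated signal model; it does not validate the scientific claims on real
patient data, which the package's design deliberately does not require.

## Problem sizes used in the test suite

Raw-signal round trips run on a reduced task (4 items per category, 60-s
rest, 10-s distraction, full-length 150-s recall blocks, 8 electrodes);
envelope-level checks use 150–600-s traces at 500 Hz with cohorts of 12–60
electrodes; the cluster-permutation calibration uses 200 null repetitions
of 8 × 601 traces with 500 permutations; the dynamics discrimination uses
50 repetitions per model with 30 electrodes each; determinism is checked on
the full default cohort end to end. These sizes were chosen so each check
has clear statistical margin while the whole suite stays comfortably
interactive.

## Known limitations

* Zero-phase FIR responses are squared relative to the single-pass design;
  notch widths and the 180-ms latency criterion inherit that convention.
* The latency estimator is biased late at low SNR (noise can only delay a
  sustained significant run); the Monte-Carlo trend is monotone but the
  absolute latency at weak responses should not be over-interpreted.
* The percentile classification is a decision rule on two p-values; cohorts
  with mixed dynamics return `indeterminate` rather than a graded score.
* Kenward-Roger degrees of freedom require `pbkrtest`; without it the
  Satterthwaite approximation is used silently (recorded in the fit
  object).
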