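---
title: "Methods: face-evoked iEEG analysis in facegamma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: face-evoked iEEG analysis in facegamma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`facegamma` analyses face-evoked responses in intracranial EEG recorded
from mesial temporal structures (amygdala, hippocampus, fusiform and
parahippocampal gyrus) in two patient groups: Group O (no mesial temporal
seizure onset zone) and Group M (mesial temporal seizure onset zone). This
vignette documents the models, parameters and numerical choices behind each
stage, and what the synthetic-data tests do and do not establish about real
recordings.

## The stimulation paradigm and the synthetic study

Real recordings from this paradigm are not distributable, so the package
ships a generator that emulates the study conditions end to end: six
picture categories (caucasian, dark-skinned, famous, veiled faces, wooden
masks, and mosaics as the non-face control) of 50 stimuli each, presented
for 1500 ms after a 300 ms fixation cross, with the interstimulus interval
drawn uniformly from 2800-3000 ms. Recordings are sampled at 1024 or
2048 Hz; 2 s of padding flank the first and last trial so the earliest
1.1 s baseline exists.

Each channel is a sum of three parts:

* **Background**: Gaussian noise spectrally shaped to a 1/f^alpha power
  spectrum (alpha = 1.5 by default, typical for local field potentials),
  scaled to 20 uV SD for depth contacts and 10 uV for the scalp Fz
  channel. These values are illustrative — the study reports no per-trial
  amplitude distributions — and were fixed once.
* **Evoked deflections**: Gaussian-windowed monophasic deflections (60 ms
  FWHM) at the nominal latencies 110/240/360 ms, identical across the
  contacts of a region. Making them identical models far-field behaviour:
  they are visible against the Fz reference and cancel under bipolar
  derivation, which is also how the two reference schemes divide the
  analysis in practice.
* **Induced gamma bursts**: band-limited noise carriers regenerated per
  trial (hence random carrier phase: they vanish from the trial average
  but not from single-trial power), with a raised-cosine-ramp (Tukey)
  envelope over the analysis window. A flat-topped envelope was chosen
  over a tapered one so the configured decibel increase is realized as the
  *mean* log-power elevation over the window; with a fully tapered
  envelope the window-mean of log power undershoots the calibrated value
  by up to ~1 dB (the mean-of-logs vs log-of-means gap). Burst power is
  calibrated against the channel's own band power so `db_increase` has its
  face-value meaning.

Cross-regional coupling is injected by multiplying the amplitude-region's
band content during post-stimulus windows by
`1 + depth * cos(phi(t - lag))`, where `phi` is the Morlet phase of the
phase region at the coupling frequency. The phase source is the leading
bipolar pair of the phase region so the injected relation survives bipolar
re-referencing. Default effect directions mirror the reported group
contrasts (face-selective gamma in amygdala and fusiform of Group O only,
famous-face gamma in hippocampus of both groups, coupling on face trials
only).

What the generator does *not* emulate: epileptiform spikes, seizures, eye
movements, electrode geometry, line noise, or non-stationary background.
Tests passing on this generator establish the correctness and calibration
of the estimators, not their robustness to those artifacts.

## Preprocessing

Recordings at 2048 Hz are down-sampled to 1024 Hz after a zero-phase
129-tap FIR anti-alias low-pass (cutoff ~460 Hz; content above the new
Nyquist is attenuated far beyond 40 dB by the forward-backward pass).

Two reference schemes serve the two analysis paths: scalp-Fz monopolar for
ERPs, and adjacent-contact bipolar derivations within each (patient,
region, hemisphere) electrode for the spectral analyses (named "A-B",
singleton contact groups dropped with a warning).

Epochs span [-1.1, +1.5) s around stimulus onset — one epoching serves both
the 1000 ms ERP baseline and the 1100 ms decibel baseline. The sample at
(or first after) the onset is t = 0; windows are half-open. Artifact
rejection follows the standard-deviation rule: per channel, epochs whose SD
over the full span exceeds 2.5 times the mean SD across epochs are masked
(not deleted). The rule is applied independently per reference scheme, on
unfiltered data, with the SD taken over the whole epoch including baseline
(the span is not otherwise constrained; these were the minimal-assumption
choices). It is scale-invariant by construction.

The ERP band-pass is a zero-phase (forward-backward) 4th-order Butterworth,
0.5-20 Hz. A zero-phase FIR was considered, but an FIR with a usable
0.5 Hz edge needs thousands of taps at 1024 Hz — longer than the 2.66 s
epochs it must filter — so the IIR realization was adopted; it meets the
same contracts (passband ripple < 1 dB, 50 Hz attenuated >= 20 dB, DC
removed, 10 Hz amplitude preserved within 5%). Epochs are reflect-padded by
1 s before filtering.

## Event-related potentials

ERPs average the kept trials after per-trial subtraction of the mean over
the [-1.0, 0) s baseline, then multiply by -1 so negative deflections plot
upward; all reported amplitudes use this display sign. Baseline correction
is per trial (not on the average) so that trial-level amplitudes are
well-defined inputs for the mixed models. Trial-level peak amplitudes are
means over 80 ms windows centred on 110, 240 and 360 ms (N110/N240/N360);
symmetric +/-40 ms windows are the minimal-assumption reading of the
nominal latencies.

## Time-frequency analysis

Morlet wavelet power is computed by FFT convolution over 40
logarithmically spaced frequencies from 1 to 200 Hz, with cycle counts
increasing logarithmically from 3 (1 Hz) to 10 (200 Hz) — the canonical
trade-off in the textbook methodology this analysis follows. Wavelets have
unit gain at their centre frequency; power is half the squared coefficient
magnitude, so a sinusoid maps to its variance in uV^2. Epochs are
reflect-padded by three standard deviations of the longest wavelet, and
padded samples never enter baselines or windows. The stored time axis may
be decimated (default: every 4th sample) since wavelet power is already
smooth at that scale.

Before the transform, the per-channel trial average is subtracted from
every kept trial ("ERP subtraction") so the power analysis reflects
induced, not evoked, activity. The average over all kept trials (not per
category) is used — the simplest reading, and category-specific averages
change the result negligibly at the trial counts involved.

Decibel baselining uses dB(t, f) = 10 log10(P(t, f) / B(f)) with B(f)
estimated from trial-averaged power over the 1100 ms pre-stimulus span.
B(f) is the *log-domain* (geometric) mean over the baseline samples: this
makes the baseline of the dB map exactly zero-mean — a self-consistency
property the package's tests assert to float precision — and coincides
with the arithmetic mean as baseline variability vanishes. Per-trial dB
values (the mixed-model inputs) use the same common B(f), which stabilizes
them relative to per-trial baselines.

Windowed gamma power is the mean dB over 45-150 Hz and the region's
analysis window: 0-750 ms (early-onset) for amygdala, fusiform and
parahippocampal gyrus, 250-1000 ms (late-onset) for hippocampus. Where the
window's lower edge is quoted as 1 ms elsewhere, [0, 750) ms half-open was
adopted; at 1024 Hz the difference is under one sample.

## Cluster-based permutation statistics

Subject-level maps are face-average minus mosaic-average dB maps per
(patient, region). The group comparison is a pooled-variance two-sample t
per pixel (positive = Group O > Group M), voxel-thresholded at two-tailed
p = 0.05, with 4-neighbour (rook) connected components. For each of 3000
permutations (default), subjects are randomly reassigned to groups of the
original sizes and the maximum positive and minimum negative cluster
t-sums recorded — 0 when no cluster forms, keeping exactly n_perm entries.
Observed positive clusters survive at or above the 95th percentile of the
maxima, negative clusters at or below the 5th percentile of the minima;
the two tails are thresholded separately (~5% per tail). Percentiles are
inverse-empirical-CDF (quantile type 1), the appropriate choice for a
discrete permutation distribution. The pooled-variance t (classic
two-sample behaviour) and rook connectivity were adopted where the
algorithm description leaves them open. When fewer distinct assignments
than permutations exist, sampling proceeds with replacement and a warning.
Monte-Carlo calibration (200 nulls at n_perm = 500, scaled down from 3000
to keep the suite fast; the statistic is the same) verifies the
false-positive rate sits in the exact binomial band around 5%.

## Phase-amplitude coupling

Inter-regional PAC is the mean-vector-length modulation index
MI = |mean(A(t) exp(i phi(t)))| over concatenated kept-trial 0-750 ms
windows, phase from one region's channel (grid 3-20 Hz in 1 Hz steps) and
amplitude from the other's (45-200 Hz in 5 Hz steps), both via complex
Morlet wavelets; one channel per region per patient, the one with the
fewest rejected epochs. Surrogates circularly shift the concatenated
amplitude series by a random offset of at least 1 s (200 by default),
preserving both autocorrelations. Because the squared MVL of an uncoupled
pair is exponential-like, z-scores are computed on the cube root of the
squared MVL (a Wilson-Hilferty variance-stabilizing transform), which
makes the surrogate z approximately standard normal so that the z >= 2
significance rule carries its nominal ~2.3% one-sided false-positive rate.
Implementation note: the MI at every circular shift is obtained in one
pass via FFT cross-correlation, so surrogate MIs are exact, not
re-estimated.

## Phase-slope-index directionality

For each (phase frequency, amplitude frequency) pair, PSI is computed
between the phase channel's raw 750 ms post-stimulus segments and the
amplitude channel's Morlet envelope at the amplitude frequency. Segments
are Hann-tapered; coherency is averaged across trials (one segment per
trial); PSI = Im(sum over the band of conj(C(f)) C(f + df)) with df one
Rayleigh bin (1/0.75 s) and the slope band f_phi +/- 2 Hz. Positive PSI
means the low-frequency site temporally leads (modulates) the gamma site;
the estimator is exactly antisymmetric under exchanging the two roles.
Significance uses z >= 2 (or <= -2) against surrogates that permute the
trial pairing between the two channels, and directionality is only
interpreted inside the PAC-significant mask. PSI at the *edges* of a
modulated band can legitimately take the opposite sign (modulation
sidebands), and its sampling distribution is heavy-tailed, so direction
recovery is assessed at the band centre and needs a few hundred trials for
stability — the recovery tests use 400.

## Group statistics

Trial-level tables pool all trials of all patients per region. Model 1
contrasts faces against mosaics (fixed effects: group, category collapsed
to face/mosaic, hemisphere, peak, group x category); Model 2 drops mosaic
trials and contrasts the five face categories; gamma variants omit the
peak term. Both include a random intercept per patient — a patient whose
hemispheres fall in different groups still gets a single intercept — and
are fit by REML via `lmerTest`, with Satterthwaite p-values and t-based
confidence intervals on the Satterthwaite degrees of freedom. When the
group x category interaction is significant, pairwise category contrasts
within group are computed from estimated marginal means with Tukey
adjustment (`emmeans`). All primary p-values within one fit are corrected
with the Holm-Bonferroni step-down, implemented directly and tested
against the brute-force reject rule and `stats::p.adjust`.

The responsive-contact classifier is a *reconstruction* — the analysis it
mirrors reports counts without stating a criterion. A contact is
ERP-responsive if any peak-window mean amplitude across face trials
differs from zero (two-sided one-sample t, Holm over the three windows,
p < 0.05), and gamma-responsive if its windowed gamma power exceeds 0 dB
(one-sided, p < 0.05).

## Pipeline, seeds and problem sizes

`run_pipeline()` chains simulate -> ingest -> ERP -> time-frequency ->
cluster -> coupling -> mixed models from one configuration and writes
TSV/JSON outputs plus a manifest. Every stochastic stage draws its seed
from the master seed through a counter-based derivation
(`derive_seed(master, stage)`), so toggling one stage never shifts
another's draws and identical configurations reproduce bit-identical
outputs. The shipped tests exercise the full chain on 2-3 patients per
group with a handful of stimuli per category, and the statistical
calibrations run at reduced sizes chosen to estimate the relevant rates
adequately (e.g. 200 null repetitions at 500 permutations; 50 recovery
runs); these sizes are the package's own choices for its test suite, and
all defaults remain at the full analysis values (3000 permutations, 200
surrogates, 50 stimuli per category). The package is driven from R; the
analysis entry points (`sim_config()`, `generate_study()`,
`run_pipeline()` and the stage functions) together with
`scripts/acceptance.R` are its interface.

## Known limitations

* EDF I/O is minimal by design: continuous recordings, a common sampling
  rate across signals, 1 s records, microvolt units. It is not a general
  EDF+ implementation (no annotations, discontinuous records, or
  per-signal rates).
* The simulator's effect sizes are illustrative, not calibrated to any
  patient dataset; absolute amplitudes should not be compared with
  published group estimates.
* PSI direction recovery at realistic trial counts (~150) is noisy at
  individual frequency pairs; conclusions should be drawn over the
  PAC-significant range, as the analysis prescribes.
* The mixed models assume Gaussian residuals; heavy-tailed single-trial
  gamma power can warrant a log-scale check that the package leaves to the
  user.
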