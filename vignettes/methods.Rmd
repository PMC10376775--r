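---
title: "Models and methods behind maskaware"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind maskaware}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`maskaware` implements, as one tested pipeline, the analysis chain used to
characterise auditory perceptual awareness under informational masking:
stimulus synthesis, behavioural scoring, windowed entropy estimation,
integrated-information measures on Gaussian models of the EEG, and
mixed-effects inference. Because the package must be fully testable without
any recorded EEG, it also contains a first-class synthetic-data generator
whose ground-truth parameters default to the effect estimates of the study
design it models; the
pipeline's principal validation is that it recovers what the generator
encodes.

## The experimental model

A trial is 10 s of a random multi-tone masker in which, on two thirds of
trials, a regular stream of target tones (100 ms tones at a fixed repetition
rate, starting 600 ms after masker onset) is embedded. Masker tones (20 ms,
10 ms cosine ramps) occupy log-spaced frequencies between 239 and 5000 Hz;
each frequency track is a renewal process whose inter-onset gaps are uniform
on `[interval_min, interval_max]` ms. Four spectro-temporal density
conditions are indexed by the labels 11, 20, 28 and 36 s^-1 oct^-1, which
correspond to the (mean gap, frequencies per octave) pairings (200, 32),
(400, 64), (600, 96) and (800, 128). The labels are carried as opaque
condition tags: all four pairings share the same fpo/miti ratio, so the
printed labels are not recomputable from the parameters and recomputing them
would be guesswork.

Energetic masking is prevented by a protected region of one equivalent
rectangular bandwidth, `ERB = 24.7 (4.37 F + 1)` Hz with `F` in kHz, on each
side of the target frequency. We treat the protected interval as closed:
a masker tone exactly on the boundary is removed (the conservative choice).
Target and masker tones share one amplitude (a 0 dB target-to-masker ratio);
rendered trials are peak-normalised to -1 dBFS before 16-bit quantisation,
since presentation levels in such experiments are set to a comfortable
listening level subjectively, and absolute calibration is out of scope.

Two open points in the stimulus model were decided as follows. First, the
masker is generated per frequency track (each frequency has its own renewal
process with the configured mean gap) rather than as one global point
process; the per-track reading matches the uniform-interval description and
is recorded as an assumption. Second, the first onset of each track is drawn
uniform on `[0, interval_max]`, which avoids synchronised track onsets while
leaving the stationary gap distribution untouched.

Responses are scored by signal detection: a key press at least 1600 ms after
trial onset on a target-present trial is a hit (two target tones must be
audible before a detection can reflect the regularity; faster presses are
dismissed as guesses and recoded as misses, with an exclusion switch),
`d' = z(HR) - z(FAR)`, and false alarms are attributed to the density of the
trial on which they occurred, since every trial carries a masker. Extreme
rates use the log-linear correction (0.5 added to each cell, 1 to each
denominator) by default.

## The synthetic EEG generator

Epochs are 6 s of 64-channel EEG at 1 kHz, centred on the *time reference*:
the button press for hits, and 3.4 s (the group-average detection time) for
misses. The generator builds each epoch in four layers:

1. **Base process.** Innovations with cluster-structured correlation drive a
   first-order autoregressive recursion (coefficient 0.5), are spectrally
   shaped to `1/f^1.5`, and band-limited at 30 Hz. The exponent and the band
   limit are the generator's realism choices: resting-EEG background
   activity has a 1/f exponent between 1 and 2 and carries little power
   above the beta band. The band limit also matters technically, as the next
   paragraph explains. Per-channel SD is 10 uV.
2. **Entropy offsets.** There is no closed form mapping a requested
   permutation-entropy shift (for example the +0.060 normalised-PeEn
   hit-minus-miss offset in the fronto-central cluster) to a generative
   parameter, so the generator calibrates one: it measures, once per session
   under a fixed internal seed, the curve of pipeline-units PeEn versus the
   fraction `w` of a gamma-band (60-80 Hz) component mixed into the base
   signal, and inverts that curve per requested offset. Positive offsets mix
   into hit trials, negative ones into miss trials. The mixing component
   must live in the upper analysis band: ordinal patterns of the 4x
   oversampled, 1-80 Hz filtered signal are moved almost exclusively by the
   rate of local extrema, which the fourth spectral moment - hence the top
   of the band - controls. A base process that already filled the band edge
   would leave no calibratable range; the 30 Hz band limit reserves it.
   The across-channel mean of the mixing noise is projected out so that
   common-average referencing cannot bleed the mixed component into other
   clusters. Every entropy estimator in the package responds to this
   component in the same direction, so the configured sign pattern
   (fronto-central positive, elsewhere negative) propagates to all five
   measures.
3. **Event-related kernels.** Gaussian bumps (SD 30 ms) are added
   time-locked to the four target tones around the reference (B2, B1, A1,
   A2 at -1.8, -0.8, +0.2 and +1.2 s). Awareness-related negativity (ARN)
   bumps peak 200 ms after tone onset at C5/F6/F7; P300 bumps peak at
   350 ms on the midline (FCz/Cz/CPz/Pz). Miss trials carry a base
   deflection (-4 uV for ARN electrodes, +4 uV for P300, oddball-sized
   components); hit trials add the configured contrast on top, with the B1
   contrasts the prominent ones (C5 -1.193 uV, CPz +0.999 uV by default).
   Giving misses a deep base is deliberate: signed-extremum peak
   extraction is biased by noise extrema, and simulation of the extraction
   chain shows the bias becomes common mode - cancelling in the
   hit-minus-miss contrast to within 0.05 uV - once both conditions carry
   a deflection of at least about four times the averaged-noise SD
   (1 uV at 100 trials). At shallower depths the shallower condition's
   peak chases noise extrema and contrasts attenuate. Waveform shapes
   beyond amplitude are not part of the ground truth.
4. **Coupling schedule.** The temporal-cluster channels share a common
   innovation component whose variance fraction steps from 0.6 to 0.15 at
   the reference on hit trials and stays at 0.35 on miss trials. This
   encodes the target pattern for the integrated-information time course:
   higher multi-information for hits before the reference, lower after.

Subjects differ by a symmetric jitter of the base band limit (SD 1 Hz),
which shifts all entropy features of a subject together and acts as the
feature-level random intercept, and by a multiplicative ERP gain (SD 0.1).
The jitter is symmetric by design: a one-sided subject effect on the steep
part of the mixing curve would compress group contrasts instead of adding
exchangeable noise. No reference values exist for these variance
components, so the SDs are realism choices. All randomness derives from one seed, fanned
out to per-subject substreams by fixed labels.

## Preprocessing and features

Preprocessing mirrors a standard non-causal chain: common-average
re-referencing, then 4th-order Butterworth high-pass (1 Hz) and low-pass
(80 Hz) sections applied forward-backward (only the cutoffs are part of
the modelled design; the filter realisation is ours). Artifact repair is a pass-through hook:
synthetic data are artifact-free, and ocular-ICA correction and automated
trial repair belong to the dedicated tools that perform them. Resampling uses the Fourier
method (spectral zero-padding or truncation), which is exact for
band-limited signals on integer-second epochs.

**Entropy.** Each epoch is oversampled to 4 kHz and split into 24 contiguous
1000-sample windows (12 per side of the reference). Oversampling adds no
information, but it is retained because the windowing of the modelled
design is defined at 4 kHz and the estimators' values depend on the
sampling grid. Five
estimators are computed per window and channel: spectral entropy (Shannon
entropy of the normalised periodogram; the unwindowed full-window
periodogram is the default, Welch is switchable), approximate entropy
(Pincus, self-inclusive matching, m = 2, r = 0.2 SD), sample entropy
(Richman-Moorman, self-matches excluded, both template sets over N - m
templates), permutation entropy and SVD entropy (order 3, delay 1,
normalised). The two template conventions are deliberately distinct -
swapping them changes toy-series values. Ordinal ties rank by order of
occurrence, so constant series have zero permutation entropy. The exact
parameter choices behind the modelled design are not recorded; these
defaults follow the common reference implementations and are configurable.
One documented subtlety: periodogram bins of white noise are exponentially
distributed, so the expected spectral entropy of a white-noise window is
`log2(M) - (1 - gamma)/ln 2` bits over `M` bins - about 0.93 after
normalisation, not 1 - and the package's tests freeze the oracle-derived
value. The Welch option, which averages bins, does approach 1.

The statistics use 11 windows per condition: the two epoch-edge windows are
dropped as filter-edge guards. The modelled design describes 24 windows in
its processing chain but 11 + 11 in its statistical design; the package
follows the statistical design, and a switch retains all 24.
Channel values are aggregated by unweighted mean into nine clusters (AF, F,
FC, C, CP, P, PO, T and the midline S). The assignment ships as an editable
YAML asset reconstructed from electrode-name prefixes, because reference
aggregation layouts are typically drawn rather than enumerated; real-data
use should review that asset.

**Integrated information.** On the temporal cluster, downsampled to 125 Hz
(750 samples per epoch), four measures are computed from the Gaussian model
of present and tau-lagged past (sample covariances, mean-subtracted, with an
escalating ridge of 1e-8 of the mean diagonal recorded in the model object
when near-singular):

* multi-information: total correlation of the joint past-present vector
  across parts;
* stochastic interaction: part-wise conditional entropies of present given
  own past, minus the joint conditional entropy (Schur complements);
* decoding-based integrated information: mutual information minus the
  mismatched-decoding information of the part-wise decoder, maximised over
  the decoding exponent beta on [0, Inf) by bracket expansion and
  golden-section/parabolic search (tolerance 1e-8); the closed-form
  objective is verified against grid quadrature in the tests;
* geometric integrated information: minimum KL divergence to the manifold
  of models whose present-on-past regression is partition-block-diagonal
  (innovation covariance free), computed by alternating exact coordinate
  updates - a linear solve for the constrained regression, a closed-form
  covariance update - to a divergence tolerance of 1e-10.

The partition defaults to atomic (each channel its own part), the common
practical choice and the natural reading of removing all interactions.
Multi-information is defined on the tau-lagged joint vector, matching the
tau-indexed time courses; the purely instantaneous total correlation is the
tau-free special case of the same function. Tiny negative values from
finite-precision arithmetic are clipped at zero with a diagnostic.

The time course slides a 110-sample window in steps of 10 samples across
the 750-sample epoch and averages each window's measure over tau = 1..10
samples (8-80 ms; the modelled design states ten lags without listing them,
so the first ten integers are used). This geometry yields 65 windows of which 27
lie entirely before the reference sample - exactly the 27 + 38 split of the
modelled statistical design, whose companion processing description (37
after) is internally inconsistent and was not followed. Window length and stride are configurable; the
defaults are a reconstruction, labelled as such.

## Statistics

Feature tables are aggregated to model cells (subject x detection x
condition x cluster for entropy; subject x detection x condition for the
temporal-cluster measures; subject x detection x tone per electrode for ERP
peaks) and fitted with maximum-likelihood linear mixed models carrying a
subject random intercept. F tests use Satterthwaite denominator degrees of
freedom - a documented deviation from the Kenward-Roger method of the
modelled design, with negligible effect at these sizes - and partial eta squared is reported
as `F df1 / (F df1 + df2)`. Estimated-marginal-means pairwise contrasts are
Bonferroni-adjusted with the family size recorded. The modelled design's
"null model" comparison is exposed as a likelihood-ratio test of the random
intercept and reported, not gated on.

The Monte-Carlo power calculator simulates the planning design: 15 subjects
by 4 blocks of 20 items, total variance 1 split by an intraclass
correlation into subject-intercept and residual shares, a two-level
within-subject effect of 0.44 total-SD units, a random-intercept fit per
replicate, and rejection counting at alpha = 0.05. The standardisation of
the planned effect is declared (total-SD units) and configurable because
the modelled design does not state its variance decomposition; the ICC is
swept in acceptance testing. A closed-form noncentral-t benchmark under
the same decomposition (`power_analytic`) cross-checks the simulator. For
the default design the two agree that a balanced within-subject effect of
0.44 total-SD units with 1200 observations is detected essentially always
(noncentrality 9-12 across the swept ICCs): under this declared
standardisation the planned 84% figure is not recoverable, which the
package reports as measured rather than adjusting the design toward the
figure. A power of 84% at this effect size corresponds to roughly 45
effective observations, suggesting the planning analysis behind that figure tested the effect
against subject-level (random-slope or aggregate) variability; a
random-slope option is a possible extension, but the declared
item-level standardisation is kept as the package's definition.

## Problem sizes and limitations

The test suite exercises the pipeline at reduced but structurally complete
sizes chosen by the package (reduced montages of 2 channels per cluster,
10 subjects x 8 trials per condition for the entropy recovery, 6 subjects
x 100 trials per condition for ERP recovery, 50 trials per condition on the
4 temporal channels for the time-course pattern, 1000 replicates per ICC
for power). Three caveats follow from the reduced montages: common-average
referencing over very few channels removes shared cluster variance (or, for
ERP montages, is dominated by the effect-carrying electrodes themselves), so
the 4-channel integrated-information check and the 7-electrode ERP recovery
run without re-referencing - with a 64-channel average both effects shrink
by an order of magnitude; single-channel clusters make aggregation the
identity; and the ERP recovery is assessed on per-subject component-mean
contrasts, because a single electrode's signed-extremum contrast carries
about 1.75 uV of per-subject noise at 100-trial averages, which no
affordable subject count turns into a sharp point estimate.

What passing tests show - and do not show - about real data: the generator
emulates stationary cluster-structured background activity, condition-locked
gamma-band mixing, tone-locked mean deflections and a stepped coupling
schedule. It does not emulate artifacts, non-Gaussian transients,
volume-conduction lead fields, latency jitter, or any relation between
masker density and the EEG; recovery on synthetic data validates the
estimators and the inference chain, not the neuroscientific claims
themselves. Reading real recordings (EDF) is out of scope of this build;
the epoch container accepts any trials x channels x samples array at 1 kHz,
so external data can be adapted by the user.
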