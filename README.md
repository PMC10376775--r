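# maskaware

Analysis toolkit for studying the neural correlates of **auditory perceptual
awareness under informational masking** — experiments in which a regular
stream of target tones is embedded in a random multi-tone masker that
interferes centrally rather than cochlearly, and listeners press a key the
moment the target pops into awareness.

The package implements the full chain such a study needs, plus a synthetic
EEG generator so that every stage is testable without any recording:

* **Stimuli** — random multi-tone maskers (log-spaced tracks between 239 and
  5000 Hz, uniform inter-onset gaps) at four spectro-temporal densities,
  with a protected region of one equivalent rectangular bandwidth
  (`ERB = 24.7 (4.37 F + 1)` Hz, `F` in kHz) on each side of the target
  frequency, rendered to 16-bit WAV.
* **Behaviour** — 240-trial sessions (160 target-present : 80 absent, four
  blocks of 60), guess dismissal below 1600 ms, and signal-detection scoring
  `d' = z(HR) − z(FAR)` per masker density.
* **Synthetic EEG** — 64-channel, 1 kHz, 6-s epochs centred on the time
  reference (button press for hits, 3.4 s for misses), with configurable
  ground truth: per-cluster hit−miss entropy offsets, tone-locked ARN/P300
  contrasts, and a temporal-cluster coupling schedule.
* **Signal** — common-average re-referencing, zero-phase 1–80 Hz Butterworth
  filtering, Fourier resampling, and topographic aggregation into nine
  clusters (AF, F, FC, C, CP, P, PO, T, S).
* **ERP** — tone-locked epochs (−200…+500 ms, baseline −200…0 ms) and signed
  peak extraction: the awareness-related negativity (minimum in 50–350 ms)
  and the P300 (maximum in 250–500 ms).
* **Entropy** — five windowed estimators (spectral, approximate, sample,
  permutation, SVD entropy) on 24 × 1000-sample windows of the 4 kHz
  oversampled epoch, each verified against brute-force oracles.
* **Integrated information** — four measures on stationary Gaussian models
  of the temporal cluster at 125 Hz: multi-information ΦMI, stochastic
  interaction ΦH, decoding-based Φ\* (mismatched-decoding closed form with a
  β search), and geometric ΦG (iterative KL projection), with τ-averaged
  sliding-window time courses.
* **Statistics** — maximum-likelihood linear mixed models with a subject
  random intercept, Satterthwaite F tests, partial η², Bonferroni-adjusted
  estimated-marginal-means contrasts, and a Monte-Carlo power calculator
  for random-intercept designs.

## Worked example

```r
library(maskaware)

# 1. a stimulus: density-36 masker with a 1 kHz target
trial <- build_trial_stimulus(density = 36, target = target_spec(1000), seed = 1)
nrow(trial$masker)                     # 6201 masker tones in 10 s
erb_bandwidth(1)                       # 132.639 Hz protected half-width

# 2. behaviour: a session and its sensitivity
sess <- simulate_responses(build_session(seed = 1), seed = 2)
dprime_summary(dprime_by_density(categorize_trials(sess)))
#> # A tibble: 4 x 4
#>   density mean_dprime sd_dprime     n
#> 1      11        1.64        NA     1
#> 2      20        0.948       NA     1
#> 3      28        1.37        NA     1
#> 4      36        1.41        NA     1

# 3. synthetic EEG -> entropy contrast in the fronto-central cluster
cfg <- effect_config(channels = c("Fp1","AF3","F3","F4","FC1","FC2","C3","C4",
                                  "CP1","CP2","P3","P4","PO3","PO4","T7","T8",
                                  "Fz","Cz"))
ds  <- generate_dataset(n_subjects = 6, n_trials_per_condition = 6, cfg = cfg, seed = 11)
fe  <- entropy_features(preprocess_epochs(ds$epochs), measures = "PeEn")
m   <- fit_lmm(aggregate_entropy(fe), "detection * condition * cluster")
emmeans_contrasts(m, "detection", by = "cluster")[, c("cluster", "estimate", "p_adjusted")]
#>   cluster estimate p_adjusted   (hit - miss, normalised PeEn units)
#> 1 AF      -0.0074   1.7e-06
#> ...
#> 5 FC       0.0603   9.3e-216    <- the configured +0.060 offset, recovered
#> ...
```

The fronto-central estimate recovers the generator's configured +0.060
permutation-entropy elevation for detected targets; the remaining clusters
recover their small negative offsets. The same pattern drives the package's
acceptance tests.

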