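#' Equivalent rectangular bandwidth of the auditory filter
#'
#' Glasberg-Moore approximation `ERB = 24.7 (4.37 f + 1)` with the centre
#' frequency `f` in kHz. The protected region around a target tone extends one
#' ERB on each side of the target frequency.
#'
#' @param f_khz centre frequency in kHz (non-negative).
#' @return bandwidth in Hz.
#' @examples
#' erb_bandwidth(1)      # 132.639
#' erb_bandwidth(2.924)  # about 340.3
#' @export
erb_bandwidth <- function(f_khz) {
  if (!is.numeric(f_khz)) stop("`f_khz` must be numeric")
  if (any(f_khz < 0)) stop("`f_khz` must be non-negative")
  24.7 * (4.37 * f_khz + 1)
}

#' The five equiprobable target frequencies (Hz)
#' @export
target_frequency_set <- function() c(699, 1000, 1430, 2045, 2924)

# density label -> (mean inter-tone interval ms, frequencies per octave).
# The labels are opaque condition tags attached to the printed pairings;
# they are never recomputed from miti/fpo.
.density_table <- function() {
  data.frame(
    density = c(11, 20, 28, 36),
    miti    = c(200, 400, 600, 800),
    fpo     = c(32, 64, 96, 128)
  )
}

#' Masker specification for one spectro-temporal density condition
#'
#' Each density label maps to a fixed pairing of mean inter-tone interval
#' (miti, ms) and frequencies per octave (fpo). Inter-tone intervals are drawn
#' uniformly on `[interval_min, interval_max]` with
#' `interval_max = 2 * miti - interval_min`, so the mean interval equals miti.
#'
#' @param density one of 11, 20, 28, 36 (s^-1 oct^-1 condition label).
#' @return a list of class `masker_spec`.
#' @export
masker_spec <- function(density = 11) {
  tab <- .density_table()
  i <- match(density, tab$density)
  if (is.na(i)) stop("`density` must be one of ", paste(tab$density, collapse = ", "))
  spec <- list(
    density_label = density,
    miti = tab$miti[i], fpo = tab$fpo[i],
    interval_min = 100, interval_max = 2 * tab$miti[i] - 100,
    freq_lo = 239, freq_hi = 5000,
    tone_duration_ms = 20, ramp_ms = 10
  )
  class(spec) <- "masker_spec"
  spec
}

#' Target specification
#'
#' A regular stream of pure tones starting 600 ms after masker onset.
#'
#' @param frequency target frequency in Hz.
#' @param tone_duration_ms tone duration (default 100 ms).
#' @param repetition_rate tones per second.
#' @param onset_ms onset of the first target tone from masker start.
#' @param ramp_ms raised-cosine on/off ramp duration.
#' @param present logical, whether a target is present.
#' @return a list of class `target_spec`.
#' @export
target_spec <- function(frequency = 1000, tone_duration_ms = 100,
                        repetition_rate = 1, onset_ms = 600,
                        ramp_ms = 10, present = TRUE) {
  structure(list(frequency = frequency, tone_duration_ms = tone_duration_ms,
                 repetition_rate = repetition_rate, onset_ms = onset_ms,
                 ramp_ms = ramp_ms, present = present),
            class = "target_spec")
}

#' Masker tone frequencies
#'
#' Frequencies equally spaced on a log2 scale between `freq_lo` and `freq_hi`
#' with `fpo` values per octave.
#'
#' @param spec a [masker_spec()].
#' @return numeric vector of frequencies in Hz.
#' @export
masker_frequencies <- function(spec) {
  if (spec$freq_lo >= spec$freq_hi) stop("freq_lo must be below freq_hi")
  if (spec$fpo <= 0) stop("fpo must be positive")
  k <- 0:floor(spec$fpo * log2(spec$freq_hi / spec$freq_lo))
  spec$freq_lo * 2^(k / spec$fpo)
}

#' Sample the masker tone sequence
#'
#' Each masker frequency carries its own renewal process: successive
#' inter-onset gaps are i.i.d. uniform on `[interval_min, interval_max]` ms,
#' and the first onset of each track is uniform on `[0, interval_max]`.
#' Tones whose offset would exceed the trial duration are discarded.
#'
#' @param spec a [masker_spec()].
#' @param trial_duration trial length in seconds.
#' @return tibble with columns `onset` (s), `frequency` (Hz),
#'   `duration_ms`, `ramp_ms` and `amplitude` (linear, 1 for all tones:
#'   0 dB target-to-masker ratio).
#' @export
sample_tone_sequence <- function(spec, trial_duration = 10) {
  # degenerate uniform (min == max) is allowed: a strictly periodic track
  if (spec$interval_max < spec$interval_min)
    stop("interval_max must not be below interval_min")
  dur_s <- spec$tone_duration_ms / 1000
  freqs <- masker_frequencies(spec)
  out <- lapply(freqs, function(f) {
    # upper bound on the number of gaps needed for this track
    n_max <- ceiling(trial_duration * 1000 / spec$interval_min) + 2L
    gaps <- runif(n_max, spec$interval_min, spec$interval_max) / 1000
    onsets <- runif(1, 0, spec$interval_max / 1000) + c(0, cumsum(gaps))
    onsets <- onsets[onsets + dur_s <= trial_duration]
    if (!length(onsets)) return(NULL)
    tibble::tibble(onset = onsets, frequency = f)
  })
  out <- dplyr::bind_rows(out)
  out$duration_ms <- spec$tone_duration_ms
  out$ramp_ms <- spec$ramp_ms
  out$amplitude <- 1
  out
}

#' Remove masker tones from the protected region around the target
#'
#' Deletes every masker tone whose frequency lies in the closed interval
#' `[target - ERB, target + ERB]`, where the ERB is evaluated at the target
#' frequency; boundary tones are removed.
#'
#' @param tones tibble of masker tones (see [sample_tone_sequence()]).
#' @param target_freq target frequency in Hz.
#' @return the tibble with protected-region tones removed.
#' @export
apply_protected_region <- function(tones, target_freq) {
  if (target_freq <= 0) stop("`target_freq` must be positive")
  if (!nrow(tones)) return(tones)
  erb <- erb_bandwidth(target_freq / 1000)
  keep <- tones$frequency < target_freq - erb | tones$frequency > target_freq + erb
  tones[keep, , drop = FALSE]
}

# Target tone events as a tibble in the same format as the masker tones.
target_tone_sequence <- function(target, trial_duration = 10) {
  if (!isTRUE(target$present)) {
    return(tibble::tibble(onset = numeric(), frequency = numeric(),
                          duration_ms = numeric(), ramp_ms = numeric(),
                          amplitude = numeric()))
  }
  dur_s <- target$tone_duration_ms / 1000
  onsets <- seq(target$onset_ms / 1000, trial_duration, by = 1 / target$repetition_rate)
  onsets <- onsets[onsets + dur_s <= trial_duration]
  tibble::tibble(onset = onsets, frequency = target$frequency,
                 duration_ms = target$tone_duration_ms,
                 ramp_ms = target$ramp_ms, amplitude = 1)
}

#' Build the tone lists for one informational-masking trial
#'
#' Draws the random multi-tone masker, applies the ERB-protected region when
#' a target is present, and lays out the regular target stream.
#'
#' @param density masker spectro-temporal density label (11, 20, 28 or 36).
#' @param target a [target_spec()] or `NULL` for a target-absent trial.
#' @param trial_duration trial length in seconds (default 10).
#' @param seed optional integer seed for reproducible synthesis.
#' @return list of class `im_trial` with elements `masker`, `target`
#'   (tone tibbles), `masker_spec`, `target_spec`, `trial_duration`, `seed`.
#' @export
build_trial_stimulus <- function(density = 11, target = target_spec(),
                                 trial_duration = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mspec <- masker_spec(density)
  masker <- sample_tone_sequence(mspec, trial_duration)
  tgt <- if (is.null(target)) target_spec(present = FALSE) else target
  if (isTRUE(tgt$present)) masker <- apply_protected_region(masker, tgt$frequency)
  structure(list(masker = masker, target = target_tone_sequence(tgt, trial_duration),
                 masker_spec = mspec, target_spec = tgt,
                 trial_duration = trial_duration, seed = seed),
            class = "im_trial")
}

#' Render tone events to an audio waveform
#'
#' Each tone is a sine with raised-cosine on/off ramps; overlapping tones sum.
#' The result is peak-normalised to -1 dBFS before any quantisation, so the
#' rendered trial can never clip when written as 16-bit PCM.
#'
#' @param tones tibble of tone events, or an `im_trial` (masker and target
#'   tones are concatenated).
#' @param sr sampling rate in Hz (default 44100).
#' @param duration output duration in seconds; defaults to the trial duration
#'   for an `im_trial`, otherwise to the last tone offset.
#' @param normalize logical; peak-normalise to -1 dBFS.
#' @return numeric vector of samples in `[-1, 1]`.
#' @export
render_waveform <- function(tones, sr = 44100, duration = NULL, normalize = TRUE) {
  if (inherits(tones, "im_trial")) {
    duration <- duration %||% tones$trial_duration
    tones <- dplyr::bind_rows(tones$masker, tones$target)
  }
  if (!nrow(tones)) {
    return(numeric(round((duration %||% 0) * sr)))
  }
  duration <- duration %||% max(tones$onset + tones$duration_ms / 1000)
  x <- numeric(round(duration * sr))
  for (i in seq_len(nrow(tones))) {
    n <- round(tones$duration_ms[i] / 1000 * sr)
    nr <- round(tones$ramp_ms[i] / 1000 * sr)
    # duration == 2 * ramp is a full raised-cosine envelope with no plateau
    # (the 20 ms masker tones with 10 ms ramps are exactly this)
    if (n < 2 * nr) stop("tone duration must cover both ramps")
    t <- (seq_len(n) - 1) / sr
    env <- rep(1, n)
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    env[seq_len(nr)] <- ramp
    env[n + 1 - seq_len(nr)] <- ramp
    i0 <- round(tones$onset[i] * sr)
    idx <- i0 + seq_len(n)
    idx_ok <- idx <= length(x)
    x[idx[idx_ok]] <- x[idx[idx_ok]] +
      (tones$amplitude[i] * sin(2 * pi * tones$frequency[i] * t) * env)[idx_ok]
  }
  if (normalize && any(x != 0)) x <- x / max(abs(x)) * 10^(-1 / 20)
  if (max(abs(x)) > 1) stop("internal error: rendered waveform clips")
  x
}
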