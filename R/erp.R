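#' Extract and baseline-correct a tone-locked waveform
#'
#' Cuts a window around a tone onset and subtracts the mean of the baseline
#' interval (the 200 ms preceding the tone by default).
#'
#' @param x numeric vector, one channel of one epoch.
#' @param sr sampling rate (Hz).
#' @param tone_onset tone onset in seconds of epoch time.
#' @param span window around the tone in seconds (default -0.2 to +0.5).
#' @param baseline baseline interval in seconds (default -0.2 to 0).
#' @return baseline-corrected waveform of `diff(span) * sr` samples with a
#'   `time` attribute (s relative to tone onset), or `NULL` with a warning
#'   when the span falls outside the epoch.
#' @export
epoch_tone <- function(x, sr, tone_onset, span = c(-0.2, 0.5),
                       baseline = c(-0.2, 0)) {
  i0 <- round(tone_onset * sr)
  idx <- (i0 + round(span[1] * sr) + 1):(i0 + round(span[2] * sr))
  if (idx[1] < 1 || idx[length(idx)] > length(x)) {
    warning(sprintf("tone window at %g s outside epoch; tone skipped", tone_onset))
    return(NULL)
  }
  w <- x[idx]
  tvec <- span[1] + (seq_along(w) - 1) / sr
  base <- mean(w[tvec >= baseline[1] & tvec < baseline[2]])
  w <- w - base
  attr(w, "time") <- tvec
  w
}

#' Pointwise grand average of waveforms
#'
#' @param waveforms matrix with one waveform per row (or a list of equal
#'   length vectors).
#' @return mean waveform with attribute `n` (number averaged).
#' @export
grand_average <- function(waveforms) {
  if (is.list(waveforms)) waveforms <- do.call(rbind, waveforms)
  if (!nrow(waveforms)) stop("no waveforms to average")
  out <- colMeans(waveforms)
  attr(out, "n") <- nrow(waveforms)
  out
}

#' Peak amplitude of an ERP component
#'
#' Signed extremum within the component's search interval: the minimum in
#' 50-350 ms for the awareness-related negativity (ARN), the maximum in
#' 250-500 ms for the P300.
#'
#' @param w waveform from [epoch_tone()] (time attribute in s, 0 = tone
#'   onset), or any numeric vector with `sr` and `span` supplied.
#' @param component `"ARN"` or `"P300"`.
#' @param sr sampling rate, required when `w` has no time attribute.
#' @param span span of `w` in seconds, required when `w` has no time
#'   attribute.
#' @return peak amplitude in uV.
#' @export
peak_amplitude <- function(w, component = c("ARN", "P300"), sr = NULL,
                           span = c(-0.2, 0.5)) {
  component <- match.arg(component)
  tvec <- attr(w, "time")
  if (is.null(tvec)) {
    if (is.null(sr)) stop("supply `sr` when the waveform has no time attribute")
    tvec <- span[1] + (seq_along(w) - 1) / sr
  }
  win <- if (component == "ARN") c(0.05, 0.35) else c(0.25, 0.5)
  dt <- tvec[2] - tvec[1]
  # the waveform samples the half-open span [span[1], span[2]): a search
  # interval ending exactly at the span end is in range
  if (win[1] < tvec[1] - 1e-9 || win[2] > tvec[length(tvec)] + dt + 1e-9)
    stop("search interval outside the waveform span")
  seg <- w[tvec >= win[1] & tvec <= win[2]]
  if (component == "ARN") min(seg) else max(seg)
}

#' Per-subject ERP peak table
#'
#' For every electrode of interest, tone and detection condition, waveforms
#' are averaged within subject and the component peak is extracted from the
#' subject average (the observation level required by the subject random
#' intercept of the mixed model).
#'
#' @param epochs an [epoch_array()] with `tone_times`.
#' @param components named list mapping component name (`"ARN"`, `"P300"`)
#'   to the electrodes scored for it; defaults to the ARN electrodes
#'   C5/F6/F7 and the midline P300 electrodes FCz/Cz/CPz/Pz (intersected
#'   with the montage).
#' @param span,baseline passed to [epoch_tone()].
#' @return tibble: `subject`, `detection`, `component`, `electrode`, `tone`,
#'   `amplitude` (uV), `n_trials`.
#' @export
erp_peak_table <- function(epochs,
                           components = list(ARN = c("C5", "F6", "F7"),
                                             P300 = c("FCz", "Cz", "CPz", "Pz")),
                           span = c(-0.2, 0.5), baseline = c(-0.2, 0)) {
  stopifnot(inherits(epochs, "epoch_array"), !is.null(epochs$tone_times))
  tones <- colnames(epochs$tone_times)
  out <- list()
  for (comp in names(components)) {
    for (el in intersect(components[[comp]], epochs$channels)) {
      ch <- match(el, epochs$channels)
      for (tone in tones) {
        cell <- tibble::tibble(subject = epochs$subject,
                               detection = epochs$labels,
                               trial = seq_along(epochs$labels))
        for (grp in split(cell, list(cell$subject, cell$detection), drop = TRUE)) {
          wfs <- lapply(grp$trial, function(i)
            epoch_tone(epochs$data[i, ch, ], epochs$sr,
                       epochs$tone_times[i, tone], span, baseline))
          wfs <- wfs[!vapply(wfs, is.null, logical(1))]
          if (!length(wfs)) next
          avg <- grand_average(wfs)
          attr(avg, "time") <- attr(wfs[[1]], "time")
          out[[length(out) + 1L]] <- tibble::tibble(
            subject = grp$subject[1], detection = grp$detection[1],
            component = comp, electrode = el, tone = tone,
            amplitude = peak_amplitude(avg, comp), n_trials = length(wfs))
        }
      }
    }
  }
  dplyr::bind_rows(out)
}
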