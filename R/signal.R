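#' Default 64-channel montage and topographic cluster map
#'
#' Channels follow the extended 10/20 naming scheme and are assigned to nine
#' topographic clusters: antero-frontal (AF), frontal (F), fronto-central
#' (FC), central (C), centro-parietal (CP), parietal (P), parieto-occipital
#' (PO), temporal (T) and sagittal (S, the midline). The assignment is
#' derived from electrode-name prefixes (midline `z` electrodes map to S;
#' FT/T/TP prefixes map to T; occipital electrodes join PO) and shipped as an
#' editable YAML asset: any use on real recordings should review that asset,
#' since reference aggregation layouts are drawn rather than enumerated.
#'
#' @return named character vector mapping channel name to cluster code.
#' @export
default_cluster_map <- function() {
  path <- system.file("extdata", "cluster_map.yaml", package = "maskaware")
  m <- yaml::read_yaml(path)
  unlist(m)
}

#' Cluster assignment from electrode-name prefixes
#'
#' @param channels character vector of 10/20 electrode names.
#' @return character vector of cluster codes.
#' @export
cluster_for_channels <- function(channels) {
  vapply(channels, function(ch) {
    if (grepl("z$", ch)) return("S")
    if (grepl("^(Fp|AF)", ch)) return("AF")
    if (grepl("^(FT|TP|T)", ch)) return("T")
    if (grepl("^FC", ch)) return("FC")
    if (grepl("^CP", ch)) return("CP")
    if (grepl("^(PO|O|I)", ch)) return("PO")
    if (grepl("^F", ch)) return("F")
    if (grepl("^C", ch)) return("C")
    if (grepl("^P", ch)) return("P")
    stop("cannot assign channel to a cluster: ", ch)
  }, character(1))
}

#' Epoch container
#'
#' A trials x channels x samples array of microvolt values with its sampling
#' rate, channel names, hit/miss labels and per-trial tone onsets. Epochs are
#' 6 s long with the time reference (button press for hits, the group-average
#' detection time for misses) at the centre, i.e. `t0 = -3` s.
#'
#' @param data numeric array, trials x channels x samples.
#' @param sr sampling rate in Hz.
#' @param channels channel names (length = dim 2).
#' @param labels character vector `"hit"`/`"miss"` per trial.
#' @param tone_times matrix trials x 4 of tone onsets (s, epoch time) with
#'   columns B2, B1, A1, A2, or `NULL`.
#' @param subject subject id per trial (recycled if length 1).
#' @param t0 time of the first sample relative to the reference (default -3).
#' @return object of class `epoch_array`.
#' @export
epoch_array <- function(data, sr, channels, labels, tone_times = NULL,
                        subject = "S1", t0 = -3) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(channels),
            dim(data)[1] == length(labels))
  if (dim(data)[3] != 6 * sr)
    stop("epochs must hold exactly 6 s of samples (6 * sr)")
  structure(list(data = data, sr = sr, channels = channels,
                 labels = labels, tone_times = tone_times,
                 subject = rep_len(subject, dim(data)[1]), t0 = t0),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf("<epoch_array> %d trials x %d channels x %d samples @ %g Hz (t0 = %g s)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sr, x$t0))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth high-pass and low-pass sections applied
#' forward-backward (zero phase lag, doubled attenuation).
#'
#' @param x numeric vector, or matrix with channels in rows.
#' @param sr sampling rate in Hz.
#' @param lo high-pass cutoff (Hz).
#' @param hi low-pass cutoff (Hz).
#' @param order filter order per section.
#' @return filtered data, same shape as `x`.
#' @export
bandpass <- function(x, sr, lo = 1, hi = 80, order = 4) {
  if (sr <= 2 * hi) stop("sampling rate must exceed twice the low-pass cutoff")
  bp_hp <- signal::butter(order, lo / (sr / 2), type = "high")
  bp_lp <- signal::butter(order, hi / (sr / 2), type = "low")
  f1 <- function(v) {
    v <- signal::filtfilt(bp_hp, v)
    signal::filtfilt(bp_lp, v)
  }
  if (is.matrix(x)) t(apply(x, 1, f1)) else f1(x)
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean at every sample; the channel mean of the
#' output is identically zero and the operation is idempotent.
#'
#' @param x matrix channels x samples.
#' @return re-referenced matrix.
#' @export
rereference_average <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2) stop("need a channels x samples matrix with >= 2 channels")
  sweep(x, 2, colMeans(x))
}

#' Extract a 6-s epoch around a time reference
#'
#' @param x continuous recording, channels x samples matrix.
#' @param sr sampling rate in Hz.
#' @param reference_time reference in seconds from recording start (button
#'   press for hits; 3.4 s for misses).
#' @param half epoch half-width in seconds (default 3).
#' @return channels x (2 * half * sr) matrix, or `NULL` (with a warning) if
#'   the recording does not cover the span.
#' @export
extract_epoch <- function(x, sr, reference_time, half = 3) {
  i0 <- round((reference_time - half) * sr)
  n <- 2 * half * sr
  if (i0 < 0 || i0 + n > ncol(x)) {
    warning(sprintf("epoch around t=%g s outside recording; trial dropped", reference_time))
    return(NULL)
  }
  x[, i0 + seq_len(n), drop = FALSE]
}

#' Fourier-method resampling
#'
#' Resamples by spectral truncation (decimation; implicit ideal anti-alias
#' filter) or zero padding (interpolation). Exact for band-limited signals on
#' integer-second epochs.
#'
#' @param x numeric vector, or matrix with channels in rows.
#' @param n_out output length (vector input), or
#' @param sr_in,sr_out sampling rates; when given, `n_out` is derived as
#'   `length(x) * sr_out / sr_in`.
#' @return resampled data.
#' @export
resample_fourier <- function(x, n_out = NULL, sr_in = NULL, sr_out = NULL) {
  if (is.matrix(x)) {
    return(t(apply(x, 1, resample_fourier, n_out = n_out, sr_in = sr_in,
                   sr_out = sr_out)))
  }
  n <- length(x)
  if (is.null(n_out)) {
    if (is.null(sr_in) || is.null(sr_out)) stop("give n_out or both sampling rates")
    n_out <- n * sr_out / sr_in
    if (abs(n_out - round(n_out)) > 1e-9) stop("non-integer output length")
    n_out <- round(n_out)
  }
  if (n_out == n) return(x)
  X <- fft(x)
  Y <- complex(length.out = n_out)
  nmin <- min(n, n_out)
  half <- nmin %/% 2
  Y[seq_len(half)] <- X[seq_len(half)]
  if (half > 1)
    Y[n_out - (half - 2:half)] <- X[n - (half - 2:half)]
  if (nmin %% 2 == 0) {
    # Nyquist bin of the smaller grid must stay real to keep the output real
    if (n_out < n) Y[half + 1] <- complex(real = Re(X[half + 1]))
    else {
      Y[half + 1] <- X[half + 1] / 2
      Y[n_out - half + 1] <- Conj(X[half + 1]) / 2
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Aggregate per-channel values into topographic clusters
#'
#' Unweighted mean of the channel values within each cluster.
#'
#' @param values named numeric vector (names are channel names).
#' @param map named character vector channel -> cluster (default asset).
#' @return named numeric vector of cluster means.
#' @export
cluster_aggregate <- function(values, map = default_cluster_map()) {
  unknown <- setdiff(names(values), names(map))
  if (length(unknown))
    stop("channel(s) not in cluster map: ", paste(unknown, collapse = ", "))
  cl <- map[names(values)]
  out <- tapply(values, cl, mean)
  setNames(as.vector(out), dimnames(out)[[1]])
}

#' Preprocess an epoch array
#'
#' Average re-reference followed by zero-phase band-pass filtering, applied
#' per trial. Artifact repair on real recordings (ocular ICA, bad-channel
#' interpolation) is intentionally a pass-through hook here: synthetic data
#' are artifact-free.
#'
#' @param epochs an [epoch_array()].
#' @param lo,hi band-pass cutoffs (Hz).
#' @param reref logical, apply common-average re-referencing.
#' @param artifact_hook optional function (channels x samples matrix -> same)
#'   applied after filtering.
#' @return a preprocessed `epoch_array`.
#' @export
preprocess_epochs <- function(epochs, lo = 1, hi = 80, reref = TRUE,
                              artifact_hook = NULL) {
  for (i in seq_len(dim(epochs$data)[1])) {
    m <- epochs$data[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    if (reref && nrow(m) > 1) m <- rereference_average(m)
    m <- bandpass(m, epochs$sr, lo, hi)
    if (!is.null(artifact_hook)) m <- artifact_hook(m)
    epochs$data[i, , ] <- m
  }
  epochs
}
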