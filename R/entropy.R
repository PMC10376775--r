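#' Entropy estimator parameters
#'
#' @param m embedding length for approximate/sample entropy.
#' @param r tolerance; a fraction of the window SD when `r_is_fraction`.
#' @param order ordinal/embedding order for permutation/SVD entropy.
#' @param delay embedding delay in samples.
#' @param normalize normalise spectral, permutation and SVD entropy to
#'   `[0, 1]`.
#' @param r_is_fraction interpret `r` as a fraction of the window SD (gives
#'   affine-invariant estimates).
#' @param spen_method spectrum estimator for spectral entropy.
#' @return list of class `entropy_params`.
#' @export
entropy_params <- function(m = 2, r = 0.2, order = 3, delay = 1,
                           normalize = TRUE, r_is_fraction = TRUE,
                           spen_method = c("periodogram", "welch")) {
  stopifnot(m >= 1, r > 0, order >= 2, delay >= 1)
  structure(list(m = m, r = r, order = order, delay = delay,
                 normalize = normalize, r_is_fraction = r_is_fraction,
                 spen_method = match.arg(spen_method)),
            class = "entropy_params")
}

#' Split an oversampled epoch into analysis windows
#'
#' A 6-s epoch oversampled to 4 kHz yields 24 contiguous non-overlapping
#' windows of 1000 samples: 12 before and 12 after the time reference.
#'
#' @param x numeric vector (epoch samples).
#' @param n_windows number of windows.
#' @return matrix `n_windows` x window length; rows concatenate back to `x`.
#' @export
window_epoch <- function(x, n_windows = 24) {
  if (length(x) %% n_windows != 0)
    stop("epoch length is not divisible into ", n_windows, " equal windows")
  matrix(x, nrow = n_windows, byrow = TRUE)
}

#' Spectral entropy
#'
#' Shannon entropy of the power spectral density normalised to a probability
#' distribution over frequency bins, divided by the log of the bin count
#' when normalised. The default spectrum is the unwindowed periodogram of
#' the full window; a Welch estimator (8 Hann segments, 50% overlap) is
#' available.
#'
#' @param x numeric window.
#' @param normalize normalise to `[0, 1]`.
#' @param method `"periodogram"` or `"welch"`.
#' @return entropy in bits (normalised if requested).
#' @export
spectral_entropy <- function(x, normalize = TRUE,
                             method = c("periodogram", "welch")) {
  method <- match.arg(method)
  if (all(x == 0)) {
    warning("all-zero window: spectral entropy defined as 0")
    return(0)
  }
  if (length(x) < 8) stop("window too short for a spectral estimate")
  if (method == "periodogram") {
    n <- length(x)
    p <- Mod(fft(x))^2
    p <- p[seq_len(n %/% 2 + 1)]
  } else {
    n <- length(x)
    nseg <- max(n %/% 8, 64)
    step <- nseg %/% 2
    starts <- seq(1, n - nseg + 1, by = step)
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
    p <- rowSums(vapply(starts, function(s) {
      ps <- Mod(fft(x[s + seq_len(nseg) - 1] * w))^2
      ps[seq_len(nseg %/% 2 + 1)]
    }, numeric(nseg %/% 2 + 1)))
  }
  p <- p / sum(p)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  if (normalize) h <- h / log2(length(p))
  h
}

#' Approximate entropy (ApEn)
#'
#' Pincus' regularity statistic `ApEn = Phi_m - Phi_{m+1}` where `Phi_m` is
#' the mean log fraction of templates within Chebyshev distance `r`,
#' counting self-matches (the classic self-inclusive convention, which keeps
#' the statistic finite on all inputs).
#'
#' @param x numeric window.
#' @param m embedding length.
#' @param r tolerance (fraction of SD when `r_is_fraction`).
#' @param r_is_fraction see [entropy_params()].
#' @return non-negative entropy in nats.
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2, r_is_fraction = TRUE) {
  if (r <= 0) stop("tolerance r must be positive")
  if (length(x) <= m + 1) stop("window too short for embedding length m")
  rr <- if (r_is_fraction) r * sd(x) else r
  apen_cpp(as.numeric(x), as.integer(m), rr)
}

#' Sample entropy (SaEn)
#'
#' Richman-Moorman convention: `SaEn = -log(A / B)` with `A` and `B` the
#' numbers of template pairs within Chebyshev distance `r` at lengths
#' `m + 1` and `m`, self-matches excluded, both counted over the same
#' `N - m` templates. Undefined (NA, with a warning) when either count is
#' zero.
#'
#' @inheritParams approximate_entropy
#' @return non-negative entropy in nats, or NA.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, r_is_fraction = TRUE) {
  if (r <= 0) stop("tolerance r must be positive")
  if (length(x) <= m + 1) stop("window too short for embedding length m")
  rr <- if (r_is_fraction) r * sd(x) else r
  ab <- sampen_counts_cpp(as.numeric(x), as.integer(m), rr)
  if (ab[1] == 0 || ab[2] == 0) {
    warning("no matching templates: sample entropy undefined for this window")
    return(NA_real_)
  }
  -log(ab[1] / ab[2])
}

# Lehmer codes of the ordinal patterns of delay-embedded windows.
# Ties are broken by order of occurrence: the earlier index ranks lower,
# so a constant series maps to the single ascending pattern.
.ordinal_codes <- function(x, order, delay) {
  n_pat <- length(x) - (order - 1) * delay
  if (n_pat < 1) stop("window too short for the requested order and delay")
  emb <- vapply(0:(order - 1), function(k) x[seq_len(n_pat) + k * delay],
                numeric(n_pat))
  if (n_pat == 1) emb <- matrix(emb, nrow = 1)
  code <- integer(n_pat)
  for (j in seq_len(order - 1)) {
    later <- emb[, (j + 1):order, drop = FALSE]
    cj <- rowSums(later < emb[, j])
    code <- code + cj * factorial(order - j)
  }
  code + 1L
}

#' Permutation entropy (PeEn)
#'
#' Shannon entropy of the distribution of ordinal patterns across all
#' length-`order` delay-embedded motifs, divided by `log(order!)` when
#' normalised. Ties rank by order of occurrence, so a constant or strictly
#' monotone series has zero permutation entropy.
#'
#' @param x numeric window.
#' @param order pattern length.
#' @param delay embedding delay in samples.
#' @param normalize normalise to `[0, 1]`.
#' @return entropy in bits (normalised if requested).
#' @export
permutation_entropy <- function(x, order = 3, delay = 1, normalize = TRUE) {
  codes <- .ordinal_codes(x, order, delay)
  p <- tabulate(codes, nbins = factorial(order))
  p <- p / sum(p)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  if (normalize) h <- h / log2(factorial(order))
  h
}

#' Singular-value decomposition entropy (SvEn)
#'
#' Shannon entropy of the normalised singular-value spectrum of the delay
#' embedding matrix, divided by `log(order)` when normalised. A constant
#' (rank-1 embedding) series has zero SVD entropy; an all-zero window is
#' defined as 0 with a warning.
#'
#' @inheritParams permutation_entropy
#' @return entropy in bits (normalised if requested).
#' @export
svd_entropy <- function(x, order = 3, delay = 1, normalize = TRUE) {
  if (all(x == 0)) {
    warning("all-zero window: SVD entropy defined as 0")
    return(0)
  }
  n_row <- length(x) - (order - 1) * delay
  if (n_row < order) stop("window too short for the requested order and delay")
  emb <- vapply(0:(order - 1), function(k) x[seq_len(n_row) + k * delay],
                numeric(n_row))
  s <- svd(emb, nu = 0, nv = 0)$d
  s <- s / sum(s)
  h <- -sum(s[s > 0] * log2(s[s > 0]))
  if (normalize) h <- h / log2(order)
  h
}

# Dispatch a measure name to its estimator.
.entropy_one <- function(x, measure, p) {
  switch(measure,
         SpEn = spectral_entropy(x, normalize = p$normalize, method = p$spen_method),
         ApEn = approximate_entropy(x, p$m, p$r, p$r_is_fraction),
         SaEn = sample_entropy(x, p$m, p$r, p$r_is_fraction),
         PeEn = permutation_entropy(x, p$order, p$delay, p$normalize),
         SvEn = svd_entropy(x, p$order, p$delay, p$normalize),
         stop("unknown entropy measure: ", measure))
}

#' Windowed entropy features for an epoch array
#'
#' Each epoch is oversampled to 4 kHz (Fourier interpolation; the modelled
#' design keeps 1000-point windows statistically comfortable for the
#' template estimators), split into 24 contiguous windows, and each window is
#' scored with the requested entropy measures per channel. Channel values are
#' then aggregated into topographic clusters. The two epoch-edge windows are
#' dropped by default as filter-edge guards, leaving 11 windows per condition
#' (before/after the reference).
#'
#' @param epochs an [epoch_array()] (typically preprocessed).
#' @param measures subset of `c("SpEn","ApEn","SaEn","PeEn","SvEn")`.
#' @param params an [entropy_params()].
#' @param map channel -> cluster map.
#' @param oversample_to target rate for the oversampling step (Hz).
#' @param keep_edges keep the first and last window of each epoch.
#' @return long tibble: `subject`, `trial`, `detection`, `condition`
#'   (before/after), `window` (index within condition), `cluster`,
#'   `measure`, `value`.
#' @export
entropy_features <- function(epochs, measures = c("SpEn", "ApEn", "SaEn",
                                                  "PeEn", "SvEn"),
                             params = entropy_params(),
                             map = default_cluster_map(),
                             oversample_to = 4000, keep_edges = FALSE) {
  stopifnot(inherits(epochs, "epoch_array"))
  n_tr <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[2]
  n <- dim(epochs$data)[3]
  n_win <- 24L
  cl <- map[epochs$channels]
  if (anyNA(cl)) stop("channel(s) missing from cluster map: ",
                      paste(epochs$channels[is.na(cl)], collapse = ", "))
  keep <- if (keep_edges) seq_len(n_win) else 2:(n_win - 1)
  rows <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    vals <- array(NA_real_, c(n_ch, n_win, length(measures)),
                  dimnames = list(NULL, NULL, measures))
    for (c_i in seq_len(n_ch)) {
      x <- resample_fourier(epochs$data[i, c_i, ],
                            n_out = round(n * oversample_to / epochs$sr))
      win <- window_epoch(x, n_windows = n_win)
      for (wi in keep) {
        for (ms in measures)
          vals[c_i, wi, ms] <- .entropy_one(win[wi, ], ms, params)
      }
    }
    # aggregate channels into clusters
    per <- lapply(measures, function(ms) {
      agg <- apply(vals[, keep, ms, drop = FALSE], 2, function(v)
        cluster_aggregate(setNames(v, epochs$channels), map))
      tibble::tibble(
        window_global = rep(keep, each = nrow(agg)),
        cluster = rep(rownames(agg), length(keep)),
        measure = ms, value = as.vector(agg))
    })
    per <- dplyr::bind_rows(per)
    per$subject <- epochs$subject[i]
    per$trial <- i
    per$detection <- epochs$labels[i]
    rows[[i]] <- per
  }
  out <- dplyr::bind_rows(rows)
  half <- n_win / 2
  out$condition <- ifelse(out$window_global <= half, "before", "after")
  first_kept <- if (keep_edges) 1L else 2L
  out$window <- ifelse(out$condition == "before",
                       out$window_global - first_kept + 1L,
                       out$window_global - half)
  out[, c("subject", "trial", "detection", "condition", "window",
          "cluster", "measure", "value")]
}

#' Aggregate entropy features to model cells
#'
#' Mean over trials and windows per (subject, detection, condition, cluster,
#' measure): the observation level of the detection x condition x cluster
#' mixed model.
#'
#' @param features output of [entropy_features()].
#' @return aggregated tibble with a `value` column.
#' @export
aggregate_entropy <- function(features) {
  features |>
    dplyr::group_by(.data$subject, .data$detection, .data$condition,
                    .data$cluster, .data$measure) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}
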