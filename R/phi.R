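#' Stationary Gaussian model of present and lagged past
#'
#' The substrate of all integrated-information measures: the covariance of
#' the present state, the covariance of the state tau samples earlier, their
#' cross-covariance, and a partition of the channels into parts.
#'
#' @param sigma_p past covariance (channels x channels).
#' @param sigma_t present covariance.
#' @param sigma_cross cross-covariance, `sigma_cross[i, j] = cov(past_i,
#'   present_j)`.
#' @param tau lag in samples.
#' @param partition list of disjoint channel index vectors covering all
#'   channels; defaults to the atomic partition (each channel its own part).
#' @return object of class `lagged_gauss_model`.
#' @export
lagged_gauss_model <- function(sigma_p, sigma_t, sigma_cross, tau = 1,
                               partition = NULL) {
  n <- nrow(sigma_t)
  stopifnot(nrow(sigma_p) == n, nrow(sigma_cross) == n)
  partition <- partition %||% as.list(seq_len(n))
  idx <- as.integer(sort(unlist(partition)))
  if (!identical(idx, seq_len(n)))
    stop("partition must cover every channel exactly once")
  joint <- rbind(cbind(sigma_p, sigma_cross),
                 cbind(t(sigma_cross), sigma_t))
  if (inherits(try(chol(joint), silent = TRUE), "try-error"))
    stop("joint past-present covariance is not positive definite")
  structure(list(sigma_p = sigma_p, sigma_t = sigma_t,
                 sigma_cross = sigma_cross, tau = tau,
                 partition = partition, n = n),
            class = "lagged_gauss_model")
}

#' Estimate a lagged Gaussian model from multichannel data
#'
#' Sample covariances of the present (`X[, (tau+1):m]`), the past
#' (`X[, 1:(m-tau)]`) and their cross-covariance, mean-subtracted per
#' channel. A ridge (1e-8 of the mean diagonal, escalated tenfold up to
#' three times with warnings) is added if the joint covariance is not
#' positive definite.
#'
#' @param X channels x samples matrix.
#' @param tau lag in samples (>= 1).
#' @param partition passed to [lagged_gauss_model()].
#' @return a [lagged_gauss_model()].
#' @export
estimate_lagged_cov <- function(X, tau, partition = NULL) {
  if (tau < 1) stop("tau must be a positive integer lag")
  n <- nrow(X); m <- ncol(X)
  if (n < 2) stop("need at least 2 channels")
  if (m <= n + tau) stop("need more samples than channels + tau")
  past <- t(X[, 1:(m - tau), drop = FALSE])
  pres <- t(X[, (tau + 1):m, drop = FALSE])
  past <- scale(past, scale = FALSE)
  pres <- scale(pres, scale = FALSE)
  k <- nrow(past) - 1
  sp <- crossprod(past) / k
  st <- crossprod(pres) / k
  sc <- crossprod(past, pres) / k
  ridge_used <- 0
  ridge <- 1e-8 * mean(diag(st))
  for (att in 0:3) {
    joint <- rbind(cbind(sp, sc), cbind(t(sc), st))
    if (!inherits(try(chol(joint), silent = TRUE), "try-error")) break
    if (att == 3) stop("covariance rank-deficient even after shrinkage")
    sp <- sp + diag(ridge, n)
    st <- st + diag(ridge, n)
    ridge_used <- ridge_used + ridge
    ridge <- ridge * 10
  }
  out <- lagged_gauss_model(sp, st, sc, tau = tau, partition = partition)
  out$ridge <- ridge_used   # shrinkage log: 0 when no regularisation was needed
  out
}

# log-determinant via Cholesky; errors on non-PD input
.logdet <- function(S) {
  ch <- tryCatch(chol(S), error = function(e)
    stop("matrix not positive definite", call. = FALSE))
  2 * sum(log(diag(ch)))
}

#' Differential entropy of a multivariate Gaussian
#'
#' `H = 0.5 log((2 pi e)^n det Sigma)` in nats.
#'
#' @param sigma positive-definite covariance matrix (or scalar variance).
#' @return entropy in nats.
#' @export
gaussian_entropy <- function(sigma) {
  sigma <- as.matrix(sigma)
  n <- nrow(sigma)
  0.5 * (n * (log(2 * pi) + 1) + .logdet(sigma))
}

.joint_cov <- function(model) {
  rbind(cbind(model$sigma_p, model$sigma_cross),
        cbind(t(model$sigma_cross), model$sigma_t))
}

# Clip small negative values arising from finite-precision arithmetic.
.clip0 <- function(v, tol = 1e-9) {
  if (v < -tol) warning("measure below -tol clipped to 0 (", signif(v, 3), ")")
  max(v, 0)
}

#' Time-lagged mutual information of a Gaussian model
#'
#' `I(past; present) = H(present) + H(past) - H(joint)`, in nats.
#'
#' @param model a [lagged_gauss_model()].
#' @return mutual information in nats.
#' @export
mutual_information <- function(model) {
  .clip0(gaussian_entropy(model$sigma_t) + gaussian_entropy(model$sigma_p) -
           gaussian_entropy(.joint_cov(model)))
}

#' Multi-information (redundancy-based integrated information)
#'
#' Total correlation of the joint past-present vector across the parts of
#' the partition: the sum of the entropies of each part's own (past_i,
#' present_i) block minus the entropy of the full joint vector. Zero iff
#' the parts are mutually independent.
#'
#' @param model a [lagged_gauss_model()].
#' @return value in nats.
#' @export
phi_mi <- function(model) {
  J <- .joint_cov(model)
  n <- model$n
  h_parts <- vapply(model$partition, function(idx) {
    gaussian_entropy(J[c(idx, n + idx), c(idx, n + idx), drop = FALSE])
  }, numeric(1))
  .clip0(sum(h_parts) - gaussian_entropy(J))
}

#' Stochastic interaction (stochastic integrated information)
#'
#' Sum over parts of the conditional entropy of each part's present given
#' its own past, minus the conditional entropy of the whole present given
#' the whole past; conditional entropies are entropy differences of joint
#' and marginal blocks (Schur complements).
#'
#' @param model a [lagged_gauss_model()].
#' @return value in nats.
#' @export
phi_h <- function(model) {
  J <- .joint_cov(model)
  n <- model$n
  h_cond_parts <- vapply(model$partition, function(idx) {
    gaussian_entropy(J[c(idx, n + idx), c(idx, n + idx), drop = FALSE]) -
      gaussian_entropy(model$sigma_p[idx, idx, drop = FALSE])
  }, numeric(1))
  h_cond <- gaussian_entropy(J) - gaussian_entropy(model$sigma_p)
  .clip0(sum(h_cond_parts) - h_cond)
}

# Full and part-wise regressions of present on past.
.regressions <- function(model) {
  A <- t(model$sigma_cross) %*% solve(model$sigma_p)
  sigma_e <- model$sigma_t - A %*% model$sigma_cross
  n <- model$n
  Ad <- matrix(0, n, n)
  Sd <- matrix(0, n, n)
  for (idx in model$partition) {
    sp <- model$sigma_p[idx, idx, drop = FALSE]
    sc <- model$sigma_cross[idx, idx, drop = FALSE]
    st <- model$sigma_t[idx, idx, drop = FALSE]
    Ai <- t(sc) %*% solve(sp)
    Ad[idx, idx] <- Ai
    Sd[idx, idx] <- st - Ai %*% sc
  }
  list(A = A, sigma_e = sigma_e, Ad = Ad, Sd = Sd)
}

# Mismatched-decoding objective I~(beta) in closed Gaussian form.
.itilde <- function(beta, model, reg) {
  Q <- solve(reg$Sd)
  Sx <- model$sigma_p; Sy <- model$sigma_t; Sxy <- model$sigma_cross
  S <- Sy - reg$Ad %*% Sxy - t(Sxy) %*% t(reg$Ad) +
    reg$Ad %*% Sx %*% t(reg$Ad)
  M <- solve(Sx) + beta * t(reg$Ad) %*% Q %*% reg$Ad
  as.numeric(
    -(beta / 2) * sum(diag(Q %*% S)) +
      0.5 * determinant(Sx %*% M, logarithm = TRUE)$modulus +
      (beta / 2) * sum(diag(Q %*% Sy)) -
      (beta^2 / 2) * sum(diag(Q %*% reg$Ad %*% solve(M) %*% t(reg$Ad) %*% Q %*% Sy)))
}

#' Decoding-based integrated information (Phi*)
#'
#' `Phi* = I - I*`, where `I*` is the mismatched-decoding information
#' obtained when the decoder assumes the part-wise conditional model (each
#' part's present decoded from its own past only). `I*` maximises the
#' Gaussian closed-form decoding objective over the exponent beta on
#' `[0, Inf)`; the bracket is expanded geometrically and the maximum located
#' by golden-section/parabolic search to the requested tolerance.
#'
#' @param model a [lagged_gauss_model()].
#' @param tol optimisation tolerance on beta.
#' @return value in nats, with attributes `beta` (maximiser) and `I`.
#' @export
phi_star <- function(model, tol = 1e-8) {
  reg <- .regressions(model)
  I <- mutual_information(model)
  f <- function(b) .itilde(b, model, reg)
  hi <- 2
  repeat {
    opt <- optimize(f, c(0, hi), maximum = TRUE, tol = tol)
    f_hi <- f(hi)
    # expand only while the objective is still rising at the bracket end
    if (f_hi <= opt$objective + 1e-12 || hi > 1e6) break
    hi <- hi * 4
  }
  if (hi > 1e6)
    warning("decoding objective still rising at beta = 1e6; using boundary value")
  istar <- max(opt$objective, f_hi, 0)   # beta = 0 gives 0 by construction
  out <- .clip0(I - istar)
  attr(out, "beta") <- opt$maximum
  attr(out, "I") <- I
  out
}

#' Geometric integrated information (Phi_G)
#'
#' Minimum Kullback-Leibler divergence from the full Gaussian model to the
#' manifold of models with no cross-part past-to-present dependence (the
#' regression of present on past constrained to be partition-block-diagonal,
#' innovation covariance free). Computed by alternating exact coordinate
#' updates: the constrained regression solves a linear system, the
#' innovation covariance has a closed-form update; iteration stops when the
#' divergence changes by less than `tol`.
#'
#' @param model a [lagged_gauss_model()].
#' @param tol convergence tolerance on the divergence (nats).
#' @param max_iter iteration cap.
#' @return value in nats, with attributes `iterations` and `converged`.
#' @export
phi_g <- function(model, tol = 1e-10, max_iter = 1000) {
  reg <- .regressions(model)
  A <- reg$A; sigma_e <- reg$sigma_e; Sx <- model$sigma_p
  n <- model$n
  part_of <- integer(n)
  for (p in seq_along(model$partition)) part_of[model$partition[[p]]] <- p
  free <- which(outer(part_of, part_of, "=="), arr.ind = TRUE)
  Aq <- A * outer(part_of, part_of, "==")   # init: masked full regression
  kl_old <- Inf; it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    Dq <- A - Aq
    Sq <- sigma_e + Dq %*% Sx %*% t(Dq)
    kl <- 0.5 * (.logdet(Sq) - .logdet(sigma_e))
    if (abs(kl_old - kl) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    kl_old <- kl
    # exact update of the free entries of Aq given Sq:
    # (P (Aq - A) Sx)[r, c] = 0 for all free (r, c), with P = Sq^-1
    P <- solve(Sq)
    rhs_mat <- P %*% A %*% Sx
    nf <- nrow(free)
    K <- matrix(0, nf, nf)
    for (a in seq_len(nf)) {
      K[a, ] <- P[free[a, 1], free[, 1]] * Sx[free[, 2], free[a, 2]]
    }
    sol <- solve(K, rhs_mat[free])
    Aq[] <- 0
    Aq[free] <- sol
  }
  if (!converged && it >= max_iter)
    stop("geometric-phi minimisation did not converge within ", max_iter,
         " iterations")
  out <- .clip0(kl)
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  out
}

# measure name -> function
.phi_fun <- function(measure) {
  switch(measure,
         MI = phi_mi, H = phi_h, star = phi_star, G = phi_g,
         stop("unknown integrated-information measure: ", measure))
}

#' Sliding-window, tau-averaged integrated-information time course
#'
#' Windows of `win` samples slide by `stride` across a 750-sample epoch at
#' 125 Hz; within each window the measure is computed at every lag in
#' `tau_list` and averaged. The defaults (110-sample windows, stride 10)
#' produce 65 windows, 27 of which lie entirely before the time reference
#' and 38 after or straddling it.
#'
#' @param X channels x samples matrix (downsampled epoch; the reference sits
#'   at sample `ref_sample`).
#' @param measure one of `"MI"`, `"H"`, `"star"`, `"G"`.
#' @param tau_list lags in samples (default 1:10).
#' @param win,stride window length and step in samples.
#' @param ref_sample index of the time-reference sample.
#' @param partition passed to [estimate_lagged_cov()].
#' @param sr sampling rate of `X` (for the time axis only).
#' @return tibble: `window`, `start`, `centre_s` (s relative to the
#'   reference), `condition` (before/after), `value` (tau-averaged, nats).
#' @export
phi_timecourse <- function(X, measure = "MI", tau_list = 1:10, win = 110,
                           stride = 10, ref_sample = NULL, partition = NULL,
                           sr = 125) {
  m <- ncol(X)
  ref_sample <- ref_sample %||% (m %/% 2 + 1)
  if (win <= max(tau_list) + nrow(X))
    stop("window too short for the largest lag and channel count")
  f <- .phi_fun(measure)
  starts <- seq(1, m - win + 1, by = stride)
  vals <- vapply(starts, function(s) {
    seg <- X[, s:(s + win - 1), drop = FALSE]
    mean(vapply(tau_list, function(tau) {
      as.numeric(f(estimate_lagged_cov(seg, tau, partition)))
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(
    window = seq_along(starts),
    start = starts,
    centre_s = (starts + (win - 1) / 2 - ref_sample) / sr,
    condition = ifelse(starts + win - 1 < ref_sample, "before", "after"),
    value = vals, measure = measure)
}

#' Integrated-information features for a dataset
#'
#' Restricts each epoch to the channels of one cluster (the temporal cluster
#' by default), downsamples to 125 Hz and computes the tau-averaged
#' time course of the requested measure per trial.
#'
#' @param epochs an [epoch_array()].
#' @param cluster cluster code to analyse.
#' @param map channel -> cluster map.
#' @param measure,tau_list,win,stride passed to [phi_timecourse()].
#' @param sr_out downsampling target rate (Hz).
#' @return long tibble: `subject`, `trial`, `detection`, `window`,
#'   `condition`, `centre_s`, `measure`, `value`.
#' @export
phi_features <- function(epochs, cluster = "T", map = default_cluster_map(),
                         measure = "MI", tau_list = 1:10, win = 110,
                         stride = 10, sr_out = 125) {
  stopifnot(inherits(epochs, "epoch_array"))
  ch_idx <- which(map[epochs$channels] == cluster)
  if (length(ch_idx) < 2)
    stop("need at least two channels in cluster ", cluster)
  n_out <- dim(epochs$data)[3] * sr_out / epochs$sr
  ref_sample <- round(-epochs$t0 * sr_out) + 1
  rows <- lapply(seq_len(dim(epochs$data)[1]), function(i) {
    Xd <- resample_fourier(epochs$data[i, ch_idx, , drop = TRUE], n_out = n_out)
    tc <- phi_timecourse(Xd, measure = measure, tau_list = tau_list,
                         win = win, stride = stride,
                         ref_sample = ref_sample, sr = sr_out)
    tc$subject <- epochs$subject[i]
    tc$trial <- i
    tc$detection <- epochs$labels[i]
    tc
  })
  dplyr::bind_rows(rows)[, c("subject", "trial", "detection", "window",
                             "condition", "centre_s", "measure", "value")]
}
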