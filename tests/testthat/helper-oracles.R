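# Independent brute-force oracles. These deliberately use naive algorithms
# (explicit loops, direct DFT sums, string pattern keys, grid quadrature)
# that share no code path with the package implementations.

oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    N <- length(x)
    M <- N - mm + 1
    cs <- numeric(M)
    for (i in 1:M) {
      cnt <- 0
      for (j in 1:M) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      cs[i] <- log(cnt / M)
    }
    mean(cs)
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m, r) {
  N <- length(x)
  M <- N - m
  A <- 0; B <- 0
  for (i in 1:(M - 1)) {
    for (j in (i + 1):M) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

oracle_pe <- function(x, order, delay) {
  n_pat <- length(x) - (order - 1) * delay
  keys <- character(n_pat)
  for (i in 1:n_pat) {
    v <- x[i + (0:(order - 1)) * delay]
    keys[i] <- paste(order(v), collapse = "-")  # order() is stable on ties
  }
  p <- table(keys) / n_pat
  -sum(p * log2(p)) / log2(factorial(order))
}

oracle_sven <- function(x, order, delay) {
  n_row <- length(x) - (order - 1) * delay
  Y <- matrix(0, n_row, order)
  for (j in 1:order) Y[, j] <- x[(1:n_row) + (j - 1) * delay]
  ev <- eigen(t(Y) %*% Y, symmetric = TRUE, only.values = TRUE)$values
  s <- sqrt(pmax(ev, 0))
  s <- s / sum(s)
  s <- s[s > 0]
  -sum(s * log2(s)) / log2(order)
}

# direct DFT periodogram (no fft), one-sided bins DC..Nyquist
oracle_spen <- function(x) {
  n <- length(x)
  nb <- n %/% 2 + 1
  p <- numeric(nb)
  for (k in 0:(nb - 1)) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    p[k + 1] <- re^2 + im^2
  }
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(nb)
}

# grid quadrature of -integral p log p for a small Gaussian (d <= 4)
oracle_gauss_entropy_grid <- function(sigma, half = 6, n_grid = NULL) {
  d <- nrow(sigma)
  n_grid <- if (is.null(n_grid)) c(4001, 401, 61, 41)[d] else n_grid
  sds <- sqrt(diag(sigma))
  axes <- lapply(sds, function(s) seq(-half * s, half * s, length.out = n_grid))
  G <- as.matrix(expand.grid(axes))
  w <- prod(vapply(axes, function(a) a[2] - a[1], numeric(1)))
  Si <- solve(sigma)
  logp <- -0.5 * rowSums((G %*% Si) * G) -
    0.5 * (d * log(2 * pi) + determinant(sigma)$modulus[1])
  p <- exp(logp)
  -sum(p * logp) * w
}

# quadrature oracle for the mismatched-decoding objective on a 2-channel
# model: term 1 in closed (quadratic) expectation, term 2 by nested 2-d grids
oracle_itilde <- function(beta, model, grid_n = 81, half = 5) {
  Sx <- model$sigma_p; Sy <- model$sigma_t; Sxy <- model$sigma_cross
  Ad <- matrix(0, 2, 2); Sd <- matrix(0, 2, 2)
  for (i in 1:2) {
    Ad[i, i] <- Sxy[i, i] / Sx[i, i]
    Sd[i, i] <- Sy[i, i] - Sxy[i, i]^2 / Sx[i, i]
  }
  Q <- solve(Sd)
  S <- Sy - Ad %*% Sxy - t(Sxy) %*% t(Ad) + Ad %*% Sx %*% t(Ad)
  t1 <- beta * (-log(2 * pi) - 0.5 * log(det(Sd)) - 0.5 * sum(diag(Q %*% S)))
  g <- seq(-half, half, length.out = grid_n)
  gy1 <- g * sqrt(Sy[1, 1]); gy2 <- g * sqrt(Sy[2, 2])
  GY <- as.matrix(expand.grid(gy1, gy2))
  wy <- (gy1[2] - gy1[1]) * (gy2[2] - gy2[1])
  py <- exp(-0.5 * rowSums((GY %*% solve(Sy)) * GY)) / (2 * pi * sqrt(det(Sy)))
  gx1 <- g * sqrt(Sx[1, 1]); gx2 <- g * sqrt(Sx[2, 2])
  GX <- as.matrix(expand.grid(gx1, gx2))
  wx <- (gx1[2] - gx1[1]) * (gx2[2] - gx2[1])
  px <- exp(-0.5 * rowSums((GX %*% solve(Sx)) * GX)) / (2 * pi * sqrt(det(Sx)))
  MU <- GX %*% t(Ad)
  lnr <- vapply(seq_len(nrow(GY)), function(i) {
    dm <- matrix(GY[i, ], nrow(GX), 2, byrow = TRUE) - MU
    lq <- -log(2 * pi) - 0.5 * log(det(Sd)) - 0.5 * rowSums((dm %*% Q) * dm)
    log(sum(px * exp(beta * lq)) * wx)
  }, numeric(1))
  t1 - sum(py * lnr * wy)
}

# random stable VAR(1)-derived lagged Gaussian model (stationary)
rand_lagged_model <- function(n = 3, tau = 1, scale = 0.4) {
  repeat {
    A <- matrix(rnorm(n * n, 0, scale), n)
    if (max(Mod(eigen(A, only.values = TRUE)$values)) < 0.95) break
  }
  SE <- crossprod(matrix(rnorm(n * n), n)) + diag(n) * 0.3
  Sig <- matrix(solve(diag(n * n) - kronecker(A, A), as.vector(SE)), n)
  Sc <- Sig %*% t(A)
  if (tau > 1) for (k in 2:tau) Sc <- Sc %*% t(A)
  lagged_gauss_model(Sig, Sig, Sc, tau = tau)
}
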