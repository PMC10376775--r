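test_that("lagged covariance estimation matches AR(1) theory", {
  set.seed(1)
  # white noise: cross-covariance vanishes with n
  X <- matrix(rnorm(2 * 20000), 2)
  m <- estimate_lagged_cov(X, tau = 1)
  expect_lt(max(abs(m$sigma_cross)), 0.03)
  # scalar AR(1): lagged correlation is a^tau
  a <- 0.8
  x <- as.numeric(stats::filter(rnorm(50000), a, method = "recursive"))
  for (tau in c(1, 3)) {
    m2 <- estimate_lagged_cov(rbind(x, rnorm(50000)), tau = tau)
    expect_equal(m2$sigma_cross[1, 1] / m2$sigma_p[1, 1], a^tau,
                 tolerance = 0.05)
  }
  expect_error(estimate_lagged_cov(X, tau = 0), "positive integer")
  expect_error(estimate_lagged_cov(X[, 1:3], tau = 1), "more samples")
})

test_that("Gaussian entropy has its closed form and additivity", {
  expect_equal(gaussian_entropy(matrix(1)), 0.5 * log(2 * pi * exp(1)))
  expect_equal(gaussian_entropy(matrix(1)), 1.4189385, tolerance = 1e-6)
  S <- diag(c(2, 3))
  expect_equal(gaussian_entropy(S),
               gaussian_entropy(matrix(2)) + gaussian_entropy(matrix(3)))
  expect_equal(gaussian_entropy(matrix(4)) - gaussian_entropy(matrix(1)),
               0.5 * log(4))
  expect_error(gaussian_entropy(matrix(-1)), "not positive definite")
  # grid-quadrature oracle agreement (1-d and 2-d)
  expect_equal(gaussian_entropy(matrix(1.7)),
               oracle_gauss_entropy_grid(matrix(1.7)), tolerance = 1e-4)
  S2 <- matrix(c(1, 0.6, 0.6, 2), 2)
  expect_equal(gaussian_entropy(S2), oracle_gauss_entropy_grid(S2),
               tolerance = 1e-3)
})

test_that("mutual information reduces to the bivariate closed form", {
  S <- diag(2)
  m0 <- lagged_gauss_model(S, S, matrix(0, 2, 2))
  expect_equal(mutual_information(m0), 0)
  for (rho in c(0.3, 0.7)) {
    m1 <- lagged_gauss_model(matrix(1), matrix(1), matrix(rho), tau = 1,
                             partition = list(1))
    expect_equal(mutual_information(m1), -0.5 * log(1 - rho^2),
                 tolerance = 1e-10)
  }
  set.seed(2)
  for (i in 1:20) expect_gte(mutual_information(rand_lagged_model()), 0)
})

test_that("the four measures vanish for independent channels", {
  S <- diag(3)
  m <- lagged_gauss_model(S, S, matrix(0, 3, 3))
  expect_equal(phi_mi(m), 0, tolerance = 1e-9)
  expect_equal(phi_h(m), 0, tolerance = 1e-9)
  expect_equal(as.numeric(phi_star(m)), 0, tolerance = 1e-9)
  expect_equal(as.numeric(phi_g(m)), 0, tolerance = 1e-9)
  # lag-diagonal but dependent-within-channel model is also independent
  md <- lagged_gauss_model(S, S, diag(0.5, 3))
  expect_equal(phi_mi(md), 0, tolerance = 1e-9)
  expect_equal(phi_h(md), 0, tolerance = 1e-9)
})

test_that("two-channel instantaneous-correlation closed forms hold", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  m <- lagged_gauss_model(S, S, matrix(0, 2, 2))
  expect_equal(phi_mi(m), -log(1 - 0.25), tolerance = 1e-6)   # 0.2877 nats
  expect_equal(phi_mi(m), 0.2876821, tolerance = 1e-6)
  expect_equal(phi_h(m), -0.5 * log(1 - 0.25), tolerance = 1e-6)  # 0.1438
  expect_equal(phi_h(m), 0.1438410, tolerance = 1e-6)
  # monotone in |rho|
  vals <- vapply(c(0.1, 0.3, 0.5, 0.7), function(r) {
    Sr <- matrix(c(1, r, r, 1), 2)
    phi_mi(lagged_gauss_model(Sr, Sr, matrix(0, 2, 2)))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the decoding objective matches a quadrature oracle", {
  set.seed(42)
  m <- rand_lagged_model(2)
  reg <- maskaware:::.regressions(m)
  for (beta in c(0.5, 1, 2)) {
    expect_equal(maskaware:::.itilde(beta, m, reg), oracle_itilde(beta, m),
                 tolerance = 1e-3)
  }
})

test_that("multi-information agrees with grid-quadrature entropies", {
  set.seed(9)
  m <- rand_lagged_model(2, scale = 0.3)
  J <- rbind(cbind(m$sigma_p, m$sigma_cross),
             cbind(t(m$sigma_cross), m$sigma_t))
  h_parts <- oracle_gauss_entropy_grid(J[c(1, 3), c(1, 3)]) +
    oracle_gauss_entropy_grid(J[c(2, 4), c(2, 4)])
  h_joint <- oracle_gauss_entropy_grid(J, half = 5, n_grid = 41)
  expect_equal(phi_mi(m), h_parts - h_joint, tolerance = 1e-3)
})

test_that("phi-star and geometric phi are bounded by mutual information", {
  set.seed(3)
  for (i in 1:60) {
    m <- rand_lagged_model(3)
    I <- mutual_information(m)
    ps <- as.numeric(phi_star(m))
    pg <- as.numeric(phi_g(m))
    expect_gte(ps, 0); expect_lte(ps, I + 1e-6)
    expect_gte(pg, 0); expect_lte(pg, I + 1e-6)
    expect_gte(phi_h(m), 0)
    expect_gte(phi_mi(m), 0)
  }
})

test_that("geometric phi is zero on the constraint manifold", {
  # block-diagonal regression with independent innovations
  A <- diag(c(0.6, -0.4))
  SE <- diag(c(1, 0.5))
  Sig <- diag(diag(SE) / (1 - diag(A)^2))
  m <- lagged_gauss_model(Sig, Sig, Sig %*% t(A))
  expect_equal(as.numeric(phi_g(m)), 0, tolerance = 1e-9)
  expect_true(attr(phi_g(m), "converged"))
})

test_that("the time course uses 65 windows split 27 before / 38 after", {
  set.seed(10)
  X <- matrix(rnorm(4 * 750), 4)
  tc <- phi_timecourse(X, measure = "MI")
  expect_equal(nrow(tc), 65)
  expect_equal(sum(tc$condition == "before"), 27)
  expect_equal(sum(tc$condition == "after"), 38)
  # single-tau list reduces to the per-window measure
  tc1 <- phi_timecourse(X, measure = "MI", tau_list = 2)
  seg <- X[, 1:110]
  expect_equal(tc1$value[1],
               phi_mi(estimate_lagged_cov(seg, 2)), tolerance = 1e-12)
  # stationary input gives a flat course within sampling error
  expect_lt(sd(tc$value), mean(tc$value))
  expect_error(phi_timecourse(X, win = 12), "too short")
})

test_that("a coupling step-down at the reference drops the MI time course", {
  set.seed(12)
  n <- 750
  shared <- rnorm(n)
  g <- c(rep(0.7, 375), rep(0.05, 375))
  X <- t(vapply(1:3, function(i) sqrt(1 - g) * rnorm(n) + sqrt(g) * shared,
                numeric(n)))
  tc <- phi_timecourse(X, measure = "MI", tau_list = 1:3)
  expect_gt(mean(tc$value[tc$condition == "before"]),
            2 * mean(tc$value[tc$condition == "after"]))
})
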