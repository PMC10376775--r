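test_that("epoch windowing yields 24 exact windows that tile the epoch", {
  x <- rnorm(24000)
  w <- window_epoch(x)
  expect_equal(dim(w), c(24, 1000))
  expect_equal(as.vector(t(w)), x)           # concatenation reproduces input
  # window 13 starts at the time reference (3 s at 4 kHz -> sample 12001)
  expect_equal(w[13, 1], x[12001])
  expect_error(window_epoch(rnorm(1001)), "divisible")
})

test_that("spectral entropy behaves on pure tones, pairs and noise", {
  n <- 1000
  t <- (0:(n - 1)) / n
  expect_lt(spectral_entropy(sin(2 * pi * 50 * t)), 1e-6)
  two <- sin(2 * pi * 50 * t) + sin(2 * pi * 120 * t)
  expect_equal(spectral_entropy(two), log2(2) / log2(n / 2 + 1),
               tolerance = 1e-6)
  # white noise: expected value of the normalised periodogram entropy is
  # log2(M) - (1 - gamma)/ln 2 bits (exponential bin weights), about 0.932
  set.seed(11)
  v <- mean(replicate(40, spectral_entropy(rnorm(n))))
  expect_equal(v, 1 - (1 - 0.5772157) / log(2) / log2(n / 2 + 1),
               tolerance = 0.01)
  expect_warning(z <- spectral_entropy(numeric(1000)), "all-zero")
  expect_equal(z, 0)
  expect_error(spectral_entropy(rnorm(4)), "too short")
})

test_that("approximate entropy matches its definition and invariances", {
  expect_equal(approximate_entropy(rep(1, 50) + 0), 0)
  x <- rep(c(1, 2), 50)
  expect_equal(approximate_entropy(x, m = 2, r = 0.5, r_is_fraction = FALSE),
               oracle_apen(x, 2, 0.5), tolerance = 1e-10)
  set.seed(1)
  y <- rnorm(120)
  expect_equal(approximate_entropy(y), approximate_entropy(5 * y - 3))
  expect_error(approximate_entropy(y, r = 0), "positive")
})

test_that("sample entropy follows the Richman-Moorman convention", {
  expect_equal(sample_entropy(rep(c(1, 2), 4), m = 2, r = 0.5,
                              r_is_fraction = FALSE), 0)
  expect_equal(sample_entropy(rep(1, 30) + 0, r = 0.2, r_is_fraction = FALSE), 0)
  # long i.i.d. data: SaEn and ApEn estimate the same quantity (agreement
  # needs dense template matches, hence the wider tolerance radius)
  set.seed(2)
  z <- rnorm(2000)
  expect_equal(sample_entropy(z, r = 0.3), approximate_entropy(z, r = 0.3),
               tolerance = 0.05)
  set.seed(3)
  expect_warning(sample_entropy(c(1, 5, -4, 9, -7, 12, -20, 33), m = 2,
                                r = 0.01, r_is_fraction = FALSE), "undefined")
})

test_that("permutation entropy counts ordinal patterns with stable ties", {
  expect_equal(permutation_entropy(1:50), 0)       # single ascending pattern
  expect_equal(permutation_entropy(rep(2, 50)), 0) # ties rank by occurrence
  expect_equal(permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), order = 2),
               0.9182958, tolerance = 1e-6)
  set.seed(4)
  expect_equal(permutation_entropy(runif(1000)), 1, tolerance = 0.02)
  expect_error(permutation_entropy(1:3, order = 5), "too short")
})

test_that("SVD entropy reflects embedding rank", {
  expect_equal(svd_entropy(rep(3, 100)), 0, tolerance = 1e-9)
  set.seed(5)
  w <- rnorm(2000)
  expect_equal(svd_entropy(w), 1, tolerance = 0.01)
  expect_equal(svd_entropy(w), svd_entropy(-w))
  expect_warning(svd_entropy(numeric(50)), "all-zero")
})

test_that("estimators are invariant to affine rescaling of the window", {
  set.seed(6)
  x <- rnorm(400)
  y <- -2.5 * x + 7
  expect_equal(spectral_entropy(x - mean(x)), spectral_entropy(-2.5 * (x - mean(x))))
  expect_equal(approximate_entropy(x), approximate_entropy(y))
  expect_equal(sample_entropy(x), sample_entropy(y))
  expect_equal(permutation_entropy(-x + 2), permutation_entropy(-x * 3 + 1))
  expect_equal(svd_entropy(x * 4), svd_entropy(x))
})

test_that("all five estimators match brute-force oracles on short sequences", {
  set.seed(7)
  p <- entropy_params()
  for (i in 1:12) {
    x <- rnorm(50)
    r_abs <- p$r * sd(x)
    expect_equal(approximate_entropy(x), oracle_apen(x, 2, r_abs),
                 tolerance = 1e-10)
    expect_equal(suppressWarnings(sample_entropy(x)),
                 oracle_sampen(x, 2, r_abs), tolerance = 1e-10)
    expect_equal(permutation_entropy(x), oracle_pe(x, 3, 1), tolerance = 1e-10)
    expect_equal(svd_entropy(x), oracle_sven(x, 3, 1), tolerance = 1e-10)
    expect_equal(spectral_entropy(x), oracle_spen(x), tolerance = 1e-10)
  }
})

test_that("entropy features carry the window bookkeeping of the epoch", {
  set.seed(8)
  dat <- array(rnorm(2 * 4 * 6000), c(2, 4, 6000))
  ep <- epoch_array(dat, 1000, c("FC1", "FC2", "T7", "T8"),
                    labels = c("hit", "miss"))
  fe <- entropy_features(ep, measures = c("PeEn", "SvEn"))
  expect_setequal(unique(fe$condition), c("before", "after"))
  expect_equal(max(fe$window), 11)        # edge windows dropped
  expect_setequal(unique(fe$cluster), c("FC", "T"))
  expect_equal(nrow(fe), 2 * 22 * 2 * 2)  # trials x windows x clusters x measures
  fe_all <- entropy_features(ep, measures = "PeEn", keep_edges = TRUE)
  expect_equal(max(fe_all$window), 12)
  agg <- aggregate_entropy(fe)
  expect_equal(nrow(agg), 2 * 2 * 2 * 2)  # subj x det fused: 1 subj here
  expect_true(all(agg$value > 0 & agg$value < 1))
})
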