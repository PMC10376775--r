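test_that("the mixed model degenerates to OLS when intercept variance is zero", {
  set.seed(1)
  d <- tibble::tibble(
    subject = rep(sprintf("S%d", 1:6), each = 40),
    detection = rep(rep(c("hit", "miss"), each = 20), 6),
    value = rnorm(240) + ifelse(rep(rep(c(TRUE, FALSE), each = 20), 6), 0.5, 0))
  m <- suppressWarnings(fit_lmm(d, "detection"))
  ols <- lm(value ~ detection, data = within(d, {
    detection <- factor(detection); contrasts(detection) <- contr.sum(2)
  }))
  expect_equal(unname(lme4::fixef(m)), unname(coef(ols)), tolerance = 0.02)
  expect_error(fit_lmm(d[d$subject == "S1", ], "detection"), "2 subjects")
})

test_that("a configured contrast is recovered by emmeans on balanced data", {
  set.seed(2)
  eff <- c(hit = 0.3, miss = 0)
  d <- expand.grid(subject = sprintf("S%d", 1:8),
                   detection = c("hit", "miss"), rep = 1:15,
                   stringsAsFactors = FALSE)
  b <- rnorm(8, 0, 0.5)
  d$value <- b[match(d$subject, sprintf("S%d", 1:8))] +
    eff[d$detection] + rnorm(nrow(d), 0, 0.3)
  m <- fit_lmm(d, "detection")
  ct <- emmeans_contrasts(m, "detection")
  expect_lt(abs(ct$estimate - 0.3), 3 * ct$SE)
  # balanced one-factor design: marginal means equal cell means
  em <- summary(emmeans::emmeans(m, "detection"))
  cells <- tapply(d$value, d$detection, mean)
  expect_equal(unname(em$emmean[match(names(cells), em$detection)]),
               as.numeric(cells), tolerance = 1e-6)
})

test_that("Bonferroni adjustment multiplies by family size and never lowers p", {
  set.seed(3)
  d <- expand.grid(subject = sprintf("S%d", 1:6),
                   detection = c("hit", "miss"),
                   cluster = c("AF", "FC", "T", "S"), rep = 1:8,
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d)) + ifelse(d$cluster == "FC" & d$detection == "hit",
                                     1, 0)
  m <- fit_lmm(d, "detection * cluster")
  ct <- emmeans_contrasts(m, "detection", by = "cluster")
  expect_equal(attr(ct, "family_size"), 4)
  raw <- 2 * pt(-abs(ct$t_ratio), ct$df)
  expect_equal(ct$p_adjusted, pmin(raw * 4, 1), tolerance = 1e-8)
  expect_true(all(ct$p_adjusted >= raw - 1e-12))
  one <- emmeans_contrasts(m, "detection")
  raw1 <- 2 * pt(-abs(one$t_ratio), one$df)
  expect_equal(one$p_adjusted, pmin(raw1, 1), tolerance = 1e-8)  # family of 1
})

test_that("partial eta squared follows its closed form", {
  expect_equal(partial_eta_squared(0, 3, 100), 0)
  expect_equal(partial_eta_squared(10.3, 3, 101), 0.2343, tolerance = 1e-3)
  f <- c(1, 2, 5, 10, 50)
  expect_true(all(diff(partial_eta_squared(f, 3, 100)) > 0))
  expect_error(partial_eta_squared(-1, 3, 100), "non-negative")
})

test_that("anova table exposes F, Satterthwaite df and effect size", {
  set.seed(4)
  d <- expand.grid(subject = sprintf("S%d", 1:6),
                   detection = c("hit", "miss"), rep = 1:10,
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d)) + (d$detection == "hit") * 1.2
  m <- fit_lmm(d, "detection")
  at <- anova_table(m)
  expect_equal(at$term, "detection")
  expect_lt(at$p, 0.001)
  expect_equal(at$peta2, partial_eta_squared(at$F, at$df1, at$df2))
  lrt <- random_intercept_lrt(m)
  expect_true(is.finite(lrt$LRT) && lrt$LRT >= 0)
})

test_that("simulated power is the test size under the null and grows with d and n", {
  p0 <- power_simulation(n_subjects = 6, n_blocks = 2, items_per_block = 10,
                         d = 0, icc = 0.4, n_reps = 400, seed = 10)
  expect_lt(p0$ci[1], 0.05)
  expect_gt(p0$ci[2], 0.03)
  p_small <- power_simulation(n_subjects = 6, n_blocks = 2, items_per_block = 10,
                              d = 0.15, icc = 0.4, n_reps = 300, seed = 11)
  p_large <- power_simulation(n_subjects = 6, n_blocks = 2, items_per_block = 10,
                              d = 0.8, icc = 0.4, n_reps = 300, seed = 12)
  expect_gt(p_large$power, p_small$power)
  expect_gt(p_large$power, 0.95)
  p_more_n <- power_simulation(n_subjects = 18, n_blocks = 2, items_per_block = 10,
                               d = 0.15, icc = 0.4, n_reps = 300, seed = 13)
  expect_gte(p_more_n$power, p_small$power - 0.05)
  expect_error(power_simulation(n_reps = 50), "at least 200")
})

test_that("simulated power tracks the analytic noncentral-t benchmark", {
  des <- list(n_subjects = 8, n_blocks = 2, items_per_block = 10)
  for (case in list(c(d = 0.2, icc = 0.5), c(d = 0.35, icc = 0.3))) {
    sim <- power_simulation(n_subjects = des$n_subjects, n_blocks = des$n_blocks,
                            items_per_block = des$items_per_block,
                            d = case[["d"]], icc = case[["icc"]],
                            n_reps = 500, seed = 20)
    ana <- power_analytic(n_subjects = des$n_subjects, n_blocks = des$n_blocks,
                          items_per_block = des$items_per_block,
                          d = case[["d"]], icc = case[["icc"]])
    expect_lt(abs(sim$power - ana), 0.07)
  }
})
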