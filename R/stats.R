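#' Fit a linear mixed-effects model with a subject random intercept
#'
#' Experimental factors (detection, condition, cluster, window, tone, ...)
#' enter as fixed effects; the subject enters as a random intercept. Models
#' are estimated by maximum likelihood. Character columns among the fixed
#' factors are converted to factors with sum-to-zero contrasts so that
#' F tests of interactions are interpretable.
#'
#' @param data tibble of observations; must contain `subject` and the
#'   response.
#' @param fixed right-hand-side formula string for the fixed effects, e.g.
#'   `"detection * condition * cluster"`. The window factor must always
#'   appear nested in condition (e.g. `"detection * condition / window_f"`).
#' @param response response column name.
#' @return a fitted `lmerModLmerTest` object.
#' @export
fit_lmm <- function(data, fixed = "detection * condition * cluster",
                    response = "value") {
  if (length(unique(data$subject)) < 2)
    stop("mixed model needs at least 2 subjects")
  vars <- intersect(all.vars(as.formula(paste("~", fixed))), names(data))
  for (v in vars) {
    if (is.character(data[[v]]) || is.logical(data[[v]]))
      data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(data[[v]]) > 1)
      stats::contrasts(data[[v]]) <- stats::contr.sum(nlevels(data[[v]]))
  }
  fml <- as.formula(paste(response, "~", fixed, "+ (1 | subject)"))
  m <- lmerTest::lmer(fml, data = data, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
  if (lme4::isSingular(m))
    warning("singular fit: a variance component is estimated at the boundary")
  m
}

#' ANOVA table with partial eta squared
#'
#' Type III F tests with Satterthwaite denominator degrees of freedom,
#' augmented with the partial eta squared effect size
#' `F df1 / (F df1 + df2)`.
#'
#' @param model a model from [fit_lmm()].
#' @return tibble: `term`, `F`, `df1`, `df2`, `p`, `peta2`.
#' @export
anova_table <- function(model) {
  a <- stats::anova(model, type = 3)
  tibble::tibble(term = rownames(a), F = a[["F value"]],
                 df1 = a$NumDF, df2 = a$DenDF,
                 p = a[["Pr(>F)"]],
                 peta2 = partial_eta_squared(a[["F value"]], a$NumDF, a$DenDF))
}

#' Partial eta squared from an F statistic
#'
#' `F df1 / (F df1 + df2)`.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return value in `[0, 1]`.
#' @export
partial_eta_squared <- function(f, df1, df2) {
  if (any(f < 0)) stop("F must be non-negative")
  f * df1 / (f * df1 + df2)
}

#' Estimated-marginal-means pairwise contrasts with Bonferroni adjustment
#'
#' Marginal means per cell of `pair_var` within each level of `by`,
#' averaged over the remaining factor levels, with pairwise differences
#' tested against the model's fixed-effect covariance. p values are
#' Bonferroni-multiplied by the family size and capped at 1.
#'
#' @param model a model from [fit_lmm()].
#' @param pair_var factor whose levels are compared (e.g. `"detection"`).
#' @param by optional stratifying factor(s) (e.g. `"cluster"`).
#' @param adjust multiplicity adjustment (default `"bonferroni"`).
#' @return tibble with columns `contrast`, the `by` columns, `estimate`,
#'   `SE`, `df`, `t_ratio`, `p_adjusted`; the Bonferroni family size is
#'   attached as attribute `family_size`.
#' @export
emmeans_contrasts <- function(model, pair_var = "detection", by = NULL,
                              adjust = "bonferroni") {
  em <- emmeans::emmeans(model, specs = pair_var, by = by,
                         lmer.df = "satterthwaite")
  pr <- summary(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  fam <- nrow(pr)
  out <- tibble::as_tibble(pr)
  names(out)[names(out) == "t.ratio"] <- "t_ratio"
  out$p_adjusted <- if (identical(adjust, "bonferroni"))
    pmin(out$p.value * fam, 1) else stats::p.adjust(out$p.value, method = adjust)
  out$p.value <- NULL
  attr(out, "family_size") <- fam
  out
}

#' Likelihood-ratio test of the subject random intercept
#'
#' Compares the ML-fitted mixed model against the corresponding fixed-effects
#' model without random effects (the "null model" comparison), on one
#' degree of freedom.
#'
#' @param model a model from [fit_lmm()].
#' @return tibble with `LRT`, `df`, `p`.
#' @export
random_intercept_lrt <- function(model) {
  fr <- model.frame(model)
  fixed_fml <- lme4::nobars(formula(model))
  null_fit <- stats::lm(fixed_fml, data = fr)
  lrt <- max(0, 2 * (as.numeric(stats::logLik(model)) -
                       as.numeric(stats::logLik(null_fit))))
  tibble::tibble(LRT = lrt, df = 1,
                 p = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Monte-Carlo power of a within-subject effect in a random-intercept model
#'
#' Simulates a balanced design of `n_subjects` subjects, each contributing
#' `n_blocks` blocks of `items_per_block` observations split evenly between
#' the two levels of a within-subject factor. Total variance is 1 and is
#' decomposed into a subject-intercept share `icc` and a residual share
#' `1 - icc`; the factor shifts observations by `d` total-SD units. Each
#' replicate fits the random-intercept mixed model and tests the effect at
#' `alpha`; power is the rejection fraction with an exact binomial CI.
#'
#' @param n_subjects number of subjects.
#' @param n_blocks,items_per_block design size per subject.
#' @param d standardised effect (total-SD units).
#' @param icc intraclass correlation (subject-intercept variance share).
#' @param alpha test level.
#' @param n_reps Monte-Carlo replicates.
#' @param seed optional integer seed.
#' @param df_method `"normal"` (Wald z, appropriate for the >1000 residual
#'   degrees of freedom of the default design) or `"satterthwaite"`.
#' @return list with `power`, `ci` (95% binomial), `n_reps`, `n_obs`, and
#'   the design parameters.
#' @export
power_simulation <- function(n_subjects = 15, n_blocks = 4,
                             items_per_block = 20, d = 0.44, icc = 0.5,
                             alpha = 0.05, n_reps = 1000, seed = NULL,
                             df_method = c("normal", "satterthwaite")) {
  df_method <- match.arg(df_method)
  if (n_reps < 200) stop("use at least 200 replicates")
  if (icc < 0 || icc >= 1) stop("icc must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  obs <- n_blocks * items_per_block
  base <- tibble::tibble(
    subject = factor(rep(seq_len(n_subjects), each = obs)),
    x = rep(rep(0:1, each = items_per_block / 2), n_blocks * n_subjects))
  n_tot <- nrow(base)
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    b <- rnorm(n_subjects, 0, sqrt(icc))
    y <- b[as.integer(base$subject)] + d * base$x +
      rnorm(n_tot, 0, sqrt(1 - icc))
    if (df_method == "normal") {
      m <- suppressMessages(lme4::lmer(y ~ x + (1 | subject), data = base,
                                       REML = FALSE,
                                       control = lme4::lmerControl(calc.derivs = FALSE)))
      tv <- stats::coef(summary(m))["x", "t value"]
      p <- 2 * pnorm(-abs(tv))
    } else {
      m <- suppressMessages(lmerTest::lmer(y ~ x + (1 | subject), data = base,
                                           REML = FALSE))
      p <- stats::coef(summary(m))["x", "Pr(>|t|)"]
    }
    rej[r] <- p < alpha
  }
  ci <- as.numeric(binom.test(sum(rej), n_reps)$conf.int)
  list(power = mean(rej), ci = ci, n_reps = n_reps, n_obs = n_tot,
       n_subjects = n_subjects, d = d, icc = icc, alpha = alpha)
}

#' Power sweep over a grid of intraclass correlations
#'
#' @param icc_grid ICC values to sweep.
#' @param ... passed to [power_simulation()].
#' @return tibble with one row per ICC (`icc`, `power`, `ci_lo`, `ci_hi`).
#' @export
power_curve <- function(icc_grid = c(0.3, 0.4, 0.5, 0.6), ...) {
  rows <- lapply(icc_grid, function(icc) {
    p <- power_simulation(icc = icc, ...)
    tibble::tibble(icc = icc, power = p$power,
                   ci_lo = p$ci[1], ci_hi = p$ci[2], n_obs = p$n_obs)
  })
  dplyr::bind_rows(rows)
}

#' Closed-form power approximation for the same design
#'
#' Analytic noncentral-t benchmark for [power_simulation()]: in the
#' balanced within-subject design the intercepts cancel from the effect
#' contrast, so the noncentrality is `d / sqrt(4 (1 - icc) / N)` against a
#' t reference with `N - n_subjects - 1` degrees of freedom.
#'
#' @inheritParams power_simulation
#' @return power (proportion).
#' @export
power_analytic <- function(n_subjects = 15, n_blocks = 4,
                           items_per_block = 20, d = 0.44, icc = 0.5,
                           alpha = 0.05) {
  N <- n_subjects * n_blocks * items_per_block
  ncp <- d / sqrt(4 * (1 - icc) / N)
  df <- N - n_subjects - 1
  crit <- qt(1 - alpha / 2, df)
  pt(-crit, df, ncp) + 1 - pt(crit, df, ncp)
}
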