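#' Build a 240-trial experimental session
#'
#' 160 target-present and 80 target-absent trials, balanced over the four
#' masker densities (40 present + 20 absent per density), shuffled and split
#' into 4 blocks of 60 trials. Target frequencies for present trials are
#' drawn from the five-element target set. Composition counts are exact, not
#' expected values.
#'
#' @param subject subject identifier stored in the table.
#' @param seed optional integer seed.
#' @return tibble with columns `subject`, `block`, `trial`, `target_present`,
#'   `density`, `target_freq`, `response_time_s` (NA, to be filled by the
#'   response process).
#' @export
build_session <- function(subject = "S1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dens <- .density_table()$density
  trials <- tibble::tibble(
    target_present = rep(c(TRUE, FALSE), c(160, 80)),
    density = c(rep(dens, each = 40), rep(dens, each = 20))
  )
  trials <- trials[sample.int(nrow(trials)), ]
  trials$subject <- subject
  trials$block <- rep(1:4, each = 60)
  trials$trial <- seq_len(240)
  trials$target_freq <- ifelse(trials$target_present,
                               sample(target_frequency_set(), 240, replace = TRUE),
                               NA_real_)
  trials$response_time_s <- NA_real_
  trials[, c("subject", "block", "trial", "target_present", "density",
             "target_freq", "response_time_s")]
}

#' Categorise trials into hits, misses, false alarms and correct rejections
#'
#' Detecting the regular target stream requires hearing at least two target
#' tones, so responses faster than the guess cutoff (1600 ms by default) are
#' dismissed from the valid responses. Under the default policy a dismissed
#' guess on a target-present trial is recoded as a miss; `"exclude"` drops
#' the trial from scoring instead. Responses on target-absent trials are
#' false alarms regardless of latency.
#'
#' @param trials tibble with `target_present` and `response_time_s`.
#' @param guess_cutoff guess cutoff in seconds (default 1.6).
#' @param guess_policy `"miss"` (default) or `"exclude"`.
#' @return the input with an `outcome` factor column (`hit`, `miss`,
#'   `false_alarm`, `correct_rejection`, or NA for excluded guesses).
#' @export
categorize_trials <- function(trials, guess_cutoff = 1.6,
                              guess_policy = c("miss", "exclude")) {
  guess_policy <- match.arg(guess_policy)
  rt <- trials$response_time_s
  present <- trials$target_present
  out <- ifelse(present,
                ifelse(!is.na(rt) & rt >= guess_cutoff, "hit", "miss"),
                ifelse(!is.na(rt), "false_alarm", "correct_rejection"))
  if (guess_policy == "exclude")
    out[present & !is.na(rt) & rt < guess_cutoff] <- NA
  trials$outcome <- factor(out, levels = c("hit", "miss", "false_alarm",
                                           "correct_rejection"))
  trials
}

#' Outcome counts and rates
#'
#' @param outcome factor of trial outcomes (see [categorize_trials()]).
#' @return list with counts (`hits`, `misses`, `false_alarms`,
#'   `correct_rejections`) and raw rates `HR`, `FAR`.
#' @export
outcome_counts <- function(outcome) {
  outcome <- outcome[!is.na(outcome)]
  n <- table(factor(outcome, levels = c("hit", "miss", "false_alarm",
                                        "correct_rejection")))
  list(hits = unname(n["hit"]), misses = unname(n["miss"]),
       false_alarms = unname(n["false_alarm"]),
       correct_rejections = unname(n["correct_rejection"]),
       HR = unname(n["hit"] / max(n["hit"] + n["miss"], 1L)),
       FAR = unname(n["false_alarm"] / max(n["false_alarm"] + n["correct_rejection"], 1L)))
}

#' Detection performance index d-prime
#'
#' `d' = z(HR) - z(FAR)` with `z` the inverse standard-normal CDF (percent
#' point function). Extreme rates of exactly 0 or 1 give infinite z-scores;
#' these are flagged with a warning (use a count-based correction upstream,
#' see [dprime_from_counts()]).
#'
#' @param hr hit rate in `[0, 1]`.
#' @param far false-alarm rate in `[0, 1]`.
#' @return d-prime value.
#' @examples
#' dprime(0.71, 0.11)  # about 1.78
#' @export
dprime <- function(hr, far) {
  if (any(hr < 0 | hr > 1 | far < 0 | far > 1)) stop("rates must lie in [0, 1]")
  if (any(hr %in% c(0, 1)) || any(far %in% c(0, 1)))
    warning("extreme rate (0 or 1) gives an infinite z-score; apply a correction")
  qnorm(hr) - qnorm(far)
}

#' d-prime from outcome counts with extreme-rate correction
#'
#' The default log-linear rule adds 0.5 to each cell count and 1 to each
#' denominator before the z-transform, which keeps d-prime finite for
#' perfect or empty cells.
#'
#' @param hits,misses,false_alarms,correct_rejections outcome counts.
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return d-prime value.
#' @export
dprime_from_counts <- function(hits, misses, false_alarms, correct_rejections,
                               correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  if (correction == "loglinear") {
    hr <- (hits + 0.5) / (hits + misses + 1)
    far <- (false_alarms + 0.5) / (false_alarms + correct_rejections + 1)
  } else {
    hr <- hits / (hits + misses)
    far <- false_alarms / (false_alarms + correct_rejections)
  }
  dprime(hr, far)
}

#' d-prime per subject and masker density
#'
#' False alarms are attributed to the density of the trial on which they
#' occurred (every trial carries a masker). Densities with no target-present
#' trials yield NA with a warning.
#'
#' @param trials categorised trials (see [categorize_trials()]); must contain
#'   `subject`, `density` and `outcome`.
#' @param correction passed to [dprime_from_counts()].
#' @return tibble with one row per (subject, density) and column `dprime`.
#' @export
dprime_by_density <- function(trials, correction = "loglinear") {
  out <- trials |>
    dplyr::filter(!is.na(.data$outcome)) |>
    dplyr::group_by(.data$subject, .data$density) |>
    dplyr::summarise(
      hits = sum(.data$outcome == "hit"),
      misses = sum(.data$outcome == "miss"),
      false_alarms = sum(.data$outcome == "false_alarm"),
      correct_rejections = sum(.data$outcome == "correct_rejection"),
      .groups = "drop")
  bad <- out$hits + out$misses == 0
  if (any(bad)) warning("density level(s) with no target-present trials: d-prime set to NA")
  out$dprime <- NA_real_
  out$dprime[!bad] <- mapply(dprime_from_counts,
                             out$hits[!bad], out$misses[!bad],
                             out$false_alarms[!bad], out$correct_rejections[!bad],
                             MoreArgs = list(correction = correction))
  out
}

#' Group summary of d-prime per density
#'
#' @param dp output of [dprime_by_density()].
#' @return tibble with mean, SD and n per density.
#' @export
dprime_summary <- function(dp) {
  dp |>
    dplyr::group_by(.data$density) |>
    dplyr::summarise(mean_dprime = mean(.data$dprime, na.rm = TRUE),
                     sd_dprime = sd(.data$dprime, na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop")
}

#' Simulate a response process for a session
#'
#' Utility generator for testing the scoring chain: hits occur with a
#' density-specific probability, misses otherwise; false alarms occur on
#' target-absent trials with probability `far`. Response times are normal
#' around `rt_mean`, truncated above the guess cutoff.
#'
#' @param session a [build_session()] table.
#' @param hr_by_density named vector of hit probabilities per density label.
#' @param far false-alarm probability.
#' @param rt_mean,rt_sd response-time distribution (s).
#' @param guess_cutoff lower truncation for generated response times.
#' @param seed optional integer seed.
#' @return the session with `response_time_s` filled in.
#' @export
simulate_responses <- function(session, hr_by_density = c(`11` = 0.8, `20` = 0.65,
                                                          `28` = 0.65, `36` = 0.75),
                               far = 0.1, rt_mean = 3.4, rt_sd = 0.8,
                               guess_cutoff = 1.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(session)
  draw_rt <- function(k) pmin(pmax(rnorm(k, rt_mean, rt_sd), guess_cutoff + 0.05), 9.9)
  rt <- rep(NA_real_, n)
  pres <- session$target_present
  p_hit <- hr_by_density[as.character(session$density)]
  hit <- pres & runif(n) < p_hit
  rt[hit] <- draw_rt(sum(hit))
  fa <- !pres & runif(n) < far
  rt[fa] <- draw_rt(sum(fa))
  session$response_time_s <- rt
  session
}
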