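# Summary statistics over trajectories: Monte-Carlo catch rates, the
# displacement-correlation statistic behind the correlation-control
# argument, proximity profiles, and analytic chance levels.

#' Monte-Carlo catch-rate estimate
#'
#' Runs `n_trials` independent trials of a wolf chasing the circling sheep
#' (full 30 s cap, the standard initialization rules, a fresh seed per
#' trial) and reports the proportion of trials in which the sheep was
#' caught, with a Wilson 95% confidence interval. Distractors are
#' dynamically irrelevant to catching and are omitted by default for
#' speed; pass `n_distractors > 0` to restore full displays.
#'
#' @param algorithm Pursuit algorithm, `"direct"`, `"mimic"` or
#'   `"intercept"`.
#' @param n_trials Number of simulated trials.
#' @param seed Seed for the whole run; per-trial seeds derive from it.
#' @param experiment Preset the trials are drawn from.
#' @param n_distractors Distractor count (0 = wolf and sheep only).
#' @param max_duration Trial cap in seconds.
#' @return A list of class `"catch_rate_estimate"` with `algorithm`,
#'   `rate` (proportion), `n_trials`, `n_caught` and `ci95`.
#' @examples
#' \donttest{
#' estimate_catch_rate("direct", n_trials = 50, seed = 1)
#' }
#' @export
estimate_catch_rate <- function(algorithm = c("direct", "mimic", "intercept"),
                                n_trials, seed = 1, experiment = "exp2",
                                n_distractors = 0, max_duration = 30) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_trials >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_trials)
  caught <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    cfg <- trial_config(experiment = experiment, algorithm = algorithm,
                        n_distractors = n_distractors, seed = seeds[i],
                        max_duration = max_duration)
    rec <- simulate_trial(cfg, record_frames = FALSE)
    caught[i] <- !is.na(rec$catch_time)
  }
  x <- sum(caught)
  ci <- if (max_duration <= 0 || n_trials < 1) {
    c(0, 1)
  } else {
    # Wilson score interval; prop.test warns about its chi-square view of
    # tiny samples, but the interval itself is what we want
    as.numeric(suppressWarnings(
      stats::prop.test(x, n_trials, correct = FALSE)$conf.int))
  }
  structure(
    list(algorithm = algorithm, rate = x / n_trials, n_trials = n_trials,
         n_caught = x, ci95 = ci),
    class = "catch_rate_estimate"
  )
}

#' @export
print.catch_rate_estimate <- function(x, ...) {
  cat(sprintf("<catch rate %s: %.2f%% of %d trials (95%% CI %.2f-%.2f%%)>\n",
              x$algorithm, 100 * x$rate, x$n_trials,
              100 * x$ci95[1], 100 * x$ci95[2]))
  invisible(x)
}

#' Catch-rate summary table across algorithms
#'
#' Convenience wrapper running [estimate_catch_rate()] per algorithm and
#' returning a tidy summary table.
#'
#' @param algorithms Character vector of pursuit algorithms.
#' @param n_trials Trials per algorithm.
#' @param seed Base seed; algorithm runs use `seed`, `seed + 1`, ...
#' @param ... Passed on to [estimate_catch_rate()].
#' @return A data frame with columns `algorithm`, `n`, `rate`, `ci_lo`,
#'   `ci_hi`.
#' @export
catch_rate_table <- function(algorithms = c("direct", "mimic", "intercept"),
                             n_trials = 2000, seed = 1, ...) {
  rows <- lapply(seq_along(algorithms), function(i) {
    est <- estimate_catch_rate(algorithms[i], n_trials = n_trials,
                               seed = seed + i - 1L, ...)
    data.frame(algorithm = est$algorithm, n = est$n_trials, rate = est$rate,
               ci_lo = est$ci95[1], ci_hi = est$ci95[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Displacement correlation between two trajectories
#'
#' Pearson correlation of the frame-to-frame displacement components of
#' two equally long trajectories, computed per axis and averaged. Using
#' displacements rather than positions avoids the spurious correlation
#' that shared arena bounds induce on raw coordinates. An axis with zero
#' displacement variance in either trajectory contributes 0. A trajectory
#' and its point-mirror have correlation -1 (mirroring negates every
#' displacement).
#'
#' @param traj_a,traj_b Numeric `n x 2` matrices of positions (n >= 3).
#' @return A correlation in `[-1, 1]`.
#' @export
displacement_correlation <- function(traj_a, traj_b) {
  traj_a <- as.matrix(traj_a)
  traj_b <- as.matrix(traj_b)
  if (nrow(traj_a) != nrow(traj_b)) {
    stop("trajectories must have the same number of frames", call. = FALSE)
  }
  if (nrow(traj_a) < 3L) {
    stop("need at least 3 frames (2 displacements)", call. = FALSE)
  }
  da <- diff(traj_a)
  db <- diff(traj_b)
  per_axis <- vapply(1:2, function(a) {
    if (stats::sd(da[, a]) == 0 || stats::sd(db[, a]) == 0) return(0)
    stats::cor(da[, a], db[, a])
  }, 0)
  mean(per_axis)
}

#' Wolf-sheep proximity profile of a trial
#'
#' Per-frame distance between two discs of a trial (wolf and sheep by
#' default) plus summary statistics.
#'
#' @param record A `trial_record` with frames.
#' @param role_a,role_b Roles of the two discs.
#' @return A list with `distance` (per-frame series), `mean`, `min`,
#'   `final` and `mean_change` (mean per-frame change; `NA` for
#'   single-frame records).
#' @export
proximity_profile <- function(record, role_a = "wolf", role_b = "sheep") {
  stopifnot(inherits(record, "trial_record"), !is.null(record$x))
  ia <- which(record$roles == role_a)[1L]
  ib <- which(record$roles == role_b)[1L]
  if (is.na(ia) || is.na(ib)) {
    stop(sprintf("record lacks a '%s' or '%s' disc", role_a, role_b),
         call. = FALSE)
  }
  d <- sqrt((record$x[, ia] - record$x[, ib])^2 +
              (record$y[, ia] - record$y[, ib])^2)
  list(distance = d,
       mean = mean(d),
       min = min(d),
       final = d[length(d)],
       mean_change = if (length(d) > 1L) mean(diff(d)) else NA_real_)
}

#' Chance level of candidate-disc guessing
#'
#' Uniform random guessing over `n_candidates` selectable discs succeeds
#' with probability `1 / n_candidates`: 5% with 19 distractors plus the
#' wolf (20 candidates) and 9% with 10 distractors plus the wolf (11
#' candidates).
#'
#' @param n_candidates Number of selectable discs (>= 1).
#' @return A proportion.
#' @examples
#' chance_level(20)  # 0.05
#' chance_level(11)  # 0.0909...
#' @export
chance_level <- function(n_candidates) {
  if (!is.numeric(n_candidates) || any(n_candidates < 1)) {
    stop("`n_candidates` must be >= 1", call. = FALSE)
  }
  1 / n_candidates
}
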