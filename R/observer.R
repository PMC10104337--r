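# Synthetic observers standing in for human participants, and the
# response-level analyses: identification rate versus chance and the
# exact binomial test on correlation-control choices.

.OBSERVER_STRATEGIES <- c("oracle", "uniform_random", "nearest_mean_proximity",
                          "max_abs_correlation", "closing_rate")

#' Synthetic observer strategy
#'
#' @param name One of `"oracle"` (always correct), `"uniform_random"`
#'   (guesses uniformly over the labels), `"nearest_mean_proximity"`
#'   (picks the candidate with the smallest mean distance to the reference
#'   disc), `"max_abs_correlation"` (picks the candidate whose
#'   displacement correlation with the reference has the largest absolute
#'   value), or `"closing_rate"` (picks the candidate that closes distance
#'   to the reference fastest on average).
#' @param lapse_rate Probability that the choice is replaced by a uniform
#'   random draw.
#' @return A list of class `"observer_strategy"`.
#' @export
observer_strategy <- function(name = .OBSERVER_STRATEGIES, lapse_rate = 0) {
  name <- match.arg(name)
  stopifnot(lapse_rate >= 0, lapse_rate <= 1)
  structure(list(name = name, lapse_rate = lapse_rate),
            class = "observer_strategy")
}

# Cue score of every candidate column against the reference column.
.candidate_scores <- function(record, strategy, cand, ref) {
  rx <- record$x[, ref]; ry <- record$y[, ref]
  vapply(cand, function(j) {
    d <- sqrt((record$x[, j] - rx)^2 + (record$y[, j] - ry)^2)
    switch(strategy,
      nearest_mean_proximity = -mean(d),
      closing_rate = -mean(diff(d)),
      max_abs_correlation = abs(displacement_correlation(
        cbind(record$x[, j], record$y[, j]), cbind(rx, ry)))
    )
  }, 0)
}

#' Simulate one observer response to a labelled trial
#'
#' Cue-based strategies score every labelled candidate disc against the
#' reference disc (the sheep in the wolf-identification task, the wolf in
#' the sheep task) and pick the argmax, ties broken uniformly. When the
#' reference disc is invisible (the hidden-sheep preset) the cue is
#' unavailable and every cue-based strategy degrades to a uniform guess.
#' With probability `lapse_rate` the choice is replaced by a uniform draw.
#' Uses the current RNG state.
#'
#' @param record A labelled `trial_record` (see [assign_labels()]).
#' @param strategy An [observer_strategy()] (or a strategy name).
#' @return A one-row data frame: `trial_id`, `chosen_label`,
#'   `correct_label`, `control_label`, `n_candidates`, `algorithm`,
#'   `n_distractors`, `experiment`, `task`.
#' @export
simulate_observer <- function(record, strategy = observer_strategy("oracle")) {
  if (is.character(strategy)) strategy <- observer_strategy(strategy)
  stopifnot(inherits(record, "trial_record"))
  if (all(is.na(record$labels))) {
    stop("record is unlabelled; run assign_labels() first", call. = FALSE)
  }
  cand <- which(!is.na(record$labels))
  labels <- record$labels[cand]
  ref_role <- if (record$config$task == "sheep_id") "wolf" else "sheep"
  ref <- which(record$roles == ref_role)[1L]
  ref_visible <- ref_role != "sheep" || record$config$sheep_visible

  chosen <- switch(strategy$name,
    oracle = record$answer_label,
    uniform_random = labels[sample.int(length(labels), 1L)],
    {
      if (!ref_visible || is.null(record$x)) {
        labels[sample.int(length(labels), 1L)]
      } else {
        sc <- .candidate_scores(record, strategy$name, cand, ref)
        best <- which(sc >= max(sc) - 1e-12)
        labels[best[sample.int(length(best), 1L)]]
      }
    }
  )
  if (strategy$lapse_rate > 0 && stats::runif(1) < strategy$lapse_rate) {
    chosen <- labels[sample.int(length(labels), 1L)]
  }
  data.frame(trial_id = record$trial_id,
             chosen_label = chosen,
             correct_label = record$answer_label,
             control_label = if (is.null(record$control_label)) NA_integer_ else record$control_label,
             n_candidates = length(labels),
             algorithm = record$config$algorithm,
             n_distractors = record$config$n_distractors,
             experiment = record$config$experiment,
             task = record$config$task,
             stringsAsFactors = FALSE)
}

#' Simulate a response table for a trial set
#'
#' Runs `n_observers` independent synthetic observers over every trial of
#' a set.
#'
#' @param trial_set A [build_trial_set()] result (or a list of labelled
#'   records).
#' @param strategy An [observer_strategy()] or strategy name.
#' @param n_observers Number of observers.
#' @param seed Seed for the whole response simulation.
#' @return A data frame with one row per observer x trial (columns of
#'   [simulate_observer()] plus `observer_id` and `correct`).
#' @export
simulate_responses <- function(trial_set, strategy, n_observers = 1, seed = 1) {
  if (is.character(strategy)) strategy <- observer_strategy(strategy)
  trials <- if (inherits(trial_set, "trial_set")) trial_set$trials else trial_set
  stopifnot(length(trials) >= 1, n_observers >= 1)
  set.seed(seed)
  rows <- vector("list", n_observers * length(trials))
  k <- 0L
  for (obs in seq_len(n_observers)) {
    for (tr in trials) {
      k <- k + 1L
      row <- simulate_observer(tr, strategy)
      row$observer_id <- obs
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$correct <- out$chosen_label == out$correct_label
  out
}

#' Identification rate per observer and condition
#'
#' @param responses A response data frame (see [simulate_responses()] or
#'   [read_responses()]).
#' @param by Condition columns to split on.
#' @return A list with `by_observer` (rate per observer x condition) and
#'   `summary` (mean, SD and n of the per-observer rates per condition).
#' @export
identification_rate <- function(responses,
                                by = c("algorithm", "n_distractors")) {
  stopifnot(nrow(responses) >= 1)
  # [[ for exact matching: $correct would partial-match correct_label
  if (is.null(responses[["correct"]])) {
    responses$correct <- responses$chosen_label == responses$correct_label
  }
  by <- intersect(by, names(responses))
  fac <- c(list(observer_id = responses$observer_id), responses[by])
  by_obs <- stats::aggregate(responses[["correct"]], by = fac,
                             FUN = function(z) mean(z))
  names(by_obs)[ncol(by_obs)] <- "rate"
  smry <- stats::aggregate(by_obs$rate, by = by_obs[, by, drop = FALSE],
                           FUN = function(z) c(mean = mean(z), sd = stats::sd(z), n = length(z)))
  smry <- cbind(smry[, by, drop = FALSE], as.data.frame(smry$x))
  list(by_observer = by_obs, summary = smry)
}

#' One-sample test of identification rates against chance
#'
#' One-sample t-test of per-observer identification rates against the
#' analytic chance level, with Cohen's d effect size
#' `(mean - chance) / SD`. Zero variance across observers is reported as
#' a degenerate result rather than an error.
#'
#' @param observer_rates Numeric vector of per-observer rates (>= 2).
#' @param chance Chance-level proportion (see [chance_level()]).
#' @return A list with `t`, `df`, `p`, `d`, `mean`, `sd` and `degenerate`.
#' @export
test_vs_chance <- function(observer_rates, chance) {
  stopifnot(length(observer_rates) >= 2, chance >= 0, chance <= 1)
  n <- length(observer_rates)
  m <- mean(observer_rates)
  s <- stats::sd(observer_rates)
  if (s == 0) {
    return(list(t = if (m == chance) 0 else sign(m - chance) * Inf,
                df = n - 1L, p = NA_real_, d = NA_real_,
                mean = m, sd = s, degenerate = TRUE))
  }
  tval <- (m - chance) / (s / sqrt(n))
  list(t = tval, df = n - 1L,
       p = 2 * stats::pt(-abs(tval), df = n - 1L),
       d = (m - chance) / s,
       mean = m, sd = s, degenerate = FALSE)
}

#' Choice analysis of the correlation-control distractor
#'
#' Restricts the responses to error trials (the true wolf was not chosen)
#' and asks how often the correlation-control wolf was picked instead. If
#' observers used raw motion correlation as the cue they should pick it
#' disproportionately often; under the uniform null an error lands on the
#' control disc with probability `1 / (n_candidates - 1)`. Tested with a
#' two-sided exact binomial test, either pooled (null probability averaged
#' over the error trials' candidate counts) or stratified by candidate
#' count.
#'
#' @param responses A response data frame containing `control_label` and
#'   `n_candidates`.
#' @param stratify `"pooled"` or `"by_condition"`.
#' @return For `"pooled"`: a list with `control_choice_rate`, `n_errors`,
#'   `n_control_choices`, `null_prob` and `p_value`. For
#'   `"by_condition"`: a list of such lists keyed by candidate count.
#' @export
control_choice_analysis <- function(responses,
                                    stratify = c("pooled", "by_condition")) {
  stratify <- match.arg(stratify)
  if (is.null(responses[["correct"]])) {
    responses$correct <- responses$chosen_label == responses$correct_label
  }
  err <- responses[!responses[["correct"]] & !is.na(responses$control_label), ,
                   drop = FALSE]
  if (nrow(err) == 0L) {
    return(list(control_choice_rate = NA_real_, n_errors = 0L,
                n_control_choices = 0L, null_prob = NA_real_,
                p_value = NA_real_))
  }
  one <- function(e) {
    x <- sum(e$chosen_label == e$control_label)
    p0 <- mean(1 / (e$n_candidates - 1))
    list(control_choice_rate = x / nrow(e), n_errors = nrow(e),
         n_control_choices = x, null_prob = p0,
         p_value = stats::binom.test(x, nrow(e), p0,
                                     alternative = "two.sided")$p.value)
  }
  if (stratify == "pooled") one(err)
  else lapply(split(err, err$n_candidates), one)
}
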