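test_that("the oracle observer is always correct, end to end", {
  ts <- direct_trial_set()
  resp <- simulate_responses(ts$trials[1:10], "oracle", n_observers = 3, seed = 1)
  expect_true(all(resp$correct))
  ir <- identification_rate(resp)
  expect_true(all(ir$summary$mean == 1))
  expect_true(all(ir$by_observer$rate == 1))
})

test_that("uniform guessing sits at the analytic chance level", {
  ts <- direct_trial_set()
  tr19 <- Filter(function(t) t$config$n_distractors == 19, ts$trials)[1:5]
  resp <- simulate_responses(tr19, "uniform_random", n_observers = 500, seed = 2)
  n <- nrow(resp)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(resp$correct) - 0.05), 3 * se)
})

test_that("an unlabelled record cannot be observed", {
  rec <- simulate_trial(trial_config("exp2", "direct", n_distractors = 10,
                                     seed = 3, max_duration = 1))
  expect_error(simulate_observer(rec, "oracle"), "unlabelled")
})

test_that("the proximity observer identifies the direct-chasing wolf above chance", {
  ts <- direct_trial_set()
  tr19 <- Filter(function(t) t$config$n_distractors == 19, ts$trials)[1:40]
  resp <- simulate_responses(tr19, "nearest_mean_proximity", seed = 4)
  expect_gt(mean(resp$correct), chance_level(20) + 0.2)
})

test_that("lapses push a perfect observer toward chance", {
  ts <- direct_trial_set()
  tr <- ts$trials[1:10]
  full_lapse <- observer_strategy("oracle", lapse_rate = 1)
  resp <- simulate_responses(tr, full_lapse, n_observers = 100, seed = 5)
  n <- nrow(resp)
  p0 <- mean(1 / resp$n_candidates)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(resp$correct) - p0), 4 * se)
})

test_that("rate tables aggregate correct choices per observer and condition", {
  resp <- data.frame(
    trial_id = rep(sprintf("t%d", 1:10), 2),
    observer_id = rep(1:2, each = 10),
    chosen_label = c(rep(1, 10), rep(1, 10)),
    correct_label = c(rep(1, 3), rep(2, 7), rep(1, 5), rep(2, 5)),
    algorithm = "direct", n_distractors = 19)
  ir <- identification_rate(resp)
  expect_equal(sort(ir$by_observer$rate), c(0.3, 0.5))
  expect_equal(ir$summary$mean, 0.4)
  expect_equal(ir$summary$n, 2)
})

test_that("the one-sample chance test matches its closed form", {
  out <- test_vs_chance(c(0.2, 0.3, 0.4), 0.05)
  expect_equal(out$t, (0.3 - 0.05) / (0.1 / sqrt(3)))
  expect_equal(out$t, 4.330127, tolerance = 1e-6)
  expect_equal(out$df, 2)
  expect_equal(out$d, 2.5)
  expect_false(out$degenerate)
  # agreement with the standard implementation
  tt <- stats::t.test(c(0.2, 0.3, 0.4), mu = 0.05)
  expect_equal(out$t, unname(tt$statistic))
  expect_equal(out$p, tt$p.value)
  # degenerate inputs signal, not crash
  flat <- test_vs_chance(c(0.3, 0.3, 0.3), 0.3)
  expect_true(flat$degenerate)
  expect_equal(flat$t, 0)
  below <- test_vs_chance(c(0.01, 0.03, 0.02), 0.05)
  expect_lt(below$d, 0)
})

test_that("control-choice analysis handles the extreme cases exactly", {
  base <- data.frame(observer_id = 1, n_candidates = 20, control_label = 20)
  # errors never on the control disc
  never <- cbind(base[rep(1, 50), ], chosen_label = 2, correct_label = 1)
  out <- control_choice_analysis(never)
  expect_equal(out$control_choice_rate, 0)
  expect_equal(out$n_errors, 50)
  expect_equal(out$null_prob, 1 / 19)
  # every error on the control disc
  always <- cbind(base[rep(1, 25), ], chosen_label = 20, correct_label = 1)
  out2 <- control_choice_analysis(always)
  expect_equal(out2$control_choice_rate, 1)
  expect_lt(out2$p_value, 1e-6)
  # no error trials: undefined rate, not an error
  perfect <- cbind(base[rep(1, 5), ], chosen_label = 1, correct_label = 1)
  expect_true(is.na(control_choice_analysis(perfect)$control_choice_rate))
})

test_that("uniform errors choose the control at its null rate", {
  ts <- direct_trial_set()
  tr19 <- Filter(function(t) t$config$n_distractors == 19, ts$trials)[1:10]
  resp <- simulate_responses(tr19, "uniform_random", n_observers = 300, seed = 6)
  out <- control_choice_analysis(resp)
  se <- sqrt(out$null_prob * (1 - out$null_prob) / out$n_errors)
  expect_lt(abs(out$control_choice_rate - out$null_prob), 4 * se)
  expect_gt(out$p_value, 0.001)
  # stratified analysis returns one stratum per candidate count
  both <- simulate_responses(ts$trials[1:12], "uniform_random",
                             n_observers = 50, seed = 7)
  strat <- control_choice_analysis(both, stratify = "by_condition")
  expect_setequal(names(strat), c("11", "20"))
})
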