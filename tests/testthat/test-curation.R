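test_that("short trials are rejected by the first experiment's rule", {
  expect_null(curate_exp1(fake_record(duration = 4)))
  expect_null(curate_exp1(fake_record(duration = 6)))
})

test_that("kept trials are cut to 5-15 s, at least 1 s shorter than the source", {
  set.seed(202)
  for (i in 1:15) {
    rec <- fake_record(duration = 30, seed = 300 + i)
    cur <- curate_exp1(rec, seed = i)
    if (is.null(cur)) next
    expect_gte(cur$duration, 5)
    expect_lte(cur$duration, 15)
    expect_lte(cur$duration, rec$duration - 1)
    # the wolf is not the nearest non-sheep disc at the final frame
    f <- cur$n_frames
    other <- which(cur$roles != "sheep")
    sheep <- which(cur$roles == "sheep")
    d <- sqrt((cur$x[f, other] - cur$x[f, sheep])^2 +
                (cur$y[f, other] - cur$y[f, sheep])^2)
    expect_false(cur$roles[other[which.min(d)]] == "wolf")
  }
  # a barely-long-enough source still truncates by at least one second
  cur <- curate_exp1(fake_record(duration = 6.5, seed = 400), seed = 2)
  if (!is.null(cur)) expect_lte(cur$duration, 5.5)
})

test_that("algorithm-experiment trials need 11 catch-free seconds, movies are 10 s", {
  expect_null(curate_exp2(fake_record(duration = 8, catch_time = 8)))
  expect_null(curate_exp2(fake_record(duration = 10.9, catch_time = 10.9)))
  cur <- curate_exp2(fake_record(duration = 20, catch_time = 20))
  expect_equal(cur$duration, 10)
  expect_equal(cur$n_frames, 601)
  expect_true(is.na(cur$catch_time))      # catch-free in the visible span
  cur2 <- curate_exp2(fake_record(duration = 30, catch_time = NA))
  expect_equal(cur2$duration, 10)
})

test_that("labels are a uniform permutation over the candidate discs", {
  rec <- fake_record(duration = 12)   # 21 discs: sheep + wolf + control + 18
  lab <- assign_labels(rec, seed = 1)
  expect_equal(sort(lab$labels[!is.na(lab$labels)]), 1:20)
  expect_true(is.na(lab$labels[which(rec$roles == "sheep")]))
  expect_equal(lab$answer_label, lab$labels[which(rec$roles == "wolf")])
  expect_equal(lab$control_label, lab$labels[which(rec$roles == "control_wolf")])
  # same seed, same permutation
  expect_identical(assign_labels(rec, seed = 7)$labels,
                   assign_labels(rec, seed = 7)$labels)
  # explicit range check
  expect_error(assign_labels(rec, seed = 1, expected_candidates = 11),
               "expected 11")
})

test_that("the wolf's label is uniform over its range", {
  rec <- fake_record(duration = 12)
  wolf_lab <- vapply(1:4000, function(s) assign_labels(rec, seed = s)$answer_label, 0L)
  p <- stats::chisq.test(tabulate(wolf_lab, 20))$p.value
  expect_gt(p, 0.001)
})

test_that("the sheep-task labelling keys on the sheep among white discs", {
  rec <- fake_record(duration = 12, experiment = "exp3_sheep_task")
  lab <- assign_labels(rec, seed = 3)
  expect_true(is.na(lab$labels[which(rec$roles == "wolf")]))
  expect_equal(sort(lab$labels[!is.na(lab$labels)]), 1:20)
  expect_equal(lab$answer_label, lab$labels[which(rec$roles == "sheep")])
})

test_that("trial sets are balanced into blocks and reproducible from the manifest", {
  ts <- build_trial_set(experiment = "exp2", algorithms = "direct",
                        n_distractors = c(19, 10), per_cell = 3,
                        block_size = 2, seed = 99)
  expect_length(ts$trials, 6)
  expect_equal(nrow(ts$manifest), 6)
  # every cell is equally represented overall and within each block
  expect_equal(as.vector(table(ts$manifest$n_distractors)), c(3, 3))
  for (b in unique(ts$manifest$block)) {
    blk <- ts$manifest[ts$manifest$block == b, ]
    expect_equal(sort(blk$n_distractors), c(10, 19))
  }
  # all curated trials are 10 s, catch-free, labelled to their range
  for (tr in ts$trials) {
    expect_equal(tr$duration, 10)
    expect_true(is.na(tr$catch_time))
    m <- sum(!is.na(tr$labels))
    expect_equal(sort(tr$labels[!is.na(tr$labels)]), seq_len(m))
  }
  # label ranges give the printed chance levels
  n_cand <- ts$manifest$n_candidates
  expect_true(all(n_cand[ts$manifest$n_distractors == 19] == 20))
  expect_true(all(n_cand[ts$manifest$n_distractors == 10] == 11))
  # manifest seeds regenerate the identical trial
  tr <- ts$trials[[4]]
  re <- regenerate_trial(ts$manifest[4, ])
  expect_identical(re$x, tr$x)
  expect_identical(re$labels, tr$labels)
  expect_identical(re$answer_label, tr$answer_label)
})

test_that("an empty request yields an empty but valid set", {
  ts <- build_trial_set(per_cell = 0, seed = 1)
  expect_length(ts$trials, 0)
  expect_equal(nrow(ts$manifest), 0)
})

test_that("exp1 curation composes with the random-walk preset", {
  ts <- build_trial_set(experiment = "exp1_cpu", n_distractors = 19,
                        per_cell = 2, block_size = 1, seed = 17)
  expect_length(ts$trials, 2)
  for (tr in ts$trials) {
    expect_gte(tr$duration, 5)
    expect_lte(tr$duration, 15)
    expect_lte(tr$duration, tr$source_duration - 1)
    expect_equal(sort(tr$labels[!is.na(tr$labels)]), 1:20)
  }
})
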