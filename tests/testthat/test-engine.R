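test_that("simulation is bit-identical under a fixed seed", {
  cfg <- trial_config("exp2", "intercept", n_distractors = 19, seed = 31)
  a <- simulate_trial(cfg)
  b <- simulate_trial(cfg)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$catch_time, b$catch_time)
})

test_that("the hidden-sheep preset changes visibility, never dynamics", {
  a <- simulate_trial(trial_config("exp2", "mimic", n_distractors = 10, seed = 77))
  b <- simulate_trial(trial_config("exp4", "mimic", n_distractors = 10, seed = 77))
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_true(a$config$sheep_visible)
  expect_false(b$config$sheep_visible)
})

test_that("no disc leaves the arena and per-frame speeds are respected", {
  for (seed in c(5, 6)) {
    cfg <- trial_config("exp2", "direct", n_distractors = 19, seed = seed,
                        max_duration = 10)
    rec <- simulate_trial(cfg)
    expect_true(all(rec$x >= 0 & rec$x <= 32))
    expect_true(all(rec$y >= 0 & rec$y <= 24))
    step <- sqrt(diff(rec$x)^2 + diff(rec$y)^2)
    caps <- ifelse(rec$roles == "sheep", 14.4, 9.6) / 60
    expect_true(all(sweep(step, 2, caps) <= 1e-12))
  }
})

test_that("exp1 preset runs with random-walk distractors", {
  cfg <- trial_config("exp1_cpu", "direct", n_distractors = 19, seed = 12,
                      max_duration = 8)
  rec <- simulate_trial(cfg)
  expect_false(any(rec$roles == "control_wolf"))
  expect_equal(sum(rec$roles == "distractor"), 19)
  expect_true(all(rec$x >= 0 & rec$x <= 32))
  # distractors actually move
  dcols <- which(rec$roles == "distractor")
  expect_true(all(colSums(abs(diff(rec$x[, dcols]))) > 0))
})

test_that("the wolf is initialized at least 11 degrees from the sheep", {
  cfg <- trial_config("exp2", "direct", n_distractors = 0)
  dmin <- Inf
  for (seed in 1:1000) {
    set.seed(seed)
    init <- initialize_trial(cfg)
    dmin <- min(dmin, point_distance(init$wolf_pos, init$sheep_pos))
  }
  expect_gte(dmin, 11)
  set.seed(123); a <- initialize_trial(cfg)
  set.seed(123); b <- initialize_trial(cfg)
  expect_identical(a, b)
})

test_that("distractor initialization is uniform over the arena", {
  cfg <- trial_config("exp2", "direct", n_distractors = 19)
  xs <- ys <- c()
  for (seed in 1:600) {
    set.seed(seed)
    init <- initialize_trial(cfg)
    xs <- c(xs, init$distractors[, 1])
    ys <- c(ys, init$distractors[, 2])
  }
  cells <- table(cut(xs, seq(0, 32, by = 8)), cut(ys, seq(0, 24, by = 8)))
  p <- stats::chisq.test(as.vector(cells))$p.value
  expect_gt(p, 0.001)
})

test_that("the catch boundary is inclusive at the sum of the radii", {
  expect_true(check_catch(c(0, 0), c(0, 0)))
  expect_true(check_catch(c(0, 0), c(1.085, 0)))
  expect_false(check_catch(c(0, 0), c(2, 0)))
  expect_false(check_catch(c(0, 0), c(1.0851, 0)))
})

test_that("the control wolf never terminates a trial", {
  cfg <- trial_config("exp2", "mimic", n_distractors = 1, seed = 55,
                      max_duration = 2)
  set.seed(55)
  init <- initialize_trial(cfg)
  # drop the control right next to the real sheep
  init$control_pos <- init$sheep_pos + c(0.1, 0)
  cfg$seed <- NULL
  rec <- simulate_trial(cfg, init = init)
  d0 <- point_distance(c(rec$x[1, 3], rec$y[1, 3]), c(rec$x[1, 1], rec$y[1, 1]))
  expect_lte(d0, 1.085)       # the control overlaps the sheep at frame 0
  expect_gt(rec$n_frames, 2)  # yet the trial does not stop
})

test_that("mirroring the initial state mirrors the whole trajectory", {
  ar <- arena()
  cfg <- pursuit_config("direct", seed = 9)
  set.seed(9)
  init <- initialize_trial(cfg)
  p <- init$path
  minit <- init
  minit$sheep_arc <- (init$sheep_arc + p$perimeter / 2) %% p$perimeter
  minit$sheep_pos <- mirror_point(init$sheep_pos, ar)
  minit$sheep_dir_idx <- (init$sheep_dir_idx + 4L) %% 8L
  minit$wolf_pos <- mirror_point(init$wolf_pos, ar)
  cfg$seed <- NULL
  a <- simulate_trial(cfg, init = init)
  b <- simulate_trial(cfg, init = minit)
  expect_equal(b$x, 32 - a$x, tolerance = 1e-9)
  expect_equal(b$y, 24 - a$y, tolerance = 1e-9)
  expect_identical(a$catch_time, b$catch_time)
})

test_that("a control wolf started at the wolf's mirror traces its mirror image", {
  ar <- arena()
  for (seed in c(14, 15)) {
    cfg <- trial_config("exp2", "direct", n_distractors = 1, seed = seed,
                        max_duration = 15)
    set.seed(seed)
    init <- initialize_trial(cfg)
    init$control_pos <- mirror_point(init$wolf_pos, ar)
    cfg$seed <- NULL
    rec <- simulate_trial(cfg, init = init)
    wolf_col <- which(rec$roles == "wolf")
    ctrl_col <- which(rec$roles == "control_wolf")
    expect_equal(rec$x[, ctrl_col], 32 - rec$x[, wolf_col], tolerance = 1e-9)
    expect_equal(rec$y[, ctrl_col], 24 - rec$y[, wolf_col], tolerance = 1e-9)
  }
})

test_that("the far-phase mimic preserves distance up to the speed gap", {
  margin <- 0.45
  interior <- function(x, y) {
    x > margin & x < 32 - margin & y > margin & y < 24 - margin
  }
  total_free <- 0L
  for (seed in 21:26) {
    cfg <- pursuit_config("mimic", seed = seed, max_duration = 6)
  rec <- simulate_trial(cfg)
  d <- proximity_profile(rec)$distance
  # steps where the wolf is away from walls (the sheep hugs its perimeter
  # loop by construction, so only the wolf can be clamped), the sheep took
  # a full cardinal step (not a corner chord), and the sheep's step repeats
  # the previous one (the wolf copies the sheep's *previous* direction)
  sx <- diff(rec$x[, 1]); sy <- diff(rec$y[, 1])
  n <- nrow(rec$x)
  k <- 2:(n - 1)
  free <- k[
    interior(rec$x[k + 1, 2], rec$y[k + 1, 2]) &
      interior(rec$x[k, 2], rec$y[k, 2]) &
      abs(sqrt(sx[k]^2 + sy[k]^2) - 0.24) < 1e-9 &
      abs(sx[k] - sx[k - 1]) < 1e-10 & abs(sy[k] - sy[k - 1]) < 1e-10 &
      d[k] >= 6]
  gap <- (14.4 - 9.6) / 60
  expect_true(all(abs(d[free + 1] - d[free]) <= gap + 1e-9))
  total_free <- total_free + length(free)
  }
  expect_gt(total_free, 50)
})
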