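# Shared test utilities: independent oracles and memoized fixtures.

# Brute-force oracle for direction quantization: argmin of absolute
# angular distance over the 8 compass candidates, ties to smaller index.
brute_quantize <- function(angle) {
  cand <- (0:7) * pi / 4
  d <- abs(((angle - cand + pi) %% (2 * pi)) - pi)
  k <- which(d == min(d))[1] - 1
  s <- sqrt(0.5)
  rbind(c(1, 0), c(s, s), c(0, 1), c(-s, s),
        c(-1, 0), c(-s, -s), c(0, -1), c(s, -s))[k + 1, ]
}

# Distractor-free trial config used throughout.
pursuit_config <- function(algorithm, seed, ...) {
  trial_config("exp2", algorithm, n_distractors = 0, seed = seed, ...)
}

# Hand-built trial record for curation / IO edge cases.
fake_record <- function(duration = 30, n_distractors = 19, catch_time = NA,
                        experiment = "exp2", seed = 99) {
  cfg <- trial_config(experiment, "direct", n_distractors = n_distractors,
                      seed = seed)
  set.seed(seed)
  dt <- cfg$dt
  n <- as.integer(round(duration / dt)) + 1L
  roles <- c("sheep", "wolf", if (cfg$include_control) "control_wolf",
             rep("distractor", n_distractors - as.integer(cfg$include_control)))
  nd <- length(roles)
  x <- matrix(stats::runif(n * nd, 0, cfg$arena$width), n, nd)
  y <- matrix(stats::runif(n * nd, 0, cfg$arena$height), n, nd)
  structure(
    list(config = cfg, trial_id = "fake", x = x, y = y, roles = roles,
         labels = rep(NA_integer_, nd), answer_label = NA_integer_,
         orientation = "ccw", catch_time = catch_time, duration = duration,
         n_frames = n),
    class = "trial_record"
  )
}

# Memoized fixtures shared across test files (built once per run).
.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Curated, labelled direct-chase trial sets (both distractor densities).
direct_trial_set <- function() {
  memo_fixture("direct_set", build_trial_set(
    experiment = "exp2", algorithms = "direct", n_distractors = c(19, 10),
    per_cell = 100, block_size = 2, seed = 424242))
}

# Hidden-sheep preset trials for the at-chance analyses.
exp4_trial_set <- function() {
  memo_fixture("exp4_set", build_trial_set(
    experiment = "exp4", algorithms = "direct", n_distractors = 19,
    per_cell = 8, block_size = 1, seed = 777))
}
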