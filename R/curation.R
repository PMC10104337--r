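# Selection, truncation and labelling rules that turn raw simulations into
# experiment-ready trial sets.

# Keep frames 0..end_frame; a catch beyond the kept span is hidden.
.truncate_record <- function(record, end_frame) {
  dt <- record$config$dt
  record$source_duration <- record$duration
  record$source_catch_time <- record$catch_time
  keep <- seq_len(end_frame + 1L)
  record$x <- record$x[keep, , drop = FALSE]
  record$y <- record$y[keep, , drop = FALSE]
  record$n_frames <- end_frame + 1L
  record$duration <- end_frame * dt
  if (!is.na(record$catch_time) && record$catch_time > record$duration) {
    record$catch_time <- NA_real_
  }
  record
}

#' Curate a trial under the video-selection rules of the first experiment
#'
#' Rejects trials lasting 6 seconds or less; otherwise truncates to a
#' uniform-random length between 5 seconds and `min(15, duration - 1)`
#' seconds (every kept trial is at least one second shorter than its
#' source). The truncation endpoint is re-drawn (up to `max_attempts`
#' times) whenever the wolf would be the non-sheep disc closest to the
#' sheep at the final frame, so that end-of-video proximity cannot give
#' the wolf away; if no admissible endpoint is found the trial is
#' rejected.
#'
#' @param record A full [simulate_trial()] record with frames.
#' @param seed Optional seed for the truncation draw.
#' @param max_attempts Endpoint re-draw budget.
#' @return A truncated `trial_record`, or `NULL` if the trial is rejected.
#' @export
curate_exp1 <- function(record, seed = NULL, max_attempts = 50) {
  stopifnot(inherits(record, "trial_record"), !is.null(record$x))
  if (!is.null(seed)) set.seed(seed)
  if (record$duration <= 6) return(NULL)
  dt <- record$config$dt
  hi <- min(15, record$duration - 1)
  if (hi < 5) return(NULL)
  wolf_col <- which(record$roles == "wolf")
  sheep_col <- which(record$roles == "sheep")
  other <- which(record$roles != "sheep")
  for (a in seq_len(max_attempts)) {
    len <- stats::runif(1, 5, hi)
    end_frame <- as.integer(round(len / dt))
    d <- sqrt((record$x[end_frame + 1L, other] - record$x[end_frame + 1L, sheep_col])^2 +
                (record$y[end_frame + 1L, other] - record$y[end_frame + 1L, sheep_col])^2)
    if (other[which.min(d)] != wolf_col) {
      return(.truncate_record(record, end_frame))
    }
  }
  NULL
}

#' Curate a trial under the selection rule of the algorithm experiments
#'
#' Only trials in which the wolf has not caught the sheep within the first
#' 11 seconds are kept; kept trials are cut down to their first 10
#' seconds, so every displayed movie is exactly 10 s and catch-free.
#'
#' @param record A full [simulate_trial()] record with frames.
#' @return A 10-second `trial_record`, or `NULL` if the trial is rejected.
#' @export
curate_exp2 <- function(record) {
  stopifnot(inherits(record, "trial_record"), !is.null(record$x))
  if (!is.na(record$catch_time) && record$catch_time < 11) return(NULL)
  movie_frames <- as.integer(round(10 / record$config$dt))
  if (record$n_frames - 1L < movie_frames) return(NULL)
  .truncate_record(record, movie_frames)
}

#' Randomly label the candidate discs
#'
#' Assigns a uniform-random permutation of `1..m` to the `m` candidate
#' discs: every disc except the reference (the sheep in the
#' wolf-identification task, the wolf in the sheep-identification task).
#' With 19 distractors this is the 1-20 labelling of the experiments; with
#' 10 distractors the labels run 1-11. The answer key records the wolf's
#' (or, for the sheep task, the sheep's) label.
#'
#' @param record A `trial_record`.
#' @param seed Optional seed for the permutation.
#' @param expected_candidates Optional check on the number of labelled
#'   discs; a mismatch is a configuration error.
#' @return The record with `labels`, `answer_label` and (when a
#'   correlation-control wolf is present) `control_label` filled in.
#' @export
assign_labels <- function(record, seed = NULL, expected_candidates = NULL) {
  stopifnot(inherits(record, "trial_record"))
  if (!is.null(seed)) set.seed(seed)
  ref_role <- if (record$config$task == "sheep_id") "wolf" else "sheep"
  target_role <- if (record$config$task == "sheep_id") "sheep" else "wolf"
  cand <- which(record$roles != ref_role)
  if (!is.null(expected_candidates) && length(cand) != expected_candidates) {
    stop(sprintf("expected %d candidate discs, found %d",
                 expected_candidates, length(cand)), call. = FALSE)
  }
  if (length(cand) < 1L) stop("no candidate discs to label", call. = FALSE)
  labels <- rep(NA_integer_, length(record$roles))
  labels[cand] <- sample.int(length(cand))
  record$labels <- labels
  record$answer_label <- labels[which(record$roles == target_role)[1L]]
  ctrl <- which(record$roles == "control_wolf")
  record$control_label <- if (length(ctrl)) labels[ctrl[1L]] else NA_integer_
  record
}

#' Generate a curated, block-balanced trial set
#'
#' Simulates trials cell by cell (pursuit algorithm x distractor count)
#' until the requested number of curated trials exists in every cell,
#' applying the experiment's curation rule and random labelling to each.
#' Trials are then ordered into blocks containing an equal number of
#' trials from every cell. The manifest records, per trial, the seeds of
#' the simulation, truncation and labelling draws, so the identical set
#' can be regenerated (see [regenerate_trial()]).
#'
#' @param experiment Preset name (see [trial_config()]).
#' @param algorithms Pursuit algorithms to cross.
#' @param n_distractors Distractor counts to cross.
#' @param per_cell Curated trials required per cell (32 in the algorithm
#'   experiments).
#' @param block_size Trials per block; must be a multiple of the number of
#'   cells. `NULL` puts everything in one block.
#' @param seed Seed for the whole generation run.
#' @param max_attempts_per_cell Simulation budget per cell before the
#'   request is declared infeasible.
#' @return A list of class `"trial_set"`: `trials` (list of curated,
#'   labelled records) and `manifest` (one data-frame row per trial).
#' @export
build_trial_set <- function(experiment = "exp2",
                            algorithms = c("direct", "mimic", "intercept"),
                            n_distractors = c(19, 10),
                            per_cell = 32, block_size = NULL, seed = 1,
                            max_attempts_per_cell = 400 * max(per_cell, 1)) {
  stopifnot(per_cell >= 0)
  set.seed(seed)
  if (experiment == "exp1_cpu") algorithms <- "direct"
  cells <- expand.grid(algorithm = algorithms, n_distractors = n_distractors,
                       stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  trials <- list()
  rows <- list()
  for (ci in seq_len(n_cells)) {
    alg <- cells$algorithm[ci]
    nd <- cells$n_distractors[ci]
    got <- 0L
    attempts <- 0L
    while (got < per_cell) {
      attempts <- attempts + 1L
      if (attempts > max_attempts_per_cell) {
        stop(sprintf("cell %s/%d distractors: rejection rate too high (%d attempts)",
                     alg, nd, attempts), call. = FALSE)
      }
      sim_seed <- sample.int(.Machine$integer.max, 1L)
      cur_seed <- sample.int(.Machine$integer.max, 1L)
      lab_seed <- sample.int(.Machine$integer.max, 1L)
      cfg <- trial_config(experiment = experiment, algorithm = alg,
                          n_distractors = nd, seed = sim_seed)
      rec <- simulate_trial(cfg)
      cur <- if (experiment == "exp1_cpu") {
        curate_exp1(rec, seed = cur_seed)
      } else {
        curate_exp2(rec)
      }
      if (is.null(cur)) next
      got <- got + 1L
      cur <- assign_labels(cur, seed = lab_seed)
      cur$trial_id <- sprintf("%s_%s_%02d_%03d", experiment, alg, nd, got)
      trials[[length(trials) + 1L]] <- cur
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = cur$trial_id, experiment = experiment, algorithm = alg,
        n_distractors = nd, sim_seed = sim_seed, curation_seed = cur_seed,
        label_seed = lab_seed, duration = cur$duration,
        source_duration = cur$source_duration,
        source_catch_time = if (is.na(cur$source_catch_time)) NA_real_ else cur$source_catch_time,
        answer_label = cur$answer_label,
        control_label = if (is.na(cur$control_label)) NA_integer_ else cur$control_label,
        n_candidates = sum(!is.na(cur$labels)),
        cell = ci, attempts_before = attempts,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else data.frame()
  # block balancing: interleave cells so each block holds equal cell counts
  if (length(trials)) {
    if (is.null(block_size)) block_size <- n_cells * per_cell
    if (per_cell > 0 && block_size %% n_cells != 0) {
      stop("`block_size` must be a multiple of the number of cells", call. = FALSE)
    }
    per_block <- if (per_cell > 0) block_size %/% n_cells else 0L
    if (per_block > 0 && per_cell %% per_block != 0) {
      stop("`per_cell` must be a multiple of the per-block cell count", call. = FALSE)
    }
    idx_by_cell <- split(seq_along(trials), manifest$cell)
    order_idx <- integer(0)
    block_id <- integer(0)
    if (per_block > 0) {
      n_blocks <- per_cell %/% per_block
      for (b in seq_len(n_blocks)) {
        take <- ((b - 1L) * per_block + 1L):(b * per_block)
        for (ci in seq_len(n_cells)) {
          order_idx <- c(order_idx, idx_by_cell[[ci]][take])
          block_id <- c(block_id, rep(b, per_block))
        }
      }
    }
    trials <- trials[order_idx]
    manifest <- manifest[order_idx, , drop = FALSE]
    manifest$block <- block_id
    rownames(manifest) <- NULL
  }
  structure(list(trials = trials, manifest = manifest,
                 experiment = experiment, seed = seed),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set %s: %d curated trials, %d cells, seed %s>\n",
              x$experiment, length(x$trials),
              if (nrow(x$manifest)) length(unique(x$manifest$cell)) else 0L,
              x$seed))
  invisible(x)
}

#' Regenerate one curated trial from its manifest row
#'
#' Re-runs the simulation, curation and labelling of a trial from the
#' seeds stored in a [build_trial_set()] manifest, reproducing the trial
#' bit for bit.
#'
#' @param manifest_row A single-row data frame from a trial-set manifest.
#' @return The regenerated `trial_record`.
#' @export
regenerate_trial <- function(manifest_row) {
  stopifnot(nrow(manifest_row) == 1L)
  cfg <- trial_config(experiment = manifest_row$experiment,
                      algorithm = manifest_row$algorithm,
                      n_distractors = manifest_row$n_distractors,
                      seed = manifest_row$sim_seed)
  rec <- simulate_trial(cfg)
  cur <- if (manifest_row$experiment == "exp1_cpu") {
    curate_exp1(rec, seed = manifest_row$curation_seed)
  } else {
    curate_exp2(rec)
  }
  if (is.null(cur)) stop("manifest row does not regenerate a curated trial",
                         call. = FALSE)
  cur <- assign_labels(cur, seed = manifest_row$label_seed)
  cur$trial_id <- manifest_row$trial_id
  cur
}
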