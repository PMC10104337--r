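# Persistence: long-format CSV trajectory tables plus JSON manifests,
# blinded exports, playback of recorded trajectories, schema validation.

.SCHEMA_VERSION <- "1.0"

#' Long-format trajectory table of a trial
#'
#' @param record A `trial_record` with frames.
#' @param blinded If `TRUE`, the roles of all non-sheep discs are withheld
#'   and, when the trial's sheep is invisible, the sheep's rows are
#'   omitted - the observer-facing view of the stimulus.
#' @return A data frame with columns `trial_id`, `frame_idx`, `time_s`,
#'   `disc_id`, `x_deg`, `y_deg`.
#' @export
trajectory_table <- function(record, blinded = FALSE) {
  stopifnot(inherits(record, "trial_record"), !is.null(record$x))
  n_f <- record$n_frames
  n_d <- length(record$roles)
  keep <- seq_len(n_d)
  if (blinded && !record$config$sheep_visible) {
    keep <- which(record$roles != "sheep")
  }
  dt <- record$config$dt
  data.frame(
    trial_id = if (is.na(record$trial_id)) "trial" else record$trial_id,
    frame_idx = rep(0:(n_f - 1L), times = length(keep)),
    time_s = rep((0:(n_f - 1L)) * dt, times = length(keep)),
    disc_id = rep(sprintf("d%02d", keep), each = n_f),
    x_deg = as.vector(record$x[, keep]),
    y_deg = as.vector(record$y[, keep]),
    stringsAsFactors = FALSE
  )
}

#' Write a trial to disk
#'
#' Writes `<stem>_trajectory.csv` (long-format positions, full precision)
#' and `<stem>_manifest.json` (schema version, configuration, roles,
#' labels, answer key, catch time). The round trip through
#' [read_trial()] reproduces positions to well below 1e-9 degrees.
#' Blinded exports withhold non-sheep roles and the answer key, and drop
#' hidden-sheep rows; they are for presentation and do not round-trip.
#'
#' @param record A `trial_record` with frames.
#' @param stem Path stem (directory + file prefix) to write to.
#' @param blinded Write the observer-facing view instead of the full
#'   record.
#' @return The path stem, invisibly.
#' @export
write_trial <- function(record, stem, blinded = FALSE) {
  tab <- trajectory_table(record, blinded = blinded)
  csv <- paste0(stem, "_trajectory.csv")
  json <- paste0(stem, "_manifest.json")
  utils::write.csv(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                   csv, row.names = FALSE, quote = FALSE)
  keep <- sort(unique(tab$disc_id))
  idx <- as.integer(sub("^d", "", keep))
  roles <- record$roles[idx]
  if (blinded) roles[roles != "sheep"] <- "candidate"
  cfg <- record$config
  manifest <- list(
    schema_version = .SCHEMA_VERSION,
    trial_id = if (is.na(record$trial_id)) "trial" else record$trial_id,
    blinded = blinded,
    experiment = cfg$experiment,
    algorithm = cfg$algorithm,
    n_distractors = cfg$n_distractors,
    include_control = cfg$include_control,
    task = cfg$task,
    sheep_visible = cfg$sheep_visible,
    speeds = as.list(cfg$speeds),
    dt = cfg$dt,
    max_duration = cfg$max_duration,
    arena = list(width = cfg$arena$width, height = cfg$arena$height),
    seed = cfg$seed,
    orientation = record$orientation,
    duration = record$duration,
    n_frames = record$n_frames,
    catch_time = record$catch_time,
    discs = lapply(seq_along(keep), function(i) {
      list(disc_id = keep[i], role = roles[i],
           label = if (blinded || is.na(record$labels[idx[i]])) NULL
                   else record$labels[idx[i]])
    }),
    answer_label = if (blinded) NULL else record$answer_label,
    control_label = if (blinded || is.null(record$control_label)) NULL
                    else record$control_label
  )
  jsonlite::write_json(manifest, json, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(stem)
}

#' Read a trial written by [write_trial()]
#'
#' @param stem The path stem the trial was written under.
#' @return A reconstructed `trial_record`.
#' @export
read_trial <- function(stem) {
  csv <- paste0(stem, "_trajectory.csv")
  json <- paste0(stem, "_manifest.json")
  if (!file.exists(csv)) stop("missing trajectory file: ", csv, call. = FALSE)
  if (!file.exists(json)) stop("missing manifest file: ", json, call. = FALSE)
  man <- jsonlite::read_json(json, simplifyVector = FALSE)
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  .validate_table(tab, man)
  cfg <- trial_config(
    experiment = man$experiment, algorithm = man$algorithm,
    n_distractors = man$n_distractors,
    include_control = man$include_control,
    seed = if (is.null(man$seed)) NULL else man$seed,
    max_duration = man$max_duration, dt = man$dt,
    arena = arena(man$arena$width, man$arena$height),
    speeds = unlist(man$speeds)
  )
  disc_ids <- vapply(man$discs, `[[`, "", "disc_id")
  n_f <- man$n_frames
  X <- matrix(NA_real_, n_f, length(disc_ids))
  Y <- matrix(NA_real_, n_f, length(disc_ids))
  for (i in seq_along(disc_ids)) {
    rows <- tab[tab$disc_id == disc_ids[i], ]
    rows <- rows[order(rows$frame_idx), ]
    X[, i] <- rows$x_deg
    Y[, i] <- rows$y_deg
  }
  labels <- vapply(man$discs, function(d) {
    if (is.null(d$label)) NA_integer_ else as.integer(d$label)
  }, 0L)
  structure(
    list(config = cfg,
         trial_id = man$trial_id,
         x = X, y = Y,
         roles = vapply(man$discs, `[[`, "", "role"),
         labels = labels,
         answer_label = if (is.null(man$answer_label)) NA_integer_ else as.integer(man$answer_label),
         control_label = if (is.null(man$control_label)) NA_integer_ else as.integer(man$control_label),
         orientation = man$orientation,
         catch_time = if (is.null(man$catch_time)) NA_real_ else man$catch_time,
         duration = man$duration,
         n_frames = n_f),
    class = "trial_record"
  )
}

# Structural checks shared by read_trial() and validate_trial().
.validate_table <- function(tab, man) {
  need <- c("trial_id", "frame_idx", "time_s", "disc_id", "x_deg", "y_deg")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("trajectory table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(tab$x_deg))
  y <- suppressWarnings(as.numeric(tab$y_deg))
  if (anyNA(x) || anyNA(y)) {
    bad <- which(is.na(x) | is.na(y))[1L]
    stop(sprintf("trajectory row %d: non-numeric position", bad), call. = FALSE)
  }
  w <- man$arena$width; h <- man$arena$height
  out <- which(x < 0 | x > w | y < 0 | y > h)
  if (length(out)) {
    stop(sprintf("trajectory row %d: position outside the arena", out[1L]),
         call. = FALSE)
  }
  n_f <- man$n_frames
  for (id in unique(tab$disc_id)) {
    fr <- sort(tab$frame_idx[tab$disc_id == id])
    if (length(fr) != n_f || !identical(as.integer(fr), 0:(n_f - 1L))) {
      stop(sprintf("disc %s: frames are not contiguous 0..%d", id, n_f - 1L),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Validate exported trial files against their schema
#'
#' @param stem Path stem of a written trial.
#' @return `TRUE` invisibly if the files validate; otherwise an error
#'   naming the first offending row or field.
#' @export
validate_trial <- function(stem) {
  csv <- paste0(stem, "_trajectory.csv")
  json <- paste0(stem, "_manifest.json")
  if (!file.exists(csv)) stop("missing trajectory file: ", csv, call. = FALSE)
  if (!file.exists(json)) stop("missing manifest file: ", json, call. = FALSE)
  man <- jsonlite::read_json(json, simplifyVector = FALSE)
  for (field in c("schema_version", "trial_id", "n_frames", "dt", "arena")) {
    if (is.null(man[[field]])) {
      stop("manifest lacks field: ", field, call. = FALSE)
    }
  }
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  .validate_table(tab, man)
  invisible(TRUE)
}

#' Playback policy from a recorded trajectory
#'
#' Wraps one disc's recorded positions so it can drive an agent anywhere a
#' live policy can - in particular, a recorded (e.g. human-controlled)
#' sheep can be replayed against a computed wolf via the
#' `sheep_playback` argument of [simulate_trial()]. Arena bounds and frame
#' contiguity are validated on construction.
#'
#' @param table A trajectory table (see [trajectory_table()]).
#' @param disc_id The disc to replay.
#' @param arena The arena the positions must lie in.
#' @return An object of class `"playback_policy"` with `x`, `y` and
#'   `n_frames`.
#' @export
playback_policy <- function(table, disc_id, arena = chasesim::arena()) {
  rows <- table[table$disc_id == disc_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no rows for disc ", disc_id, call. = FALSE)
  rows <- rows[order(rows$frame_idx), ]
  fr <- as.integer(rows$frame_idx)
  if (!identical(fr, 0:(nrow(rows) - 1L))) {
    stop("recorded frames are not contiguous from 0", call. = FALSE)
  }
  if (any(rows$x_deg < 0 | rows$x_deg > arena$width |
            rows$y_deg < 0 | rows$y_deg > arena$height)) {
    stop("recorded position outside the arena", call. = FALSE)
  }
  structure(list(disc_id = disc_id, x = rows$x_deg, y = rows$y_deg,
                 n_frames = nrow(rows)),
            class = "playback_policy")
}

#' Write / read observer response tables
#'
#' Plain-CSV persistence for response tables keyed to exported trial IDs,
#' so externally collected responses can be fed to the same analyses.
#'
#' @param responses A response data frame.
#' @param path CSV path.
#' @return `write_responses()`: the path, invisibly; `read_responses()`:
#'   the response data frame.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "observer_id", "chosen_label", "correct_label")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("response table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out$correct <- out$chosen_label == out$correct_label
  out
}
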