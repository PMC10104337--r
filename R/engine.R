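# Frame-synchronous simulation of whole trials. All policies are evaluated
# against the previous frame's state, then every disc is advanced at once,
# so the update is order-independent.

#' Trial configuration
#'
#' Builds the experiment preset describing one trial: pursuit algorithm,
#' distractor regime and count, speeds, task, visibility and timing.
#'
#' Presets:
#' * `exp1_cpu` - direct-chasing wolf, random-walk distractors, no
#'   correlation-control disc, speeds (sheep 14.4, wolf 9.6, distractor
#'   9.6) deg/s, wolf-identification task.
#' * `exp2` - wolf driven by one of the three algorithms; distractors chase
#'   invisible circling targets; one of the `n_distractors` is the
#'   correlation-control wolf; same speeds as `exp1_cpu`.
#' * `exp3_sheep_task` - as `exp2` but the observer identifies the sheep;
#'   sheep slowed to 9.6 deg/s and wolf to 6.4 deg/s (2/3 of the sheep's
#'   speed, preserving the speed ratio).
#' * `exp4` - identical to `exp2` except the sheep is invisible; the flag
#'   affects exports and observers only, never the dynamics.
#'
#' @param experiment Preset name.
#' @param algorithm Pursuit algorithm for the wolf (and the control wolf).
#' @param n_distractors Number of distractor discs (10 or 19 in the
#'   experiments; the correlation-control wolf counts as one of them).
#'   0 gives a wolf-and-sheep-only trial used for catch-rate simulation.
#' @param seed Integer seed; every random choice in the trial flows from it.
#' @param max_duration Trial length cap in seconds (trials stop earlier
#'   when the sheep is caught).
#' @param dt Frame duration in seconds (60 Hz display).
#' @param arena An [arena()] object.
#' @param params A [policy_params()] object.
#' @param speeds Optional length-3 override `c(sheep, wolf, distractor)`
#'   in deg/s.
#' @param include_control Whether one distractor is the correlation-control
#'   wolf; defaults to `TRUE` for the exp2 family when distractors are
#'   present, `FALSE` for `exp1_cpu`.
#' @return A list of class `"trial_config"`.
#' @export
trial_config <- function(experiment = c("exp2", "exp1_cpu", "exp3_sheep_task", "exp4"),
                         algorithm = c("direct", "mimic", "intercept"),
                         n_distractors = 19, seed = NULL,
                         max_duration = 30, dt = 1 / 60,
                         arena = chasesim::arena(), params = policy_params(),
                         speeds = NULL, include_control = NULL) {
  experiment <- match.arg(experiment)
  algorithm <- match.arg(algorithm)
  stopifnot(n_distractors >= 0, max_duration >= 0, dt > 0)
  if (experiment == "exp1_cpu" && algorithm != "direct") {
    stop("the exp1_cpu preset uses the direct-chasing wolf", call. = FALSE)
  }
  if (is.null(speeds)) {
    speeds <- if (experiment == "exp3_sheep_task") c(9.6, 6.4, 9.6) else c(14.4, 9.6, 9.6)
  }
  stopifnot(length(speeds) == 3, all(speeds >= 0))
  names(speeds) <- c("sheep", "wolf", "distractor")
  if (is.null(include_control)) {
    include_control <- experiment != "exp1_cpu" && n_distractors > 0
  }
  if (include_control && n_distractors < 1) {
    stop("`include_control` requires at least one distractor", call. = FALSE)
  }
  structure(
    list(experiment = experiment,
         algorithm = algorithm,
         n_distractors = as.integer(n_distractors),
         include_control = include_control,
         distractor_regime = if (experiment == "exp1_cpu") "random_walk" else "invisible_sheep",
         task = if (experiment == "exp3_sheep_task") "sheep_id" else "wolf_id",
         sheep_visible = experiment != "exp4",
         speeds = speeds,
         sheep_radius = .SHEEP_RADIUS,
         wolf_radius = .WOLF_RADIUS,
         max_duration = max_duration,
         dt = dt,
         arena = arena,
         params = params,
         seed = seed),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf(
    "<trial_config %s: %s wolf, %d distractors%s, speeds %.1f/%.1f/%.1f deg/s, %gs cap, seed %s>\n",
    x$experiment, x$algorithm, x$n_distractors,
    if (x$include_control) " (incl. control)" else "",
    x$speeds[1], x$speeds[2], x$speeds[3], x$max_duration,
    if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Catch rule
#'
#' The sheep is caught when the wolf-sheep centre distance falls to or
#' below the sum of the two disc radii (1.085 degrees at the default
#' sizes). The boundary is inclusive.
#'
#' @param wolf_pos,sheep_pos Length-2 positions.
#' @param wolf_radius,sheep_radius Disc radii in degrees.
#' @return `TRUE` if the catch condition holds.
#' @export
check_catch <- function(wolf_pos, sheep_pos,
                        wolf_radius = .WOLF_RADIUS, sheep_radius = .SHEEP_RADIUS) {
  point_distance(wolf_pos, sheep_pos) <= wolf_radius + sheep_radius
}

#' Initial disc placement for a trial
#'
#' The sheep starts at a uniform-random arc position on its perimeter loop
#' with a random circling orientation; the wolf is drawn uniformly in the
#' arena, rejecting draws closer than `init_min_dist` (11 degrees) to the
#' sheep; distractors, their invisible targets, and the correlation-control
#' wolf are drawn uniformly in the arena. Uses the current RNG state.
#'
#' @param config A [trial_config()] object.
#' @return A list with the initial state (sheep arc/orientation/position,
#'   wolf and control positions, distractor matrix and regime state).
#' @export
initialize_trial <- function(config) {
  ar <- config$arena
  path <- circling_path(ar, margin = config$sheep_radius)
  orientation <- sample(c("ccw", "cw"), 1L)
  orient <- if (orientation == "ccw") 1 else -1
  s0 <- stats::runif(1, 0, path$perimeter)
  sheep_pos <- drop(.rect_point(s0, path$cx, path$cy, path$px, path$py))
  sheep_dir_idx <- .rect_tangent_idx(s0, path$px, path$py, orient)

  wolf_pos <- NULL
  for (i in seq_len(10000L)) {
    cand <- c(stats::runif(1, 0, ar$width), stats::runif(1, 0, ar$height))
    if (point_distance(cand, sheep_pos) >= config$params$init_min_dist) {
      wolf_pos <- cand
      break
    }
  }
  if (is.null(wolf_pos)) {
    stop("could not place the wolf at least init_min_dist from the sheep",
         call. = FALSE)
  }

  n_plain <- config$n_distractors - as.integer(config$include_control)
  D <- cbind(stats::runif(n_plain, 0, ar$width), stats::runif(n_plain, 0, ar$height))
  regime <- NULL
  if (n_plain > 0) {
    if (config$distractor_regime == "random_walk") {
      regime <- list(dir_idx = sample.int(8L, n_plain, replace = TRUE) - 1L)
    } else {
      qx <- stats::runif(n_plain, 0, ar$width)
      qy <- stats::runif(n_plain, 0, ar$height)
      loops <- lapply(seq_len(n_plain), function(i) {
        .loop_through_point(c(qx[i], qy[i]), path, ar)
      })
      regime <- list(
        px = vapply(loops, `[[`, 0, "px"),
        py = vapply(loops, `[[`, 0, "py"),
        arc = vapply(loops, `[[`, 0, "arc"),
        orient = sample(c(1, -1), n_plain, replace = TRUE)
      )
    }
  }
  control_pos <- if (config$include_control) {
    c(stats::runif(1, 0, ar$width), stats::runif(1, 0, ar$height))
  }
  list(path = path, orientation = orientation, sheep_arc = s0,
       sheep_pos = sheep_pos, sheep_dir_idx = sheep_dir_idx,
       wolf_pos = wolf_pos, control_pos = control_pos,
       distractors = D, regime = regime)
}

# Predicted path of an on-loop circling sheep: exact arc-length traversal,
# vectorized (matches predict_sheep_path() for on-path states).
.circ_path_points <- function(arc, orient, path, horizon, speed, dt) {
  s <- arc + orient * speed * dt * seq_len(horizon)
  .rect_point(s, path$cx, path$cy, path$px, path$py)
}

#' Simulate one complete trial
#'
#' Runs the frame loop at `1/dt` Hz until the sheep is caught or
#' `max_duration` elapses. Policies see the previous frame's state; all
#' discs then move synchronously. Distractor "catches" of their invisible
#' targets trigger a respawn of the target, never trial termination; the
#' correlation-control wolf is never catch-checked against the real sheep.
#'
#' @param config A [trial_config()] object with a `seed`.
#' @param record_frames If `FALSE`, per-frame positions are discarded and
#'   only the outcome (catch time, duration) is kept - used for
#'   Monte-Carlo catch-rate estimation.
#' @param init Optional initial state overriding [initialize_trial()]
#'   (same structure); used for controlled experiments and tests.
#' @param sheep_playback Optional [playback_policy()] driving the sheep
#'   from recorded positions instead of the circling algorithm.
#' @return An object of class `"trial_record"`: list with `config`, `x`
#'   and `y` (frame x disc position matrices, unless
#'   `record_frames = FALSE`), `roles`, `orientation`, `catch_time`
#'   (seconds or `NA`), `duration` and `n_frames`.
#' @export
simulate_trial <- function(config, record_frames = TRUE, init = NULL,
                           sheep_playback = NULL) {
  stopifnot(inherits(config, "trial_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ar <- config$arena
  dt <- config$dt
  pp <- config$params
  v_sheep <- config$speeds[["sheep"]]
  v_wolf <- config$speeds[["wolf"]]
  v_dist <- config$speeds[["distractor"]]
  catch_r <- config$wolf_radius + config$sheep_radius

  if (is.null(init)) init <- initialize_trial(config)
  path <- init$path
  orient <- if (init$orientation == "ccw") 1 else -1
  s <- init$sheep_arc
  sheep <- init$sheep_pos
  sheep_idx <- init$sheep_dir_idx
  wolf <- init$wolf_pos
  control <- init$control_pos
  D <- init$distractors
  regime <- init$regime
  n_plain <- if (is.null(D)) 0L else nrow(D)
  has_control <- !is.null(control)

  nstep <- as.integer(round(config$max_duration / dt))
  if (!is.null(sheep_playback)) {
    nstep <- min(nstep, sheep_playback$n_frames - 1L)
    sheep <- c(sheep_playback$x[1L], sheep_playback$y[1L])
    sheep_idx <- NA_integer_
  }

  roles <- c("sheep", "wolf",
             if (has_control) "control_wolf",
             rep("distractor", n_plain))
  n_disc <- length(roles)
  if (record_frames) {
    X <- matrix(NA_real_, nstep + 1L, n_disc)
    Y <- matrix(NA_real_, nstep + 1L, n_disc)
    X[1L, ] <- c(sheep[1], wolf[1], if (has_control) control[1], D[, 1])
    Y[1L, ] <- c(sheep[2], wolf[2], if (has_control) control[2], D[, 2])
  }

  # distractor regime state
  rw <- config$distractor_regime == "random_walk" && n_plain > 0
  inv <- config$distractor_regime == "invisible_sheep" && n_plain > 0
  if (rw) {
    redirect_every <- max(1L, as.integer(round(pp$redirect_interval / dt)))
    d_idx <- regime$dir_idx
  }
  if (inv) {
    ipx <- regime$px; ipy <- regime$py; iarc <- regime$arc; iorient <- regime$orient
    iper <- 4 * (ipx + ipy)
    inv_pos <- .rect_point(iarc, path$cx, path$cy, ipx, ipy)
    inv_catch_r <- config$wolf_radius + config$sheep_radius
  }

  wolf_step <- v_wolf * dt
  sheep_step <- v_sheep * dt
  dist_step <- v_dist * dt
  horizon <- pp$predict_horizon
  prox <- pp$proximity_switch
  half_per <- path$perimeter / 2

  catch_frame <- NA_integer_
  last_f <- 0L

  for (f in seq_len(nstep)) {
    # --- directions from the state at frame f-1 ---

    # sheep: next position along its loop (or from playback)
    if (!is.null(sheep_playback)) {
      sheep_new <- c(sheep_playback$x[f + 1L], sheep_playback$y[f + 1L])
    } else {
      s_new <- (s + orient * sheep_step) %% path$perimeter
      sheep_new <- drop(.rect_point(s_new, path$cx, path$cy, path$px, path$py))
    }
    sheep_dir <- if (is.na(sheep_idx)) .DIR_NONE else .DIR8[sheep_idx + 1L, ]

    # wolf
    dws <- sqrt((wolf[1] - sheep[1])^2 + (wolf[2] - sheep[2])^2)
    if (config$algorithm == "direct" || dws < prox) {
      w_dir <- direct_chase(wolf, sheep)
    } else if (config$algorithm == "mimic") {
      w_dir <- sheep_dir
    } else {
      pred <- if (is.null(sheep_playback)) {
        .circ_path_points(s, orient, path, horizon, v_sheep, dt)
      } else {
        predict_sheep_path(sheep, sheep_dir, ar, horizon = horizon,
                           orientation = init$orientation,
                           speed = v_sheep, dt = dt)
      }
      w_dir <- intercept(wolf, sheep, sheep_dir, ar, params = pp,
                         wolf_speed = v_wolf, sheep_speed = v_sheep,
                         dt = dt, path = pred)
    }
    wolf_new <- c(min(max(wolf[1] + wolf_step * w_dir[1], 0), ar$width),
                  min(max(wolf[2] + wolf_step * w_dir[2], 0), ar$height))

    # correlation-control wolf: same algorithm against the mirrored sheep
    if (has_control) {
      m_pos <- c(2 * path$cx - sheep[1], 2 * path$cy - sheep[2])
      dcm <- sqrt((control[1] - m_pos[1])^2 + (control[2] - m_pos[2])^2)
      if (config$algorithm == "direct" || dcm < prox) {
        c_dir <- direct_chase(control, m_pos)
      } else if (config$algorithm == "mimic") {
        c_dir <- -sheep_dir
      } else {
        m_pred <- if (is.null(sheep_playback)) {
          .circ_path_points(s + half_per, orient, path, horizon, v_sheep, dt)
        } else {
          predict_sheep_path(m_pos, -sheep_dir, ar, horizon = horizon,
                             orientation = init$orientation,
                             speed = v_sheep, dt = dt)
        }
        c_dir <- intercept(control, m_pos, -sheep_dir, ar, params = pp,
                           wolf_speed = v_dist, sheep_speed = v_sheep,
                           dt = dt, path = m_pred)
      }
      control_new <- c(min(max(control[1] + dist_step * c_dir[1], 0), ar$width),
                       min(max(control[2] + dist_step * c_dir[2], 0), ar$height))
    }

    # plain distractors
    if (rw) {
      if (f > 1L && (f - 1L) %% redirect_every == 0L) {
        d_idx <- sample.int(8L, n_plain, replace = TRUE) - 1L
      }
      Dn <- cbind(pmin(pmax(D[, 1] + dist_step * .DIR8[d_idx + 1L, 1L], 0), ar$width),
                  pmin(pmax(D[, 2] + dist_step * .DIR8[d_idx + 1L, 2L], 0), ar$height))
      blocked <- which(abs(Dn[, 1] - D[, 1]) + abs(Dn[, 2] - D[, 2]) < 1e-12)
      for (b in blocked) {
        for (tries in 1:16) {
          d_idx[b] <- sample.int(8L, 1L) - 1L
          nb <- c(min(max(D[b, 1] + dist_step * .DIR8[d_idx[b] + 1L, 1L], 0), ar$width),
                  min(max(D[b, 2] + dist_step * .DIR8[d_idx[b] + 1L, 2L], 0), ar$height))
          if (abs(nb[1] - D[b, 1]) + abs(nb[2] - D[b, 2]) > 1e-12) break
        }
        Dn[b, ] <- c(min(max(D[b, 1] + dist_step * .DIR8[d_idx[b] + 1L, 1L], 0), ar$width),
                     min(max(D[b, 2] + dist_step * .DIR8[d_idx[b] + 1L, 2L], 0), ar$height))
      }
      D <- Dn
    } else if (inv) {
      # advance invisible targets along their loops
      iarc_new <- ifelse(iper > 1e-12, (iarc + iorient * sheep_step) %% iper, iarc)
      inv_new <- .rect_point(iarc_new, path$cx, path$cy, ipx, ipy)
      # distractors direct-chase their targets (previous-frame positions)
      ang <- atan2(inv_pos[, 2] - D[, 2], inv_pos[, 1] - D[, 1])
      idx <- .quantize_idx(ang)
      Dn <- cbind(pmin(pmax(D[, 1] + dist_step * .DIR8[idx + 1L, 1L], 0), ar$width),
                  pmin(pmax(D[, 2] + dist_step * .DIR8[idx + 1L, 2L], 0), ar$height))
      D <- Dn
      # catches: respawn the invisible target uniformly in the arena
      dcatch <- sqrt((D[, 1] - inv_new[, 1])^2 + (D[, 2] - inv_new[, 2])^2)
      hit <- which(dcatch <= inv_catch_r)
      for (b in hit) {
        q <- c(stats::runif(1, 0, ar$width), stats::runif(1, 0, ar$height))
        lp <- .loop_through_point(q, path, ar)
        ipx[b] <- lp$px; ipy[b] <- lp$py; iarc_new[b] <- lp$arc
        iper[b] <- lp$perimeter
        iorient[b] <- sample(c(1, -1), 1L)
      }
      iarc <- iarc_new
      inv_pos <- .rect_point(iarc, path$cx, path$cy, ipx, ipy)
    }

    # --- commit frame f ---
    if (is.null(sheep_playback)) s <- s_new
    new_idx <- if (abs(sheep_new[1] - sheep[1]) + abs(sheep_new[2] - sheep[2]) < 1e-12) {
      NA_integer_
    } else {
      .quantize_idx(atan2(sheep_new[2] - sheep[2], sheep_new[1] - sheep[1]))
    }
    sheep <- sheep_new
    sheep_idx <- new_idx
    wolf <- wolf_new
    if (has_control) control <- control_new

    if (record_frames) {
      X[f + 1L, ] <- c(sheep[1], wolf[1], if (has_control) control[1], D[, 1])
      Y[f + 1L, ] <- c(sheep[2], wolf[2], if (has_control) control[2], D[, 2])
    }
    last_f <- f
    dcatch <- sqrt((wolf[1] - sheep[1])^2 + (wolf[2] - sheep[2])^2)
    if (dcatch <= catch_r) {
      catch_frame <- f
      break
    }
  }

  n_frames <- last_f + 1L
  duration <- last_f * dt
  structure(
    list(config = config,
         trial_id = NA_character_,
         x = if (record_frames) X[seq_len(n_frames), , drop = FALSE],
         y = if (record_frames) Y[seq_len(n_frames), , drop = FALSE],
         roles = roles,
         labels = rep(NA_integer_, n_disc),
         answer_label = NA_integer_,
         orientation = init$orientation,
         catch_time = if (is.na(catch_frame)) NA_real_ else catch_frame * dt,
         duration = duration,
         n_frames = n_frames),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record %s/%s: %d discs, %.2f s (%d frames), %s>\n",
    x$config$experiment, x$config$algorithm, length(x$roles),
    x$duration, x$n_frames,
    if (is.na(x$catch_time)) "no catch"
    else sprintf("caught at %.2f s", x$catch_time)))
  invisible(x)
}
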