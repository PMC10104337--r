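# Per-frame movement policies: the three wolf algorithms (direct chasing,
# sheep mimicking, sheep interception), the random-walk distractor rule,
# wall-aware extrapolation of the sheep's path, and the correlation-control
# wolf that chases the mirrored sheep.

#' Policy parameters
#'
#' Tunable constants shared by the pursuit policies.
#'
#' @param proximity_switch Distance (degrees) below which the mimicking and
#'   intercepting wolves switch to direct chasing; the switch is strict
#'   (`distance < proximity_switch`).
#' @param redirect_interval Seconds between random-walk distractor
#'   re-directions (0.167 s, i.e. 10 frames at 60 Hz).
#' @param init_min_dist Minimum wolf-sheep distance at initialization
#'   (degrees).
#' @param predict_horizon Number of frames the interception policy
#'   extrapolates the sheep's path over (180 frames = 3 s at 60 Hz).
#' @return A list of class `"policy_params"`.
#' @export
policy_params <- function(proximity_switch = 6, redirect_interval = 0.167,
                          init_min_dist = 11, predict_horizon = 180) {
  stopifnot(proximity_switch > 0, redirect_interval > 0,
            init_min_dist > 0, predict_horizon >= 1)
  structure(
    list(proximity_switch = proximity_switch,
         redirect_interval = redirect_interval,
         init_min_dist = init_min_dist,
         predict_horizon = as.integer(predict_horizon)),
    class = "policy_params"
  )
}

#' Direct ("heat-seeking") chasing direction
#'
#' The bearing from the wolf to the target is computed and the wolf moves
#' in the allowable compass direction closest to it. Coincident positions
#' yield the no-move direction.
#'
#' @param wolf_pos Length-2 wolf position.
#' @param target_pos Length-2 target position.
#' @return A compass unit vector, or `c(0, 0)` if the positions coincide.
#' @examples
#' direct_chase(c(0, 0), c(2, 1))  # snaps to the 45-degree diagonal
#' @export
direct_chase <- function(wolf_pos, target_pos) {
  dx <- target_pos[1] - wolf_pos[1]
  dy <- target_pos[2] - wolf_pos[2]
  if (dx == 0 && dy == 0) return(.DIR_NONE)
  .dir_from_idx(.quantize_idx(atan2(dy, dx)))
}

#' Extrapolate the sheep's future path with wall-aware turns
#'
#' Simulates the sheep forward from its position and last movement
#' direction, one frame at a time. The sheep is modelled as a circler:
#' motion is bounded by the circling-path rectangle (arena inset by
#' `margin`), and when the heading runs into that bound the sheep is
#' expected to turn onto the adjacent edge continuing the trial's
#' orientation. The unused portion of a step is carried through the turn,
#' so the path is the exact arc-length traversal for a sheep already on
#' the loop. A diagonal heading slides along the bound (blocked component
#' zeroed) before corner turns apply; a no-move heading predicts a
#' stationary sheep.
#'
#' @param pos Length-2 current sheep position.
#' @param dir Length-2 last movement direction (compass unit vector or
#'   `c(0, 0)`).
#' @param arena An [arena()] object.
#' @param horizon Number of frames to extrapolate (>= 1).
#' @param orientation `"ccw"` or `"cw"` circling orientation used for
#'   corner turns.
#' @param speed Sheep speed in degrees per second.
#' @param dt Frame duration in seconds.
#' @param margin Inset of the motion bound from the walls (degrees).
#' @return A `horizon` x 2 matrix of predicted positions (frames 1..horizon).
#' @export
predict_sheep_path <- function(pos, dir, arena, horizon = 180,
                               orientation = c("ccw", "cw"),
                               speed = 14.4, dt = 1 / 60,
                               margin = .SHEEP_RADIUS) {
  orientation <- match.arg(orientation)
  stopifnot(horizon >= 1)
  horizon <- as.integer(horizon)
  if (all(dir == 0)) {
    return(matrix(rep(pos, each = horizon), horizon, 2,
                  dimnames = list(NULL, c("x", "y"))))
  }
  lo <- c(margin, margin)
  hi <- c(arena$width - margin, arena$height - margin)
  rot <- if (orientation == "ccw") {
    function(v) c(-v[2], v[1])   # left turn
  } else {
    function(v) c(v[2], -v[1])   # right turn
  }
  p <- pmin(pmax(pos, lo), hi)
  v <- dir
  step <- speed * dt
  out <- matrix(NA_real_, horizon, 2, dimnames = list(NULL, c("x", "y")))
  for (k in seq_len(horizon)) {
    rem <- step
    for (guard in 1:8) {
      if (rem <= 1e-12 || all(v == 0)) break
      # time (in step units) until each moving axis hits its bound
      t_hit <- rep(Inf, 2)
      for (a in 1:2) {
        if (v[a] > 0) t_hit[a] <- (hi[a] - p[a]) / v[a]
        else if (v[a] < 0) t_hit[a] <- (p[a] - lo[a]) / (-v[a])
      }
      tmin <- max(min(t_hit), 0)
      if (tmin >= rem) {
        p <- p + rem * v
        rem <- 0
      } else {
        p <- p + tmin * v
        rem <- rem - tmin
        blocked <- which(t_hit - tmin <= 1e-9)
        if (length(blocked) == sum(v != 0)) {
          # heading fully blocked: turn onto the adjacent edge
          for (r in 1:4) {
            v <- rot(v)
            ok <- TRUE
            for (a in 1:2) {
              if ((v[a] > 0 && p[a] >= hi[a] - 1e-12) ||
                  (v[a] < 0 && p[a] <= lo[a] + 1e-12)) ok <- FALSE
            }
            if (ok) break
          }
        } else {
          # diagonal sliding: zero the blocked component, keep the rest
          v[blocked] <- 0
        }
      }
      p <- pmin(pmax(p, lo), hi)
    }
    out[k, ] <- p
  }
  out
}

#' Sheep-interception chasing direction
#'
#' When the sheep is within `proximity_switch` the wolf reverts to direct
#' chasing. Otherwise the sheep's future path is extrapolated (with
#' wall-aware turns, see [predict_sheep_path()]) and the wolf targets the
#' earliest predicted point it could reach in time, i.e. the first frame
#' `t` with `distance(wolf, path[t]) <= wolf_speed * t * dt`; if no point
#' is reachable within the horizon the wolf heads for the horizon's end.
#'
#' @param wolf_pos Length-2 wolf position.
#' @param sheep_pos Length-2 sheep position.
#' @param sheep_dir Sheep's last movement direction.
#' @param arena An [arena()] object.
#' @param orientation Circling orientation assumed for the extrapolation.
#' @param params A [policy_params()] object.
#' @param wolf_speed,sheep_speed Speeds in degrees per second.
#' @param dt Frame duration in seconds.
#' @param path Optional precomputed predicted path (`horizon` x 2 matrix);
#'   when supplied the extrapolation step is skipped.
#' @return A compass unit vector.
#' @export
intercept <- function(wolf_pos, sheep_pos, sheep_dir, arena,
                      orientation = "ccw", params = policy_params(),
                      wolf_speed = 9.6, sheep_speed = 14.4, dt = 1 / 60,
                      path = NULL) {
  if (point_distance(wolf_pos, sheep_pos) < params$proximity_switch) {
    return(direct_chase(wolf_pos, sheep_pos))
  }
  if (is.null(path)) {
    path <- predict_sheep_path(sheep_pos, sheep_dir, arena,
                               horizon = params$predict_horizon,
                               orientation = orientation,
                               speed = sheep_speed, dt = dt)
  }
  h <- nrow(path)
  d <- sqrt((path[, 1] - wolf_pos[1])^2 + (path[, 2] - wolf_pos[2])^2)
  reach <- which(d <= wolf_speed * dt * seq_len(h))
  k <- if (length(reach)) reach[1] else h
  direct_chase(wolf_pos, path[k, ])
}

#' Sheep-mimicking chasing direction
#'
#' The wolf copies the sheep's last (quantized) movement direction while
#' the sheep is at least `proximity_switch` away, and switches to direct
#' chasing when the sheep is strictly closer than that. Wall clamping in
#' [step_position()] then keeps a mimicking wolf moving around an edge or
#' corner when the copied direction runs into the frame.
#'
#' @inheritParams intercept
#' @return A compass unit vector (or `c(0, 0)` if the sheep has not moved).
#' @export
mimic <- function(wolf_pos, sheep_pos, sheep_dir, params = policy_params()) {
  if (point_distance(wolf_pos, sheep_pos) < params$proximity_switch) {
    direct_chase(wolf_pos, sheep_pos)
  } else {
    sheep_dir
  }
}

#' Random-walk distractor direction
#'
#' Distractors keep their direction and re-draw it uniformly from the
#' eight compass directions every `redirect_interval` seconds (frames that
#' are multiples of `round(redirect_interval / dt)`). A direction that is
#' wall-blocked (zero net motion from `pos`) is re-drawn immediately.
#'
#' @param pos Length-2 distractor position.
#' @param last_dir Current direction.
#' @param frame_idx Frame counter (0-based).
#' @param arena An [arena()] object.
#' @param speed,dt Speed (deg/s) and frame duration (s).
#' @param params A [policy_params()] object.
#' @return A compass unit vector.
#' @export
random_walk <- function(pos, last_dir, frame_idx, arena, speed = 9.6,
                        dt = 1 / 60, params = policy_params()) {
  every <- max(1L, as.integer(round(params$redirect_interval / dt)))
  dir <- last_dir
  if (frame_idx %% every == 0L || all(dir == 0)) {
    dir <- .dir_from_idx(sample.int(8L, 1L) - 1L)
  }
  for (tries in 1:16) {
    nxt <- step_position(pos, dir, speed, dt, arena)
    if (point_distance(nxt, pos) > 1e-12) break
    dir <- .dir_from_idx(sample.int(8L, 1L) - 1L)
  }
  dir
}

#' Correlation-control wolf direction
#'
#' The control disc applies the trial's pursuit algorithm to the mirror
#' image of the sheep (point-reflected through the arena centre, with the
#' last movement direction negated). Its motion is therefore as correlated
#' with the sheep's as the true wolf's, while never moving toward her.
#'
#' @param control_pos Length-2 control-wolf position.
#' @param sheep_pos,sheep_dir The real sheep's position and last direction.
#' @param arena An [arena()] object.
#' @param algorithm `"direct"`, `"mimic"` or `"intercept"`.
#' @param orientation Circling orientation of the trial.
#' @param params A [policy_params()] object.
#' @param wolf_speed,sheep_speed,dt As in [intercept()].
#' @param path Optional precomputed predicted path of the *mirrored* sheep.
#' @return A compass unit vector.
#' @export
control_wolf <- function(control_pos, sheep_pos, sheep_dir, arena,
                         algorithm = c("direct", "mimic", "intercept"),
                         orientation = "ccw", params = policy_params(),
                         wolf_speed = 9.6, sheep_speed = 14.4, dt = 1 / 60,
                         path = NULL) {
  algorithm <- match.arg(algorithm)
  m_pos <- mirror_point(sheep_pos, arena)
  m_dir <- -sheep_dir
  switch(algorithm,
    direct = direct_chase(control_pos, m_pos),
    mimic = mimic(control_pos, m_pos, m_dir, params),
    intercept = intercept(control_pos, m_pos, m_dir, arena,
                          orientation = orientation, params = params,
                          wolf_speed = wolf_speed, sheep_speed = sheep_speed,
                          dt = dt, path = path)
  )
}
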