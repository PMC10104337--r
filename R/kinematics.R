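# Geometry and eight-direction quantized motion shared by every agent.
# All positions are disc centres in degrees of visual angle, origin at the
# arena's lower-left corner.

#' Display arena
#'
#' The bounded frame that all discs move in. The default 32 x 24 degrees of
#' visual angle corresponds to the display frame used for the chasing
#' stimuli (assuming a 50 cm viewing distance).
#'
#' @param width Arena width in degrees of visual angle.
#' @param height Arena height in degrees of visual angle.
#' @return An object of class `"arena"`: a list with `width`, `height` and
#'   `center` (the point `c(width, height) / 2`).
#' @examples
#' ar <- arena()
#' ar$center
#' @export
arena <- function(width = 32, height = 24) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0)
  structure(
    list(width = width, height = height, center = c(width, height) / 2),
    class = "arena"
  )
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena %g x %g deg, center (%g, %g)>\n",
              x$width, x$height, x$center[1], x$center[2]))
  invisible(x)
}

# Unit vectors for the 8 compass directions, counterclockwise from east.
# Diagonals are exactly (+-sqrt(1/2), +-sqrt(1/2)) so every row has norm 1.
.DIR8 <- local({
  s <- sqrt(0.5)
  m <- rbind(
    c(1, 0), c(s, s), c(0, 1), c(-s, s),
    c(-1, 0), c(-s, -s), c(0, -1), c(s, -s)
  )
  dimnames(m) <- list(NULL, c("dx", "dy"))
  m
})

# No-move null direction.
.DIR_NONE <- c(dx = 0, dy = 0)

# Compass index (0..7, counterclockwise from east) nearest to `angle`.
# Exact ties go to the smaller compass index; the tie at 337.5 deg is
# between indices 7 and 0 and therefore resolves to 0. Vectorized.
.quantize_idx <- function(angle) {
  a <- (angle / (pi / 4)) %% 8
  # snap floating-point near-ties onto the exact half-integer so the
  # documented tie-break applies deterministically
  half <- round(2 * a) / 2
  a <- ifelse(abs(a - half) < 1e-9, half, a)
  idx <- ceiling(a - 0.5)
  idx[a >= 7.5] <- 0
  as.integer(idx)
}

.dir_from_idx <- function(idx) .DIR8[idx + 1L, , drop = TRUE]

#' Quantize an angle to the nearest of the eight allowed directions
#'
#' Discs may only move in the four cardinal and four ordinal directions.
#' This returns the unit vector of the compass direction with minimum
#' absolute angular distance to `angle`; exact ties (angles half-way
#' between two compass directions) are broken toward the smaller compass
#' index in counterclockwise-from-east order.
#'
#' @param angle Heading in radians (any finite value; measured
#'   counterclockwise from the positive x axis).
#' @return A length-2 unit vector `c(dx, dy)`.
#' @examples
#' quantize_direction(0)          # east
#' quantize_direction(atan2(1, 2)) # snaps to the 45-degree diagonal
#' @export
quantize_direction <- function(angle) {
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle)) {
    stop("`angle` must be a single finite number (radians)", call. = FALSE)
  }
  .dir_from_idx(.quantize_idx(angle))
}

#' Advance a position one time step with wall sliding
#'
#' Moves `pos` by `speed * dt` along the unit direction `dir`, then clamps
#' the result inside the arena. Clamping zeroes the portion of the
#' displacement that would exit the frame while keeping the tangential
#' portion, so discs slide along walls rather than sticking to them.
#'
#' @param pos Length-2 position `c(x, y)` inside the arena.
#' @param dir Length-2 direction (a compass unit vector or `c(0, 0)`).
#' @param speed Speed in degrees per second.
#' @param dt Time step in seconds (must be positive).
#' @param arena An [arena()] object.
#' @return The new position, guaranteed inside `[0, width] x [0, height]`.
#' @examples
#' step_position(c(5, 5), c(1, 0), speed = 9.6, dt = 1 / 60, arena())
#' @export
step_position <- function(pos, dir, speed, dt, arena) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  p <- pos + speed * dt * dir
  c(min(max(p[1], 0), arena$width), min(max(p[2], 0), arena$height))
}

#' Euclidean distance between two points
#'
#' @param a,b Length-2 points in degrees.
#' @return Distance in degrees (non-negative, symmetric).
#' @export
point_distance <- function(a, b) {
  sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2)
}

#' Reflect a point through the arena centre
#'
#' Point reflection used to build the correlation-control distractor's
#' target: the control disc chases the mirror image of the sheep, so its
#' motion is as correlated with the sheep's as the true wolf's while never
#' approaching her. The map is an involution and sends the arena onto
#' itself.
#'
#' @param p Length-2 point inside the arena.
#' @param arena An [arena()] object.
#' @return `2 * center - p`.
#' @examples
#' mirror_point(c(10, 5), arena())  # (22, 19)
#' @export
mirror_point <- function(p, arena) {
  2 * arena$center - p
}
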