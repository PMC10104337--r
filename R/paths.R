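# Arc-length parameterization of rectangular circling loops.
#
# The sheep "circles" the arena: it traverses a rectangle inset from the
# walls by a margin (default: the sheep's radius, so the disc edge grazes
# the frame). Invisible targets chased by the distractors circle smaller
# rectangles of the same aspect, concentric with the arena, passing through
# their spawn point. Arc length runs counterclockwise from the lower-left
# corner of the loop; clockwise travel decreases the arc coordinate.

# Default disc sizes (degrees). Sheep diameter 0.87, wolf/distractor 1.3.
.SHEEP_RADIUS <- 0.87 / 2
.WOLF_RADIUS <- 1.3 / 2

#' Perimeter circling path of the sheep
#'
#' Describes the rectangular loop the sheep travels around. The loop is the
#' arena rectangle inset from every wall by `margin` so the whole disc
#' stays visible.
#'
#' @param arena An [arena()] object.
#' @param margin Inset from the walls in degrees; defaults to the sheep's
#'   radius (0.435).
#' @return An object of class `"circling_path"`: list with center `cx`,
#'   `cy`, half-widths `px`, `py` and `perimeter`.
#' @export
circling_path <- function(arena, margin = .SHEEP_RADIUS) {
  px <- arena$width / 2 - margin
  py <- arena$height / 2 - margin
  stopifnot(px > 0, py > 0)
  structure(
    list(cx = arena$center[1], cy = arena$center[2], px = px, py = py,
         perimeter = 4 * (px + py)),
    class = "circling_path"
  )
}

# Point on a rectangular loop at arc coordinate s (counterclockwise from
# the lower-left corner). Vectorized over s and over loop geometry; loops
# with (near-)zero perimeter collapse to their centre.
.rect_point <- function(s, cx, cy, px, py) {
  per <- 4 * (px + py)
  n <- max(length(s), length(px))
  s <- rep_len(s, n); cx <- rep_len(cx, n); cy <- rep_len(cy, n)
  px <- rep_len(px, n); py <- rep_len(py, n); per <- rep_len(per, n)
  x <- cx; y <- cy
  ok <- per > 1e-12
  ss <- ifelse(ok, s %% per, 0)
  w <- 2 * px; h <- 2 * py
  # bottom edge [0, w)
  e1 <- ok & ss < w
  x[e1] <- cx[e1] - px[e1] + ss[e1]
  y[e1] <- cy[e1] - py[e1]
  # right edge [w, w + h)
  e2 <- ok & !e1 & ss < w + h
  x[e2] <- cx[e2] + px[e2]
  y[e2] <- cy[e2] - py[e2] + (ss[e2] - w[e2])
  # top edge [w + h, 2w + h)
  e3 <- ok & !e1 & !e2 & ss < 2 * w + h
  x[e3] <- cx[e3] + px[e3] - (ss[e3] - w[e3] - h[e3])
  y[e3] <- cy[e3] + py[e3]
  # left edge [2w + h, per)
  e4 <- ok & !e1 & !e2 & !e3
  x[e4] <- cx[e4] - px[e4]
  y[e4] <- cy[e4] + py[e4] - (ss[e4] - 2 * w[e4] - h[e4])
  cbind(x = x, y = y)
}

# Compass index of the tangent at arc s; clockwise travel reverses the
# counterclockwise tangent (idx + 4 mod 8). At an exact corner the tangent
# belongs to the edge being entered, which depends on the orientation.
.rect_tangent_idx <- function(s, px, py, orient) {
  per <- 4 * (px + py)
  ss <- if (orient < 0) (s - 1e-9) %% per else s %% per
  w <- 2 * px; h <- 2 * py
  idx <- ifelse(ss < w, 0L, ifelse(ss < w + h, 2L, ifelse(ss < 2 * w + h, 4L, 6L)))
  if (orient < 0) idx <- (idx + 4L) %% 8L
  as.integer(idx)
}

# Arc coordinate of the point on the loop boundary nearest to q:
# clamp into the rectangle, push the axis proportionally closest to its
# edge onto that edge, then read the arc off the edge the point lies on.
.rect_arc_of_point <- function(q, cx, cy, px, py) {
  per <- 4 * (px + py)
  if (per <= 1e-12) return(0)
  dx <- min(max(q[1] - cx, -px), px)
  dy <- min(max(q[2] - cy, -py), py)
  if (abs(dx) < px && abs(dy) < py) {
    rx <- if (px > 0) abs(dx) / px else 1
    ry <- if (py > 0) abs(dy) / py else 1
    if (rx >= ry) dx <- if (dx >= 0) px else -px else dy <- if (dy >= 0) py else -py
  }
  w <- 2 * px; h <- 2 * py
  s <- if (abs(dy + py) <= 1e-9) {
    dx + px                # bottom
  } else if (abs(dx - px) <= 1e-9) {
    w + (dy + py)          # right
  } else if (abs(dy - py) <= 1e-9) {
    w + h + (px - dx)      # top
  } else {
    2 * w + h + (py - dy)  # left
  }
  s %% per
}

# Invisible-target loop through spawn point q: the sheep's loop rectangle
# scaled about the arena centre until its boundary passes through q, then
# clipped to the arena. Degenerate (q at the centre) loops collapse to a
# point.
.loop_through_point <- function(q, path, arena) {
  dx <- abs(q[1] - path$cx); dy <- abs(q[2] - path$cy)
  cc <- max(if (path$px > 0) dx / path$px else 0,
            if (path$py > 0) dy / path$py else 0)
  px <- min(cc * path$px, arena$width / 2)
  py <- min(cc * path$py, arena$height / 2)
  s <- .rect_arc_of_point(q, path$cx, path$cy, px, py)
  list(px = px, py = py, perimeter = 4 * (px + py), arc = s)
}

#' Tangential circling direction of the sheep
#'
#' Returns the compass direction the circling sheep moves in at a point of
#' its perimeter loop: the tangent of the rectangle in the trial's
#' orientation. At a corner the direction already belongs to the next edge,
#' so repeatedly stepping carries the sheep around the loop.
#'
#' @param pos Length-2 position on (or near) the circling path.
#' @param path A [circling_path()] object.
#' @param orientation `"ccw"` or `"cw"`; randomized across trials in the
#'   experiments.
#' @param tol Maximum allowed distance from the loop before the position is
#'   considered off the path.
#' @return A length-2 compass unit vector.
#' @export
circling_sheep <- function(pos, path, orientation = c("ccw", "cw"), tol = 0.5) {
  orientation <- match.arg(orientation)
  s <- .rect_arc_of_point(pos, path$cx, path$cy, path$px, path$py)
  on_path <- .rect_point(s, path$cx, path$cy, path$px, path$py)
  if (point_distance(pos, on_path) > tol) {
    stop("position is off the circling path beyond tolerance", call. = FALSE)
  }
  orient <- if (orientation == "ccw") 1 else -1
  .dir_from_idx(.rect_tangent_idx(s, path$px, path$py, orient))
}
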