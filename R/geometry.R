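# Arena geometry and coordinate conventions.
#
# Canonical frame: arena center at (0,0); the bridge to the home base lies on
# the negative-y axis, so "south" (0,-1) points from the arena center toward
# the bridge. Angles are measured counterclockwise-positive and reported in
# degrees in [-180, 180).

# Lever-box footprint (cm). The box is a 11.6 x 8.2 cm rectangle; the
# pressable lever sits on one long face, so the long axis runs across the
# lever direction.
LEVER_BOX_LONG <- 11.6
LEVER_BOX_SHORT <- 8.2

#' Arena geometry
#'
#' Container for the fixed geometry of the apparatus: an 80-cm circular arena
#' with its center at the origin, a bridge to the home base on the negative-y
#' axis, and the distance thresholds used by path segmentation and the
#' lever-centered analyses.
#'
#' @param arena_radius Arena radius in cm (default 40, i.e. an 80 cm arena).
#' @param bridge_center Bridge center (x, y) in cm; must lie outside the
#'   arena circle on the negative-y side.
#' @param periphery_threshold Distance from the arena edge (cm) within which
#'   the animal is considered to have reached the periphery (default 3).
#' @param lever_proximity_threshold Distance from the lever-box wall (cm)
#'   within which the animal is considered at the lever (default 10).
#' @param lever_frame_radius Maximal distance from the lever-box wall (cm)
#'   included in lever-centered maps and tuning curves (default 12).
#' @param lever_center_max_radius Maximal distance of the lever-box center
#'   from the arena center for a trial to be analyzed; fixed at 0.75 x
#'   `arena_radius`.
#' @return An object of class `arena_geometry`.
#' @export
arena_geometry <- function(arena_radius = 40,
                           bridge_center = c(0, -45),
                           periphery_threshold = 3,
                           lever_proximity_threshold = 10,
                           lever_frame_radius = 12,
                           lever_center_max_radius = 0.75 * arena_radius) {
  stopifnot(arena_radius > 0)
  if (sqrt(sum(bridge_center^2)) <= arena_radius || bridge_center[2] >= 0)
    stop("bridge_center must lie outside the arena circle on the negative-y side")
  if (!(0 < periphery_threshold &&
        periphery_threshold < lever_proximity_threshold &&
        lever_proximity_threshold < lever_frame_radius &&
        lever_frame_radius < arena_radius))
    stop("thresholds must satisfy 0 < periphery < lever proximity < lever frame < arena radius")
  structure(list(
    arena_center = c(0, 0),
    arena_radius = arena_radius,
    bridge_center = as.numeric(bridge_center),
    periphery_threshold = periphery_threshold,
    lever_proximity_threshold = lever_proximity_threshold,
    lever_frame_radius = lever_frame_radius,
    lever_center_max_radius = lever_center_max_radius
  ), class = "arena_geometry")
}

# Rotate 2D points counterclockwise by `deg` degrees about the origin.
rotate_xy <- function(x, y, deg) {
  a <- deg2rad(deg)
  list(x = cos(a) * x - sin(a) * y, y = sin(a) * x + cos(a) * y)
}

# Angle of vectors (x, y) measured counterclockwise from south (0,-1),
# in degrees in [-180, 180). A point straight south of the origin is 0.
angle_from_south <- function(x, y) {
  wrap180(rad2deg(atan2(y, x)) + 90)
}

#' Distance to the lever-box wall
#'
#' Distance from head positions to the nearest point of the lever-box
#' rectangle (11.6 x 8.2 cm footprint), oriented so that its long axis is
#' perpendicular to the lever direction. Points inside the footprint get
#' distance 0.
#'
#' @param x,y Positions in cm (canonical frame).
#' @param lever_center Lever-box center (x, y) in cm.
#' @param lever_direction Unit vector from the box center toward the
#'   pressable lever.
#' @return Numeric vector of distances in cm.
#' @export
lever_wall_distance <- function(x, y, lever_center, lever_direction) {
  dx <- x - lever_center[1]
  dy <- y - lever_center[2]
  # u: along lever direction (short half-extent), v: across (long half-extent)
  u <- dx * lever_direction[1] + dy * lever_direction[2]
  v <- -dx * lever_direction[2] + dy * lever_direction[1]
  du <- pmax(abs(u) - LEVER_BOX_SHORT / 2, 0)
  dv <- pmax(abs(v) - LEVER_BOX_LONG / 2, 0)
  sqrt(du^2 + dv^2)
}
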