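#' World configuration for the perceptual-crossing environment
#'
#' Describes the invisible one-dimensional circular space in which the two
#' players interact. Positions live on a torus of circumference
#' \code{space_length}; every object (avatar, shadow, static lure) is an
#' interval of \code{object_length} units anchored at its left edge. A
#' "shadow" object is rigidly attached to each avatar at
#' \code{shadow_offset} units (in the direction of \code{shadow_sign}), so it
#' replays the avatar's trajectory displaced along the circle. Two static
#' objects, one per player, complete the set of three objects each player can
#' encounter.
#'
#' @param space_length circumference of the circular space, in units.
#' @param object_length length of every object, in units.
#' @param shadow_offset distance between an avatar and its shadow, in units.
#' @param shadow_sign direction of the shadow offset, \code{+1} or \code{-1}.
#' @param trial_duration duration of one trial, in seconds.
#' @param tick simulation time step, in seconds.
#' @param static_positions numeric length-2: positions of the static object
#'   felt by player 1 and player 2, respectively.
#' @return an object of class \code{pc_world}.
#' @export
world_config <- function(space_length = 600, object_length = 4,
                         shadow_offset = 150, shadow_sign = 1,
                         trial_duration = 60, tick = 0.01,
                         static_positions = c(100, 400)) {
  if (space_length <= 0)
    stop("invalid configuration: space_length must be > 0")
  if (object_length <= 0 || object_length >= space_length)
    stop("invalid configuration: need 0 < object_length < space_length")
  if (shadow_offset < 0 || shadow_offset >= space_length)
    stop("invalid configuration: need 0 <= shadow_offset < space_length")
  if (!shadow_sign %in% c(-1, 1))
    stop("invalid configuration: shadow_sign must be +1 or -1")
  if (trial_duration <= 0)
    stop("invalid configuration: trial_duration must be > 0")
  if (tick <= 0 || tick > trial_duration)
    stop("invalid configuration: need 0 < tick <= trial_duration")
  if (length(static_positions) != 2 ||
      any(static_positions < 0 | static_positions >= space_length))
    stop("invalid configuration: static_positions must be 2 values in [0, space_length)")
  structure(list(space_length = space_length, object_length = object_length,
                 shadow_offset = shadow_offset, shadow_sign = shadow_sign,
                 trial_duration = trial_duration, tick = tick,
                 static_positions = as.numeric(static_positions)),
            class = "pc_world")
}

#' @export
print.pc_world <- function(x, ...) {
  cat("<pc_world> circular space of", x$space_length, "units;",
      "objects", x$object_length, "units long;",
      "shadow offset", x$shadow_sign * x$shadow_offset, "units;",
      "trials", x$trial_duration, "s at tick", x$tick, "s\n")
  invisible(x)
}

#' Object categories a click can be assigned to
#'
#' The three objects a player can feel, plus \code{"unknown"} for clicks that
#' cannot be attributed to any object. \code{"unknown"} is a classification
#' outcome only; it never labels a simulated object.
#' @export
object_kinds <- function() c("other_avatar", "shadow", "static", "unknown")

wrap_pos <- function(x, L) {
  y <- x %% L
  # guard against -1e-17 %% L == L on some platforms
  y[y >= L] <- y[y >= L] - L
  y
}

#' Shortest distance between two points on the circle
#'
#' @param x,y positions in \code{[0, L)}, in units. Vectorised.
#' @param L circumference of the space.
#' @return the arc distance \code{min(|x - y|, L - |x - y|)}, in
#'   \code{[0, L/2]}.
#' @export
torus_distance <- function(x, y, L) {
  if (L <= 0) stop("invalid configuration: L must be > 0")
  d <- abs(x - y) %% L
  pmin(d, L - d)
}

#' Position of the shadow attached to an avatar
#'
#' @param avatar avatar position in \code{[0, space_length)}. Vectorised.
#' @param cfg a \code{\link{world_config}}.
#' @return shadow anchor position, in \code{[0, space_length)}.
#' @export
shadow_position <- function(avatar, cfg = world_config()) {
  wrap_pos(avatar + cfg$shadow_sign * cfg$shadow_offset, cfg$space_length)
}

#' Do two objects overlap on the torus?
#'
#' Objects are half-open intervals \code{[x, x + object_length)}; two objects
#' overlap iff the intervals intersect on the circle. Touching edges (gap
#' exactly one object length) do not count as contact.
#'
#' @param x1,x2 anchor positions in \code{[0, space_length)}. Vectorised.
#' @param cfg a \code{\link{world_config}}.
#' @return logical.
#' @export
objects_overlap <- function(x1, x2, cfg = world_config()) {
  L <- cfg$space_length
  len <- cfg$object_length
  ((x2 - x1) %% L) < len | ((x1 - x2) %% L) < len
}

# Sensor of one player given full object geometry: on iff the player's avatar
# overlaps the partner's avatar, the partner's shadow, or the player's own
# static object.
sensor_state <- function(own_avatar, partner_avatar, own_static, cfg) {
  objects_overlap(own_avatar, partner_avatar, cfg) |
    objects_overlap(own_avatar, shadow_position(partner_avatar, cfg), cfg) |
    objects_overlap(own_avatar, own_static, cfg)
}
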