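# Object trajectories and their projection onto the P-unit array.
#
# All stimuli are rigid rectangles on a flat angular map, sampled once per
# simulated millisecond. Distances are in mm, speeds in m/s (= mm/ms), angles
# in degrees. The projection treats azimuth and elevation independently
# (azimuth = atan(lateral/distance), elevation = atan(vertical/distance)),
# matching the planar small-angle treatment used for the unit array.

.new_trajectory <- function(type, half_width, half_height, speed, duration,
                            distance, lateral, extra = list()) {
  if (any(distance <= 0))
    stop("invalid stimulus: object distance reaches zero within the duration",
         call. = FALSE)
  structure(
    c(list(
      type = type,
      half_width_mm = half_width,
      half_height_mm = half_height,
      speed_m_s = speed,
      dt_ms = 1,
      duration_ms = duration,
      time_ms = seq_len(duration),
      distance_mm = distance,
      lateral_mm = lateral
    ), extra),
    class = "object_trajectory"
  )
}

#' Angular subtense of an object
#'
#' Visual angle spanned by an object of half-size `half_size` at `distance`:
#' `2 * atan(half_size / distance)`, in degrees.
#'
#' @param half_size_mm half of the object's extent, mm.
#' @param distance_mm viewing distance, mm (must be positive).
#' @return Angle in degrees.
#' @examples
#' angular_subtense(37.5, 37.5)  # 90 degrees
#' @export
angular_subtense <- function(half_size_mm, distance_mm) {
  if (any(distance_mm <= 0))
    stop("`distance_mm` must be positive", call. = FALSE)
  2 * atan(half_size_mm / distance_mm) * 180 / pi
}

#' Loom kinematic constant l/v
#'
#' Ratio of object half-size to approach speed, the constant that
#' parameterizes a loom. With the half-size in mm and the speed in m/s
#' (= mm/ms) the ratio comes out in milliseconds.
#'
#' @param diameter_mm object diameter (full size), mm.
#' @param speed_m_s approach speed, m/s.
#' @return l/v in ms.
#' @examples
#' l_over_v(75, 10)  # 3.75 ms
#' @export
l_over_v <- function(diameter_mm, speed_m_s) {
  if (speed_m_s <= 0)
    stop("`speed_m_s` must be positive", call. = FALSE)
  if (diameter_mm < 0)
    stop("`diameter_mm` must be non-negative", call. = FALSE)
  (diameter_mm / 2) / speed_m_s
}

#' Looming-object trajectory
#'
#' A square of side `side` mm approaches head-on at constant `speed`, starting
#' `start_distance` mm away and travelling `travel` mm, so the simulated
#' duration is `travel / speed` ms. Distance at time t is
#' `start_distance - speed * t`.
#'
#' @param side square side, mm.
#' @param speed approach speed, m/s.
#' @param start_distance starting distance, mm.
#' @param travel distance travelled, mm (must be less than `start_distance`).
#' @return An `object_trajectory`.
#' @examples
#' make_loom(75, 10, 500, 400)  # the 40 ms reference loom
#' @export
make_loom <- function(side = 75, speed = 10, start_distance = 500,
                      travel = 400) {
  if (speed <= 0) stop("`speed` must be positive", call. = FALSE)
  if (side <= 0) stop("`side` must be positive", call. = FALSE)
  if (travel <= 0 || travel >= start_distance)
    stop("`travel` must be positive and smaller than `start_distance`",
         call. = FALSE)
  duration <- as.integer(round(travel / speed))
  t <- seq_len(duration)
  .new_trajectory("loom", side / 2, side / 2, speed, duration,
                  distance = start_distance - speed * t,
                  lateral = rep(0, duration))
}

#' Near-miss trajectory
#'
#' Same radial kinematics as [make_loom()] but the object centre is displaced
#' laterally by a constant `lateral_offset`, so the image drifts off-axis as
#' the distance shrinks. A zero offset reduces exactly to the loom.
#'
#' @inheritParams make_loom
#' @param lateral_offset constant lateral displacement of the object centre,
#'   mm (sign gives the side).
#' @return An `object_trajectory`.
#' @export
make_near_miss <- function(side = 75, speed = 10, start_distance = 500,
                           travel = 400, lateral_offset = 100) {
  traj <- make_loom(side, speed, start_distance, travel)
  traj$type <- "near_miss"
  traj$lateral_mm <- rep(lateral_offset, traj$duration_ms)
  traj
}

#' Translating-object trajectory
#'
#' A `width` x `height` mm rectangle (width along the direction of motion,
#' height vertical) moves laterally at constant `speed` and constant
#' `distance`, crossing the field centre at `duration / 2`.
#'
#' @param width extent along the direction of motion, mm.
#' @param height vertical extent, mm.
#' @param distance constant viewing distance, mm.
#' @param speed lateral speed, m/s.
#' @param duration motion duration, ms.
#' @return An `object_trajectory`.
#' @examples
#' make_translation(70, 20, 100, 0.8, 90)  # the 90 ms reference translation
#' @export
make_translation <- function(width = 70, height = 20, distance = 100,
                             speed = 0.8, duration = 90) {
  if (any(c(width, height, distance, duration) <= 0) || speed < 0)
    stop("translation parameters must be positive (speed may be zero)",
         call. = FALSE)
  duration <- as.integer(round(duration))
  t <- seq_len(duration)
  offset_start <- -speed * duration / 2
  .new_trajectory("translation", width / 2, height / 2, speed, duration,
                  distance = rep(distance, duration),
                  lateral = offset_start + speed * t)
}

#' @export
print.object_trajectory <- function(x, ...) {
  cat(sprintf(
    "<object_trajectory> %s: %g x %g mm, %g m/s, %d ms (distance %g..%g mm)\n",
    x$type, 2 * x$half_width_mm, 2 * x$half_height_mm, x$speed_m_s,
    x$duration_ms, x$distance_mm[1], x$distance_mm[x$duration_ms]
  ))
  invisible(x)
}

# rectangle silhouette in angular coordinates at frame t (degrees, 4 corners)
.silhouette_polygon <- function(traj, t) {
  d <- traj$distance_mm[t]
  xc <- traj$lateral_mm[t]
  az <- atan(c(xc - traj$half_width_mm, xc + traj$half_width_mm) / d) * 180 / pi
  el <- atan(c(-traj$half_height_mm, traj$half_height_mm) / d) * 180 / pi
  cbind(
    azimuth_deg = c(az[1], az[2], az[2], az[1]),
    elevation_deg = c(el[1], el[1], el[2], el[2])
  )
}

#' Render a trajectory as a stimulus movie
#'
#' Projects the object silhouette onto the array once per millisecond and
#' rasterizes it, producing one binary coverage frame per ms plus per-frame
#' angular-subtense metadata (the vertical subtense,
#' `2 atan(half_height / distance)`).
#'
#' @param trajectory an `object_trajectory`.
#' @param array a [hex_array()].
#' @param coverage_rule passed to [rasterize()].
#' @return An object of class `stimulus_movie`: list with `frames` (units x
#'   time 0/1 matrix), `time_ms`, `subtense_deg`, `trajectory`, `array`.
#' @export
render_stimulus <- function(trajectory, array,
                            coverage_rule = c("centre", "fraction")) {
  stopifnot(inherits(trajectory, "object_trajectory"),
            inherits(array, "hex_array"))
  coverage_rule <- match.arg(coverage_rule)
  T <- trajectory$duration_ms
  frames <- matrix(0L, nrow(array), T)
  for (t in seq_len(T)) {
    frames[, t] <- rasterize(array, .silhouette_polygon(trajectory, t),
                             coverage_rule)
  }
  structure(
    list(
      frames = frames,
      time_ms = trajectory$time_ms,
      subtense_deg = angular_subtense(trajectory$half_height_mm,
                                      trajectory$distance_mm),
      trajectory = trajectory,
      array = array,
      coverage_rule = coverage_rule
    ),
    class = "stimulus_movie"
  )
}

#' @export
print.stimulus_movie <- function(x, ...) {
  cat(sprintf(
    "<stimulus_movie> %s, %d frames x %d units, subtense %.1f..%.1f deg\n",
    x$trajectory$type, ncol(x$frames), nrow(x$frames),
    x$subtense_deg[1], x$subtense_deg[length(x$subtense_deg)]
  ))
  invisible(x)
}

#' Per-frame movie summary
#'
#' @param movie a `stimulus_movie`.
#' @return Data frame with `time_ms`, `subtense_deg`, `covered_units`.
#' @export
movie_summary <- function(movie) {
  stopifnot(inherits(movie, "stimulus_movie"))
  data.frame(
    time_ms = movie$time_ms,
    subtense_deg = movie$subtense_deg,
    covered_units = colSums(movie$frames)
  )
}

#' Export a movie as delimited text
#'
#' Long format: one row per (frame, unit) with the binary coverage value.
#'
#' @param movie a `stimulus_movie`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "stimulus_movie"))
  long <- data.frame(
    time_ms = rep(movie$time_ms, each = nrow(movie$frames)),
    unit_id = rep(seq_len(nrow(movie$frames)), ncol(movie$frames)),
    coverage = as.integer(movie$frames)
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
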