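#' Arena configuration
#'
#' Geometry of the square experimental arena and its feeder sites. Two
#' layouts are supported: an X-shaped layout with a central site and four
#' outer sites on the square's diagonals (used by the random and
#' blocked-trial tasks), and a pentagonal layout with five outer sites and
#' no center (all-to-all task). Units are millimeters; the world origin is
#' the arena center with z pointing up and the floor at z = 0.
#'
#' @param layout "x_shape" or "pentagon".
#' @param arena_side side of the open central square, mm.
#' @param outer_radius distance from the arena center to each outer site, mm.
#' @return an object of class `arena_config` with elements `layout`,
#'   `arena_side`, `site_positions` (matrix n_sites x 2, mm),
#'   `n_outer_sites`, `outer_sites` (indices), and `center_site_index`
#'   (`NA` for pentagon).
#' @examples
#' arena <- arena_config()
#' arena$site_positions
#' @export
arena_config <- function(layout = c("x_shape", "pentagon"),
                         arena_side = 610,
                         outer_radius = if (match.arg(layout) == "x_shape") 340 else 280) {
  layout <- match.arg(layout)
  stopifnot(arena_side > 0, outer_radius > 0, outer_radius < arena_side)
  if (layout == "x_shape") {
    ang <- deg2rad(c(45, 135, 225, 315))
    sites <- rbind(outer_radius * cbind(cos(ang), sin(ang)), c(0, 0))
    outer <- 1:4
    center <- 5L
  } else {
    ang <- deg2rad(90 + 72 * (0:4))
    sites <- outer_radius * cbind(cos(ang), sin(ang))
    outer <- 1:5
    center <- NA_integer_
  }
  structure(list(layout = layout, arena_side = arena_side,
                 site_positions = sites, n_outer_sites = length(outer),
                 outer_sites = outer, center_site_index = center),
            class = "arena_config")
}

#' Behavioral generator configuration
#'
#' Parameters of the synthetic head-movement generator. Saccade durations
#' are drawn from a truncated normal; intervals between successive saccade
#' peaks are drawn from a gamma distribution calibrated so that the
#' *reciprocal* interval (the instantaneous saccade rate) has the configured
#' mean and standard deviation.
#'
#' @param sample_rate head-tracking rate, Hz (>= 100).
#' @param saccade_duration_mean,saccade_duration_sd saccade duration, s.
#' @param saccade_rate_mean,saccade_rate_sd instantaneous saccade rate
#'   (1 / inter-saccade interval), Hz.
#' @param fixation_jitter_sd angular jitter of head orientation during
#'   fixations, degrees.
#' @param eye_in_head_mad typical spread of eye-in-head angles, degrees
#'   (informational; the generator emits fixed eye axes).
#' @param inter_eye_angle angle between the two optical axes, degrees.
#' @param gaze_down_offset downward rotation of gaze below the optical
#'   axis, degrees.
#' @param head_height_mean,head_height_sd vertical head position while
#'   perched, mm.
#' @param dash_speed peak linear speed of dashes between sites, mm/s.
#' @param min_saccade_amplitude smallest scanning-saccade amplitude, deg.
#' @param main_sequence_slope slope of peak angular speed against
#'   amplitude, (deg/s)/deg; with the raised-cosine velocity profile this
#'   equals 2 / duration, so the default is tied to
#'   `saccade_duration_mean`.
#' @param rng_seed session seed.
#' @return an object of class `behavior_config`.
#' @export
behavior_config <- function(sample_rate = 300,
                            saccade_duration_mean = 0.076,
                            saccade_duration_sd = 0.021,
                            saccade_rate_mean = 3.8,
                            saccade_rate_sd = 1.4,
                            fixation_jitter_sd = 1,
                            eye_in_head_mad = 5.4,
                            inter_eye_angle = 106,
                            gaze_down_offset = 5,
                            head_height_mean = 54,
                            head_height_sd = 6,
                            dash_speed = 1100,
                            min_saccade_amplitude = 15,
                            main_sequence_slope = 2 / saccade_duration_mean,
                            rng_seed = 1L) {
  stopifnot(sample_rate >= 100,
            saccade_duration_mean > 0, saccade_duration_sd > 0,
            saccade_rate_mean > 0, saccade_rate_sd > 0,
            dash_speed > 0, head_height_mean > 0)
  structure(as.list(environment()), class = "behavior_config")
}

#' Closed-loop task configuration
#'
#' Rules of the gaze-triggered light cue. The target light turns on when an
#' eligible eye's angular deviation to the current target stays below
#' `gaze_trigger_threshold` for at least `gaze_trigger_min_samples`
#' consecutive samples; the light change is applied after
#' `trigger_latency_median`. In the blocked variant the target repeats for
#' `block_length` trials and `catch_per_block` of the within-block positions
#' 2..block_length are catch trials, on which the first gaze detection
#' yields no light.
#'
#' @param variant "random", "blocked" or "all_to_all".
#' @param gaze_trigger_threshold trigger threshold, degrees (in [10, 20]).
#' @param gaze_trigger_min_samples consecutive samples required.
#' @param trigger_latency_median latency from detection to light change, s.
#' @param block_length trials per block (blocked variant).
#' @param catch_per_block catch trials per block (must be < block_length).
#' @param reward_probability probability the feeder opens on a correct
#'   visit.
#' @param eligible_eyes "both" or "contra_only".
#' @return an object of class `task_config`.
#' @export
task_config <- function(variant = c("random", "blocked", "all_to_all"),
                        gaze_trigger_threshold = 15,
                        gaze_trigger_min_samples = 3L,
                        trigger_latency_median = 0.040,
                        block_length = 6L,
                        catch_per_block = 2L,
                        reward_probability = 0.75,
                        eligible_eyes = c("both", "contra_only")) {
  variant <- match.arg(variant)
  eligible_eyes <- match.arg(eligible_eyes)
  stopifnot(gaze_trigger_threshold >= 10, gaze_trigger_threshold <= 20,
            gaze_trigger_min_samples >= 1,
            catch_per_block < block_length,
            reward_probability > 0, reward_probability <= 1)
  structure(as.list(environment()), class = "task_config")
}

#' Per-bird eye calibration
#'
#' Eye positions and optical axes in the head-centered frame (x through the
#' eyes, right positive; y through the beak; z up; origin at the eye
#' midpoint). Optical axes point laterally, symmetric about the beak by
#' half the inter-eye angle, and gaze is taken `gaze_down_offset` degrees
#' below the optical axis (rotated about the head x axis).
#'
#' @param inter_eye_angle angle between the two optical axes, degrees.
#' @param eye_separation distance between the eyes, mm.
#' @param gaze_down_offset downward gaze offset, degrees.
#' @return an object of class `eye_calibration` with per-eye positions and
#'   unit optical axes (rows "left", "right").
#' @export
eye_calibration <- function(inter_eye_angle = 106, eye_separation = 12,
                            gaze_down_offset = 5) {
  stopifnot(inter_eye_angle > 0, inter_eye_angle < 180, eye_separation > 0)
  half <- deg2rad(inter_eye_angle / 2)
  # azimuth measured from the beak (+y); left eye toward -x, right toward +x
  axes <- rbind(left  = c(-sin(half), cos(half), 0),
                right = c(sin(half), cos(half), 0))
  pos <- rbind(left = c(-eye_separation / 2, 0, 0),
               right = c(eye_separation / 2, 0, 0))
  structure(list(eye_position_in_head = pos, optical_axis_in_head = axes,
                 inter_eye_angle = inter_eye_angle,
                 gaze_down_offset = gaze_down_offset),
            class = "eye_calibration")
}

#' Read or write configuration files
#'
#' Configurations are serialized as flat YAML. Matrices are stored as
#' nested lists and restored on read.
#'
#' @param cfg a config object (`arena_config`, `behavior_config`,
#'   `task_config` or `eye_calibration`).
#' @param path file path.
#' @return `read_config` returns the restored object; `write_config` the
#'   path, invisibly.
#' @export
write_config <- function(cfg, path) {
  lst <- lapply(unclass(cfg), function(x) {
    if (is.matrix(x)) {
      rows <- lapply(seq_len(nrow(x)), function(i) as.numeric(x[i, ]))
      names(rows) <- rownames(x)
      list(.matrix_rows = rows)
    } else x
  })
  lst$.class <- class(cfg)[1]
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- lst$.class
  lst$.class <- NULL
  lst <- lapply(lst, function(x) {
    if (is.list(x) && identical(names(x), ".matrix_rows")) {
      rows <- x$.matrix_rows
      m <- do.call(rbind, lapply(rows, as.numeric))
      rownames(m) <- names(rows)
      m
    } else x
  })
  structure(lst, class = cls)
}
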