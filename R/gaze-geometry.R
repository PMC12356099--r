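#' Head reference frame from facial landmarks
#'
#' Builds the head-centered frame used throughout: origin at the midpoint
#' of the two eyes, x axis through the eyes (right positive), y axis from
#' the origin through the beak tip (beak positive, orthogonalized against
#' x), z axis up, completing a right-handed orthonormal basis.
#'
#' @param left_eye,right_eye,beak_tip length-3 landmark positions (mm).
#' @return list with `origin` (length 3) and `axes` (3 x 3 matrix, columns
#'   x, y, z in world coordinates) and `quaternion` (1 x 4).
#' @export
head_frame_from_landmarks <- function(left_eye, right_eye, beak_tip) {
  origin <- (left_eye + right_eye) / 2
  x <- right_eye - left_eye
  nx <- sqrt(sum(x^2))
  b <- beak_tip - origin
  if (nx == 0 || sum(b^2) == 0)
    stop("degenerate geometry: coincident landmarks")
  x <- x / nx
  y <- b - sum(b * x) * x
  ny <- sqrt(sum(y^2))
  if (ny < 1e-9 * sqrt(sum(b^2)) || ny == 0)
    stop("degenerate geometry: collinear landmarks")
  y <- y / ny
  z <- c(cross3(matrix(x, ncol = 3), matrix(y, ncol = 3)))
  R <- cbind(x = x, y = y, z = z)
  list(origin = origin, axes = R, quaternion = quat_from_matrix(R))
}

#' Gaze rays in the world frame
#'
#' Applies a head pose to the calibrated per-eye positions and optical
#' axes, then pitches each axis downward about the head x axis by the
#' calibration's `gaze_down_offset` to obtain the gaze direction.
#'
#' @param position head positions, n x 3 mm (eye-midpoint origin).
#' @param orientation unit quaternions, n x 4.
#' @param calib an [eye_calibration()].
#' @param tol tolerance on quaternion unit norm.
#' @return list with per-eye elements `left`, `right`, each a list of
#'   `origin` (n x 3) and `direction` (n x 3 unit vectors).
#' @export
gaze_rays <- function(position, orientation, calib = eye_calibration(),
                      tol = 1e-6) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3L)
  orientation <- quat_mat(orientation)
  nrm <- abs(sqrt(rowSums(orientation^2)) - 1)
  if (any(nrm > tol)) stop("orientation quaternions are not unit-norm")
  down <- quat_from_axis_angle(c(1, 0, 0), -deg2rad(calib$gaze_down_offset))
  out <- lapply(c(left = "left", right = "right"), function(eye) {
    axis_head <- quat_rotate(down, calib$optical_axis_in_head[eye, ])
    list(origin = position +
           quat_rotate(orientation, calib$eye_position_in_head[eye, ]),
         direction = quat_rotate(orientation, axis_head))
  })
  out
}

site_positions_3d <- function(arena, site_height = 0) {
  cbind(arena$site_positions, site_height)
}

#' Angular deviation of gaze from each site
#'
#' For every sample and eye, the angle between the gaze direction and the
#' unit vector from the eye to each site center. An eye coincident with a
#' site center has deviation 0 by convention.
#'
#' @param rays output of [gaze_rays()].
#' @param arena an [arena_config()].
#' @param site_height height of site centers above the floor, mm.
#' @return list with elements `left` and `right`, each an n x n_sites
#'   matrix of angles in degrees.
#' @export
angular_distances_to_sites <- function(rays, arena, site_height = 0) {
  sites <- site_positions_3d(arena, site_height)
  lapply(rays, function(ray) {
    n <- nrow(ray$origin)
    out <- matrix(0, n, nrow(sites))
    for (k in seq_len(nrow(sites))) {
      tosite <- sweep(-ray$origin, 2, -sites[k, ])
      out[, k] <- angle_between_deg(ray$direction, tosite)
    }
    colnames(out) <- paste0("site", seq_len(nrow(sites)))
    out
  })
}

#' Frontal vs lateral gaze strategy around dashes
#'
#' For each dash and each of the `n_back` saccade-end fixations preceding
#' it (index 0 = the last fixation before the dash), tests whether the
#' frontal (beak) vector or either eye's lateral (gaze) vector points
#' within `hit_threshold` degrees of the upcoming dash target, and reports
#' hit probabilities with binomial standard errors per saccade index.
#'
#' @param segments a segment table (see [refine_segments()]).
#' @param trace a behavior trace (list with `t`, `position`,
#'   `orientation`).
#' @param arena an [arena_config()].
#' @param calib an [eye_calibration()].
#' @param n_back how many pre-dash fixations to include.
#' @param hit_threshold hit criterion, degrees.
#' @return data.frame with columns `saccade_index` (0 = pre-dash, negative
#'   counting backwards), `frontal_prob`, `lateral_prob`, `frontal_se`,
#'   `lateral_se`, `n`.
#' @export
classify_gaze_strategy <- function(segments, trace, arena,
                                   calib = eye_calibration(),
                                   n_back = 6, hit_threshold = 20) {
  dashes <- segments[segments$state == "dash" & !is.na(segments$dst), ]
  saccs <- segments[segments$state == "saccade", ]
  if (nrow(dashes) == 0L)
    return(data.frame(saccade_index = integer(), frontal_prob = numeric(),
                      lateral_prob = numeric(), frontal_se = numeric(),
                      lateral_se = numeric(), n = integer()))
  sites <- site_positions_3d(arena)
  hits <- list()
  for (d in seq_len(nrow(dashes))) {
    target <- dashes$dst[d]
    prior <- saccs[saccs$t_end <= dashes$t_start[d], ]
    if (nrow(prior) == 0L) next
    prior <- prior[order(prior$t_end, decreasing = TRUE), ]
    m <- min(n_back, nrow(prior))
    for (j in seq_len(m)) {
      # sample the fixation shortly after the saccade end
      i <- findInterval(prior$t_end[j] + 0.02, trace$t)
      i <- min(max(i, 1L), length(trace$t))
      q <- trace$orientation[i, , drop = FALSE]
      pos <- trace$position[i, ]
      tosite <- sites[target, ] - pos
      frontal <- quat_rotate(q, c(0, 1, 0))
      left <- quat_rotate(q, calib$optical_axis_in_head["left", ])
      right <- quat_rotate(q, calib$optical_axis_in_head["right", ])
      hits[[length(hits) + 1L]] <- data.frame(
        saccade_index = -(j - 1L),
        frontal = angle_between_deg(frontal, tosite) < hit_threshold,
        lateral = min(angle_between_deg(left, tosite),
                      angle_between_deg(right, tosite)) < hit_threshold)
    }
  }
  h <- do.call(rbind, hits)
  out <- do.call(rbind, lapply(split(h, h$saccade_index), function(g) {
    n <- nrow(g)
    pf <- mean(g$frontal); pl <- mean(g$lateral)
    data.frame(saccade_index = g$saccade_index[1],
               frontal_prob = pf, lateral_prob = pl,
               frontal_se = sqrt(pf * (1 - pf) / n),
               lateral_se = sqrt(pl * (1 - pl) / n), n = n)
  }))
  out[order(out$saccade_index), , drop = FALSE]
}

#' Project a gaze cone onto the arena floor
#'
#' Returns the occupancy weight each floor bin receives from a cone of
#' half-angle `cone_radius` around the gaze direction: bins whose center
#' direction from the eye lies within the cone get equal shares of unit
#' weight. The grid is the same 40 x 40 partition of the arena used by
#' rate maps. A cone that misses the floor yields an all-zero matrix.
#'
#' @param origin eye position, length 3 (mm, z above floor).
#' @param direction gaze direction, length 3.
#' @param cone_radius cone half-angle, degrees.
#' @param arena an [arena_config()].
#' @param n_bins grid size per side.
#' @return n_bins x n_bins weight matrix summing to 1 (or 0).
#' @export
project_gaze_to_floor <- function(origin, direction, cone_radius, arena,
                                  n_bins = 40) {
  half <- arena$arena_side / 2
  edges <- seq(-half, half, length.out = n_bins + 1)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  cx <- matrix(ctr, n_bins, n_bins)
  cy <- matrix(ctr, n_bins, n_bins, byrow = TRUE)
  w <- matrix(0, n_bins, n_bins)
  dirs <- cbind(c(cx) - origin[1], c(cy) - origin[2], -origin[3])
  ang <- angle_between_deg(dirs, direction)
  if (cone_radius <= 0) {
    # exact ray-floor intersection
    if (direction[3] >= 0) return(w)
    s <- -origin[3] / direction[3]
    px <- origin[1] + s * direction[1]
    py <- origin[2] + s * direction[2]
    ix <- findInterval(px, edges, rightmost.closed = TRUE)
    iy <- findInterval(py, edges, rightmost.closed = TRUE)
    if (ix >= 1 && ix <= n_bins && iy >= 1 && iy <= n_bins) w[ix, iy] <- 1
    return(w)
  }
  inside <- ang <= cone_radius
  if (!any(inside)) return(w)
  w[inside] <- 1 / sum(inside)
  w
}
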