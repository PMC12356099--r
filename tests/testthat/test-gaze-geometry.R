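test_that("head frame from landmarks gives the canonical axis-aligned frame", {
  f <- head_frame_from_landmarks(c(-5, 0, 0), c(5, 0, 0), c(0, 10, 0))
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(unname(f$axes), diag(3), tolerance = 1e-12)
})

test_that("head frame rotates with rigidly rotated landmarks", {
  set.seed(1)
  for (rep in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    q <- quat_from_axis_angle(ax, runif(1, -pi, pi))
    le <- c(quat_rotate(q, c(-5, 0, 0)))
    re <- c(quat_rotate(q, c(5, 0, 0)))
    bk <- c(quat_rotate(q, c(0, 10, 0)))
    f <- head_frame_from_landmarks(le, re, bk)
    # frame axes equal the rotated canonical axes
    expect_equal(unname(f$axes), t(rbind(quat_rotate(q, c(1, 0, 0)),
                                         quat_rotate(q, c(0, 1, 0)),
                                         quat_rotate(q, c(0, 0, 1)))),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # right-handed orthonormal
    expect_equal(crossprod(f$axes), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_gt(det(f$axes), 0)
  }
})

test_that("collinear landmarks raise a degenerate-geometry error", {
  expect_error(head_frame_from_landmarks(c(-5, 0, 0), c(5, 0, 0),
                                         c(10, 0, 0)), "collinear|degenerate")
})

test_that("gaze rays reproduce the calibration at identity pose", {
  calib0 <- eye_calibration(gaze_down_offset = 0)
  r <- gaze_rays(c(0, 0, 0), c(1, 0, 0, 0), calib0)
  expect_equal(r$left$direction[1, ],
               unname(calib0$optical_axis_in_head["left", ]),
               tolerance = 1e-12)
  expect_equal(r$right$origin[1, ],
               unname(calib0$eye_position_in_head["right", ]))
})

test_that("the downward offset pitches the gaze 5 degrees below the axis", {
  calib5 <- eye_calibration(gaze_down_offset = 5)
  calib0 <- eye_calibration(gaze_down_offset = 0)
  r5 <- gaze_rays(c(0, 0, 0), c(1, 0, 0, 0), calib5)
  r0 <- gaze_rays(c(0, 0, 0), c(1, 0, 0, 0), calib0)
  for (eye in c("left", "right")) {
    # a 5-degree rotation about the inter-eye axis moves a lateral eye
    # axis by 2 asin(sin(2.5 deg) sin(angle to x axis))
    sinphi <- abs(calib0$optical_axis_in_head[eye, 2])
    expected <- 2 * asin(sin(2.5 * pi / 180) * sinphi) * 180 / pi
    expect_equal(angle_between_deg(r5[[eye]]$direction[1, ],
                                   r0[[eye]]$direction[1, ]),
                 unname(expected), tolerance = 1e-6)
    expect_lt(r5[[eye]]$direction[1, 3], r0[[eye]]$direction[1, 3])
  }
})

test_that("a yawed pose yaws the rays and permutes site angles", {
  arena <- arena_config()
  calib <- eye_calibration(gaze_down_offset = 0)
  q0 <- c(1, 0, 0, 0)
  q90 <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  pos <- c(0, 0, 54)
  a0 <- angular_distances_to_sites(gaze_rays(pos, q0, calib), arena)
  a90 <- angular_distances_to_sites(gaze_rays(pos, q90, calib), arena)
  # sites are at 45, 135, 225, 315 degrees: a 90-degree yaw maps
  # site k's deviation onto site (k mod 4) + 1
  expect_equal(a90$left[1, c(2, 3, 4, 1)], a0$left[1, 1:4],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("angular distances hit the closed-form cases", {
  arena <- arena_config()
  sites3 <- cbind(arena$site_positions, 0)
  calib <- eye_calibration(gaze_down_offset = 0, eye_separation = 1e-9)
  # construct rays directly for full control
  ray_to <- function(dir) list(left = list(origin = matrix(c(0, 0, 0), 1),
                                           direction = matrix(dir / sqrt(sum(dir^2)), 1)),
                               right = list(origin = matrix(c(0, 0, 0), 1),
                                            direction = matrix(dir / sqrt(sum(dir^2)), 1)))
  d1 <- angular_distances_to_sites(ray_to(sites3[1, ]), arena)
  expect_equal(unname(d1$left[1, 1]), 0, tolerance = 1e-9)
  d2 <- angular_distances_to_sites(ray_to(-sites3[1, ]), arena)
  expect_equal(unname(d2$left[1, 1]), 180, tolerance = 1e-9)
  # 45-degree offset in the plane
  arena1 <- arena_config(arena_side = 3000, outer_radius = 1000)
  az <- pi / 4  # site 1 sits at azimuth 45 degrees
  dir45 <- c(cos(az + pi / 4), sin(az + pi / 4), 0)
  d3 <- angular_distances_to_sites(ray_to(dir45), arena1)
  expect_equal(unname(d3$left[1, 1]), 45, tolerance = 1e-9)
})

test_that("angular distances are rotation equivariant", {
  set.seed(2)
  arena <- arena_config()
  calib <- eye_calibration()
  pos <- c(10, -20, 54)
  q <- quat_normalize(matrix(rnorm(4), 1))
  base <- angular_distances_to_sites(gaze_rays(pos, q, calib), arena)
  for (rep in 1:5) {
    yaw <- runif(1, 0, 2 * pi)
    # rotating pose and sites together about z leaves angles unchanged
    qz <- quat_from_axis_angle(c(0, 0, 1), yaw)
    q2 <- quat_multiply(qz, q)
    pos2 <- c(quat_rotate(qz, pos))
    arena2 <- arena
    arena2$site_positions <- t(apply(arena$site_positions, 1, function(p)
      c(quat_rotate(qz, c(p, 0)))[1:2]))
    rot <- angular_distances_to_sites(gaze_rays(pos2, q2, calib), arena2)
    expect_equal(rot$left, base$left, tolerance = 1e-6)
    expect_equal(rot$right, base$right, tolerance = 1e-6)
  }
})

test_that("a downward gaze cone projects to the expected floor disc", {
  arena <- arena_config()
  h <- 200
  w <- project_gaze_to_floor(c(0, 0, h), c(0, 0, -1), 10, arena)
  expect_equal(sum(w), 1)
  half <- arena$arena_side / 2
  ctr <- seq(-half, half, length.out = 41)
  ctr <- (ctr[-1] + ctr[-41]) / 2
  hit <- which(w > 0, arr.ind = TRUE)
  d <- sqrt(ctr[hit[, 1]]^2 + ctr[hit[, 2]]^2)
  rad <- h * tan(10 * pi / 180)
  bin_diag <- sqrt(2) * (arena$arena_side / 40)
  expect_true(all(d <= rad + bin_diag))
  # every bin whose center is well inside the disc is hit
  inside <- which(outer(ctr^2, ctr^2, "+") <= (rad - bin_diag)^2,
                  arr.ind = TRUE)
  expect_true(all(w[inside] > 0))
})

test_that("degenerate cones behave as documented", {
  arena <- arena_config()
  # parallel to the floor, zero radius: empty
  w <- project_gaze_to_floor(c(0, 0, 100), c(1, 0, 0), 0, arena)
  expect_equal(sum(w), 0)
  # cone entirely above the floor: empty, not an error
  w2 <- project_gaze_to_floor(c(0, 0, 100), c(0, 0, 1), 10, arena)
  expect_equal(sum(w2), 0)
  # zero radius pointing at a floor point: exactly that bin
  w3 <- project_gaze_to_floor(c(0, 0, 100), c(100, 100, -100), 0, arena)
  expect_equal(sum(w3 > 0), 1)
  half <- arena$arena_side / 2
  edges <- seq(-half, half, length.out = 41)
  ib <- findInterval(100, edges)
  expect_equal(unname(which(w3 > 0, arr.ind = TRUE)[1, ]), c(ib, ib))
})

test_that("cone floor area grows monotonically with cone radius", {
  arena <- arena_config()
  areas <- vapply(c(2, 5, 10, 20), function(r)
    sum(project_gaze_to_floor(c(0, 0, 150), c(0.3, 0.1, -1), r, arena) > 0),
    0)
  expect_true(all(diff(areas) >= 0))
})

test_that("gaze strategy analysis recovers the programmed lateral-then-frontal structure", {
  fx <- fixture_session()
  gs <- classify_gaze_strategy(fx$segments, fx$session$trace,
                               fx$session$arena, fx$session$calib)
  expect_gt(nrow(gs), 2)
  at0 <- gs[gs$saccade_index == 0, ]
  at1 <- gs[gs$saccade_index == -1, ]
  # the last pre-dash fixation is frontal toward the dash target
  expect_gt(at0$frontal_prob, 0.8)
  expect_gt(at0$frontal_prob, at0$lateral_prob)
  # frontal hits peak at index 0; lateral hits peak earlier (the
  # gaze-trigger fixation is lateral at the target)
  expect_equal(gs$saccade_index[which.max(gs$frontal_prob)], 0)
  expect_lt(gs$saccade_index[which.max(gs$lateral_prob)], 0)
  expect_gt(at1$lateral_prob, at1$frontal_prob)
})
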