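#' Raised-cosine saccade kinematics
#'
#' Angular-velocity profile of a single head saccade: a raised-cosine
#' (Hann) pulse, smooth and unimodal, whose integral equals the requested
#' amplitude. With duration D the peak angular speed is 2 * amplitude / D,
#' so at fixed duration peak speed grows linearly with amplitude (the
#' main-sequence property). Duration, when not supplied, is drawn from the
#' configured truncated-normal distribution (lower bound 30 ms).
#'
#' @param amplitude total angular displacement, degrees (>= 0).
#' @param cfg a [behavior_config()].
#' @param duration optional fixed duration, s.
#' @return list with `t` (sample-time offsets from saccade start, s),
#'   `velocity` (deg/s), `displacement` (cumulative, deg), `duration` (s),
#'   `t_peak` (offset of peak speed, s).
#' @export
sample_saccade_kinematics <- function(amplitude, cfg = behavior_config(),
                                      duration = NULL) {
  if (amplitude < 0) stop("saccade amplitude must be non-negative")
  if (is.null(duration)) {
    duration <- rtruncnorm(1, cfg$saccade_duration_mean,
                           cfg$saccade_duration_sd, lo = 0.03)
  }
  dt <- 1 / cfg$sample_rate
  n <- max(2L, round(duration / dt))
  tt <- seq_len(n) * dt - dt / 2    # midpoint sampling of the pulse
  v <- (2 * amplitude / duration) * 0.5 * (1 - cos(2 * pi * tt / duration))
  v[tt > duration] <- 0
  disp <- cumsum(v) * dt
  # normalize discretization so displacement integrates exactly to amplitude
  if (amplitude > 0 && disp[n] > 0) {
    v <- v * amplitude / disp[n]
    disp <- disp * amplitude / disp[n]
  }
  list(t = tt, velocity = v, displacement = disp, duration = duration,
       t_peak = tt[which.max(v)])
}

rtruncnorm <- function(n, mean, sd, lo = -Inf) {
  p_lo <- stats::pnorm(lo, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, 1), mean, sd)
}

#' Gamma parameters for inter-saccade intervals
#'
#' Intervals between successive saccade peaks are gamma distributed with
#' shape and scale chosen so that the reciprocal interval (the
#' instantaneous saccade rate) has the configured mean and standard
#' deviation: for ISI ~ Gamma(k, theta), 1/ISI is inverse-gamma with mean
#' 1/(theta (k-1)) and sd mean/sqrt(k-2).
#'
#' @param cfg a [behavior_config()].
#' @return list with `shape` and `scale` (s).
#' @export
isi_gamma_params <- function(cfg = behavior_config()) {
  k <- 2 + (cfg$saccade_rate_mean / cfg$saccade_rate_sd)^2
  list(shape = k, scale = 1 / (cfg$saccade_rate_mean * (k - 1)))
}

#' Consecutive-run gaze detection
#'
#' Returns the sample index at which an eligible eye's angular deviation
#' to the target has stayed below `threshold` for at least `min_samples`
#' consecutive samples (the index of the `min_samples`-th sample of the
#' first such run), or `NA` if no run completes.
#'
#' @param deviation n x n_eyes matrix of angular deviations, degrees.
#' @param threshold trigger threshold, degrees.
#' @param min_samples required consecutive samples.
#' @return integer sample index or `NA_integer_`.
#' @export
detect_gaze_trigger <- function(deviation, threshold, min_samples = 3L) {
  if (is.null(dim(deviation))) deviation <- matrix(deviation, ncol = 1L)
  below <- deviation < threshold
  for (e in seq_len(ncol(below))) {
    run <- 0L
    for (i in seq_len(nrow(below))) {
      run <- if (below[i, e]) run + 1L else 0L
      if (run >= min_samples) {
        below[i, e] <- NA  # marker reuse below
        return(i)
      }
    }
  }
  NA_integer_
}

# -- internal helpers for the session generator ------------------------------

# orientation that exactly aims the given head-frame unit vector at `target`
# from `from`: the shortest-arc rotation taking the vector onto the target
# line, followed by a spin about that line that keeps the head as upright
# as possible (birds do not roll their heads to fixate)
aim_orientation <- function(head_vec, from, target) {
  b <- target - from
  b <- b / sqrt(sum(b^2))
  a <- head_vec / sqrt(sum(head_vec^2))
  ax <- c(cross3(matrix(a, ncol = 3), matrix(b, ncol = 3)))
  s <- sqrt(sum(ax^2))
  d <- sum(a * b)
  q0 <- if (s < 1e-12) {
    if (d > 0) matrix(c(1, 0, 0, 0), ncol = 4)
    else quat_from_axis_angle(c(0, 0, 1), pi)
  } else {
    quat_from_axis_angle(ax / s, atan2(s, d))
  }
  # spin about b to maximize head-z alignment with world up
  z0 <- c(quat_rotate(q0, c(0, 0, 1)))
  ez <- c(0, 0, 1)
  zperp <- z0 - sum(z0 * b) * b
  eperp <- ez - sum(ez * b) * b
  nz <- sqrt(sum(zperp^2)); ne <- sqrt(sum(eperp^2))
  if (nz > 1e-9 && ne > 1e-9) {
    zp <- zperp / nz; ep <- eperp / ne
    sang <- sum(cross3(matrix(zp, ncol = 3), matrix(ep, ncol = 3)) * b)
    cang <- sum(zp * ep)
    q0 <- quat_multiply(quat_from_axis_angle(b, atan2(sang, cang)), q0)
  }
  q0
}

# head-frame gaze vectors (down offset applied) used for aiming
gaze_axes_head <- function(calib) {
  down <- quat_from_axis_angle(c(1, 0, 0), -deg2rad(calib$gaze_down_offset))
  list(left = c(quat_rotate(down, calib$optical_axis_in_head["left", ])),
       right = c(quat_rotate(down, calib$optical_axis_in_head["right", ])),
       frontal = c(quat_rotate(down, c(0, 1, 0))))
}

small_rotation <- function(sd_deg) {
  ax <- stats::rnorm(3)
  quat_from_axis_angle(ax / sqrt(sum(ax^2)),
                       deg2rad(stats::rnorm(1, 0, sd_deg)))
}

# balanced pseudorandom target sequence for the random task
next_random_target <- function(counts, prev) {
  cand <- setdiff(seq_along(counts), prev)
  cand <- cand[counts[cand] == min(counts[cand])]
  if (length(cand) > 1L) cand <- sample(cand, 1L)
  cand
}

# all-to-all target sequence step: exclude three adjacent pentagon sites in
# a row (prev-cur adjacent and cur-cand adjacent)
next_all_to_all_target <- function(pair_counts, prev, cur) {
  adjacent <- function(a, b) min((a - b) %% 5, (b - a) %% 5) == 1
  cand <- setdiff(1:5, cur)
  if (!is.na(prev) && adjacent(prev, cur))
    cand <- cand[!vapply(cand, adjacent, logical(1), b = cur)]
  w <- pair_counts[cbind(cur, cand)]
  cand <- cand[w == min(w)]
  if (length(cand) > 1L) cand <- sample(cand, 1L)
  cand
}

# catch-trial positions for one block, drawn to keep session-wide position
# tallies within +/-1 (positions 2..block_length)
draw_catch_positions <- function(position_counts, n_catch) {
  pos <- as.integer(names(position_counts))
  chosen <- integer(0)
  for (i in seq_len(n_catch)) {
    avail <- setdiff(pos, chosen)
    cnt <- position_counts[as.character(avail)]
    lo <- avail[cnt == min(cnt)]
    pick <- if (length(lo) > 1L) sample(lo, 1L) else lo
    chosen <- c(chosen, pick)
  }
  sort(chosen)
}

#' Generate a ground-truthed synthetic session
#'
#' Simulates a bird performing the discrete visual-search task: bouts of
#' gaze fixations separated by ballistic head saccades while perched,
#' closed-loop gaze-triggered target lights, dashes between sites, and
#' feeding bouts. Head pose is emitted at the configured sample rate as
#' position (mm) plus a unit quaternion per sample, together with exact
#' per-sample state labels and per-saccade ground truth.
#'
#' During search, each fixation aims one eye (lateral gaze) or the beak
#' (frontal gaze) at a task site via the minimal head rotation; the last
#' fixation before a dash is frontal toward the dash target, earlier ones
#' lateral. The closed-loop controller monitors the generated gaze with
#' [detect_gaze_trigger()] and applies the catch-trial and latency rules of
#' the task variant.
#'
#' @param arena an [arena_config()] (pentagon required for `all_to_all`).
#' @param beh a [behavior_config()].
#' @param task a [task_config()].
#' @param duration session length, s.
#' @param rng_seed integer seed; identical seeds give identical sessions.
#' @return list of class `synthetic_session` with elements `trace`
#'   (list: `t`, `position` n x 3, `orientation` n x 4), `events` (list:
#'   `trials` data.frame, `light` per-sample logical), `labels` (list:
#'   `state` character per sample, `site`, `gaze_site`, `gaze_eye`,
#'   `saccades` data.frame with `t_start`, `t_peak`, `t_end`, `amplitude`,
#'   `duration`, `gaze_site`, `eye`, `frontal`), plus `arena`, `beh`,
#'   `task`, `calib`.
#' @export
generate_session <- function(arena = arena_config(),
                             beh = behavior_config(),
                             task = task_config(),
                             duration = 1800, rng_seed = beh$rng_seed) {
  if (duration <= 0) stop("duration must be positive")
  if (task$variant == "all_to_all" && arena$layout != "pentagon")
    stop("the all-to-all task requires the pentagon layout (no center site)")
  if (task$variant != "all_to_all" && arena$layout != "x_shape")
    stop("random and blocked tasks require the x_shape layout")
  set.seed(rng_seed)
  calib <- eye_calibration(inter_eye_angle = beh$inter_eye_angle,
                           gaze_down_offset = beh$gaze_down_offset)
  axes <- gaze_axes_head(calib)
  dt <- 1 / beh$sample_rate
  n_total <- round(duration * beh$sample_rate)
  isi <- isi_gamma_params(beh)
  sites3 <- site_positions_3d(arena)
  outer <- arena$outer_sites
  center <- arena$center_site_index

  head_height <- rtruncnorm(1, beh$head_height_mean, beh$head_height_sd,
                            lo = 20)
  perch_pos <- function(site) c(sites3[site, 1:2], head_height)

  # accumulators
  segs <- vector("list", 65536L); nseg <- 0L
  push <- function(seg) {
    nseg <<- nseg + 1L
    segs[[nseg]] <<- seg
  }
  sacc_rows <- list()
  trial_rows <- list()
  light_intervals <- list()

  t_now <- 0
  cur_site <- if (is.na(center)) 1L else center
  cur_q <- quat_yaw_pitch(stats::runif(1, 0, 2 * pi))
  cur_gaze_site <- NA_integer_
  cur_eye <- NA_character_

  # task bookkeeping
  target_counts <- numeric(length(outer))
  pair_counts <- if (arena$layout == "pentagon") matrix(0, 5, 5) else NULL
  prev_target <- NA_integer_
  prev_site <- NA_integer_   # site occupied before the current one
  block_pos_counts <- stats::setNames(numeric(task$block_length - 1L),
                                      2:task$block_length)
  block_target <- NA_integer_
  block_index <- 0L
  block_trial <- 0L
  block_catch <- integer(0)
  trial_no <- 0L

  emit_fixation <- function(dur_s, q, gaze_site, eye, site) {
    n <- max(1L, round(dur_s / dt))
    jit <- quat_multiply(small_rotation(beh$fixation_jitter_sd), q)
    qs <- jit[rep(1L, n), , drop = FALSE]
    # small per-sample orientation noise, well below saccade speeds
    if (n > 1L) {
      e <- deg2rad(stats::rnorm(n, 0, 0.05))
      qs <- quat_normalize(quat_multiply(cbind(cos(e / 2), 0, 0,
                                               sin(e / 2)), qs))
    }
    pos <- matrix(perch_pos(site), n, 3, byrow = TRUE)
    pos <- pos + matrix(stats::rnorm(3L * n, 0, 0.3), n, 3)
    list(n = n, state = "fixation", site = site, gaze_site = gaze_site,
         eye = eye, pos = pos, q = qs)
  }

  emit_saccade <- function(q_from, q_to, site, gaze_site, eye, frontal) {
    rel <- quat_multiply(q_to, quat_conjugate(q_from))
    rel <- rel / sqrt(sum(rel^2))
    ang <- 2 * acos(min(1, abs(rel[1])))
    if (rel[1] < 0) rel <- -rel
    ax <- rel[2:4]
    if (sqrt(sum(ax^2)) < 1e-12) ax <- c(0, 0, 1) else ax <- ax / sqrt(sum(ax^2))
    amp <- max(rad2deg(ang), 1e-6)
    kin <- sample_saccade_kinematics(amp, beh)
    frac <- kin$displacement / amp
    n <- length(frac)
    qs <- matrix(0, n, 4)
    for (i in seq_len(n))
      qs[i, ] <- quat_multiply(quat_from_axis_angle(ax, ang * frac[i]), q_from)
    pos <- matrix(perch_pos(site), n, 3, byrow = TRUE) +
      matrix(stats::rnorm(3L * n, 0, 0.3), n, 3)
    list(n = n, state = "saccade", site = site, gaze_site = gaze_site,
         eye = eye, pos = pos, q = qs, kin = kin, frontal = frontal,
         q_end = quat_multiply(quat_from_axis_angle(ax, ang), q_from))
  }

  emit_dash <- function(from_site, to_site, q_from) {
    p0 <- perch_pos(from_site); p1 <- perch_pos(to_site)
    dist <- sqrt(sum((p1 - p0)^2))
    # trapezoidal speed: constant at dash_speed with smoothstep ramps
    ramp <- 0.08
    ddur <- dist / beh$dash_speed + ramp
    n <- max(2L, round(ddur / dt))
    tt <- seq_len(n) * dt - dt / 2
    up <- pmin(1, pmax(0, tt / ramp))
    dn <- pmin(1, pmax(0, (ddur - tt) / ramp))
    ss <- function(u) u * u * (3 - 2 * u)
    v <- beh$dash_speed * pmin(ss(up), ss(dn))
    s <- cumsum(v) * dt
    s <- s / s[n]
    pos <- outer(1 - s, p0) + outer(s, p1)
    # orientation glides smoothly from the arrival pose to facing the goal
    q_to <- aim_orientation(axes$frontal, p0, c(p1[1:2], 0))
    rel <- quat_multiply(q_to, quat_conjugate(q_from))
    rel <- rel / sqrt(sum(rel^2))
    if (rel[1] < 0) rel <- -rel
    ang <- 2 * acos(min(1, rel[1]))
    ax <- rel[2:4]
    ax <- if (sqrt(sum(ax^2)) < 1e-12) c(0, 0, 1) else ax / sqrt(sum(ax^2))
    u <- pmin(1, tt / (0.5 * ddur))
    u <- u * u * (3 - 2 * u)   # smoothstep ramp over the first half
    qs <- matrix(0, n, 4)
    for (i in seq_len(n))
      qs[i, ] <- quat_multiply(quat_from_axis_angle(ax, ang * u[i]), q_from)
    list(n = n, state = "dash", site = NA_integer_, src = from_site,
         dst = to_site, gaze_site = NA_integer_, eye = NA_character_,
         pos = pos, q = qs, q_end = qs[n, , drop = FALSE])
  }

  emit_feed <- function(site, dur_s, q_from) {
    n <- max(2L, round(dur_s / dt))
    ramp <- pmin(1, seq_len(n) * dt / 0.3)
    pitch <- -deg2rad(60) * ramp
    beak <- quat_rotate(q_from, c(0, 1, 0))
    yaw0 <- atan2(-beak[1], beak[2])
    qs <- quat_yaw_pitch(rep(yaw0, n), pitch)
    pos <- matrix(perch_pos(site), n, 3, byrow = TRUE)
    pos[, 3] <- pos[, 3] - 15 * ramp
    list(n = n, state = "feed", site = site, gaze_site = NA_integer_,
         eye = NA_character_, pos = pos, q = qs)
  }

  # choose the next gaze (site, eye) during search; never repeats the
  # current one so every saccade has non-trivial amplitude
  choose_gaze <- function(target, p_target = 0.15) {
    repeat {
      site <- if (stats::runif(1) < p_target) target else sample(outer, 1L)
      eye <- sample(c("left", "right"), 1L)
      if (!(identical(site, cur_gaze_site) && identical(eye, cur_eye)))
        return(list(site = site, eye = eye))
    }
  }

  fixation_q <- function(site, eye, at_site) {
    a <- if (eye == "frontal") axes$frontal else axes[[eye]]
    q <- aim_orientation(a, perch_pos(at_site), sites3[site, ])
    # ocular scatter: the eye foveates the target, so the head-frame mean
    # axis misses by the eye-in-head deviation; drawn once per fixation
    quat_multiply(small_rotation(beh$eye_in_head_mad), q)
  }

  n_done <- 0L
  start_new_trial <- function() {
    trial_no <<- trial_no + 1L
    if (task$variant == "blocked") {
      block_trial <<- block_trial + 1L
      if (is.na(block_target) || block_trial > task$block_length) {
        block_index <<- block_index + 1L
        block_trial <<- 1L
        block_target <<- next_random_target(target_counts, block_target)
        block_catch <<- draw_catch_positions(block_pos_counts,
                                             task$catch_per_block)
        for (p in block_catch)
          block_pos_counts[as.character(p)] <<- block_pos_counts[as.character(p)] + 1
      }
      target <- block_target
      is_catch <- block_trial %in% block_catch
    } else if (task$variant == "all_to_all") {
      target <- next_all_to_all_target(pair_counts, prev_site, cur_site)
      pair_counts[cur_site, target] <<- pair_counts[cur_site, target] + 1
      is_catch <- FALSE
    } else {
      target <- next_random_target(target_counts, prev_target)
      is_catch <- FALSE
    }
    if (task$variant != "all_to_all")
      target_counts[target] <<- target_counts[target] + 1
    list(target = target, is_catch = is_catch,
         block = if (task$variant == "blocked") block_index else NA_integer_)
  }

  # main loop: one iteration = one trial
  while (n_done < n_total) {
    trial <- start_new_trial()
    target <- trial$target
    detections <- 0L
    light_on_time <- NA_real_
    # search bout at cur_site
    repeat {
      if (n_done >= n_total) break
      g <- choose_gaze(target)
      q_to <- fixation_q(g$site, g$eye, cur_site)
      sac <- emit_saccade(cur_q, q_to, cur_site, g$site, g$eye, FALSE)
      t_peak <- t_now + sac$kin$t_peak
      push(sac); n_done <- n_done + sac$n
      sacc_rows[[length(sacc_rows) + 1L]] <- data.frame(
        t_start = t_now, t_peak = t_peak,
        t_end = t_now + sac$n * dt,
        amplitude = sac$kin$displacement[length(sac$kin$displacement)],
        duration = sac$kin$duration, gaze_site = g$site, eye = g$eye,
        frontal = FALSE)
      t_now <- t_now + sac$n * dt
      cur_q <- sac$q_end
      cur_gaze_site <- g$site; cur_eye <- g$eye
      gap <- stats::rgamma(1, shape = isi$shape, scale = isi$scale)
      fix_dur <- max(0.06, gap - sac$kin$duration)
      fix <- emit_fixation(fix_dur, cur_q, g$site, g$eye, cur_site)
      push(fix); n_done <- n_done + fix$n
      # closed-loop controller: monitor this fixation's gaze
      if (is.na(light_on_time) && g$site == target) {
        rays <- gaze_rays(fix$pos, quat_normalize(fix$q), calib)
        devs <- angular_distances_to_sites(rays, arena)
        eyes <- if (task$eligible_eyes == "both") c("left", "right")
                else "left"  # contralateral eye fixed as left by convention
        dev <- sapply(eyes, function(e) devs[[e]][, target])
        hit <- detect_gaze_trigger(dev, task$gaze_trigger_threshold,
                                   task$gaze_trigger_min_samples)
        if (!is.na(hit)) {
          detections <- detections + 1L
          if (!(trial$is_catch && detections == 1L)) {
            light_on_time <- t_now + hit * dt + task$trigger_latency_median
          }
        }
      }
      t_now <- t_now + fix$n * dt
      cur_q <- quat_normalize(fix$q[fix$n, , drop = FALSE])
      if (!is.na(light_on_time) && t_now > light_on_time) break
    }
    if (n_done >= n_total) break
    # orient frontally toward the dash target, short fixation, then dash
    q_to <- fixation_q(target, "frontal", cur_site)
    sac <- emit_saccade(cur_q, q_to, cur_site, target, "frontal", TRUE)
    sacc_rows[[length(sacc_rows) + 1L]] <- data.frame(
      t_start = t_now, t_peak = t_now + sac$kin$t_peak,
      t_end = t_now + sac$n * dt,
      amplitude = sac$kin$displacement[length(sac$kin$displacement)],
      duration = sac$kin$duration, gaze_site = target, eye = "frontal",
      frontal = TRUE)
    push(sac); n_done <- n_done + sac$n; t_now <- t_now + sac$n * dt
    cur_q <- sac$q_end
    fix <- emit_fixation(0.25, cur_q, target, "frontal", cur_site)
    push(fix); n_done <- n_done + fix$n; t_now <- t_now + fix$n * dt
    cur_q <- quat_normalize(fix$q[fix$n, , drop = FALSE])

    dash <- emit_dash(cur_site, target, cur_q)
    push(dash); n_done <- n_done + dash$n
    dash_start <- t_now
    t_now <- t_now + dash$n * dt
    cur_q <- dash$q_end
    from_site <- cur_site
    cur_site <- target

    rewarded <- stats::runif(1) < task$reward_probability
    feed <- emit_feed(cur_site, stats::runif(1, 0.7, 1.2), cur_q)
    push(feed); n_done <- n_done + feed$n
    light_off_time <- if (!is.na(light_on_time)) t_now else NA_real_
    t_now <- t_now + feed$n * dt
    cur_q <- feed$q[feed$n, , drop = FALSE]
    cur_gaze_site <- NA_integer_; cur_eye <- NA_character_

    if (!is.na(light_on_time))
      light_intervals[[length(light_intervals) + 1L]] <-
        c(light_on_time, light_off_time)
    trial_rows[[length(trial_rows) + 1L]] <- data.frame(
      trial = trial_no, target = target, source = from_site,
      t_light_on = light_on_time, t_light_off = light_off_time,
      reward = rewarded, catch = trial$is_catch, block = trial$block)
    prev_site <- from_site
    prev_target <- target

    # return leg (random/blocked): frontal fixation toward center, dash
    # back, brief feed at center
    if (task$variant != "all_to_all" && n_done < n_total) {
      q_to <- fixation_q(center, "frontal", cur_site)
      sac <- emit_saccade(cur_q, q_to, cur_site, center, "frontal", TRUE)
      sacc_rows[[length(sacc_rows) + 1L]] <- data.frame(
        t_start = t_now, t_peak = t_now + sac$kin$t_peak,
        t_end = t_now + sac$n * dt,
        amplitude = sac$kin$displacement[length(sac$kin$displacement)],
        duration = sac$kin$duration, gaze_site = center, eye = "frontal",
        frontal = TRUE)
      push(sac); n_done <- n_done + sac$n; t_now <- t_now + sac$n * dt
      cur_q <- sac$q_end
      fix <- emit_fixation(0.2, cur_q, center, "frontal", cur_site)
      push(fix); n_done <- n_done + fix$n; t_now <- t_now + fix$n * dt
      dash <- emit_dash(cur_site, center, cur_q)
      push(dash); n_done <- n_done + dash$n; t_now <- t_now + dash$n * dt
      cur_q <- dash$q_end
      cur_site <- center
      feed <- emit_feed(center, stats::runif(1, 0.4, 0.8), cur_q)
      push(feed); n_done <- n_done + feed$n; t_now <- t_now + feed$n * dt
      cur_q <- feed$q[feed$n, , drop = FALSE]
    }
  }

  segs <- segs[seq_len(nseg)]
  pos <- do.call(rbind, lapply(segs, `[[`, "pos"))
  q <- do.call(rbind, lapply(segs, `[[`, "q"))
  state <- rep(vapply(segs, `[[`, "", "state"),
               vapply(segs, function(s) as.integer(s$n), 0L))
  site <- rep(vapply(segs, function(s)
    if (is.null(s$site)) NA_integer_ else as.integer(s$site), 0L),
    vapply(segs, function(s) as.integer(s$n), 0L))
  gaze_site <- rep(vapply(segs, function(s)
    as.integer(s$gaze_site %||% NA_integer_), 0L),
    vapply(segs, function(s) as.integer(s$n), 0L))
  gaze_eye <- rep(vapply(segs, function(s)
    as.character(s$eye %||% NA_character_), ""), vapply(segs, function(s) as.integer(s$n), 0L))
  keep <- seq_len(min(n_total, nrow(pos)))
  tvec <- (keep - 1L) * dt
  q <- quat_normalize(q[keep, , drop = FALSE])
  trace <- list(t = tvec, position = pos[keep, , drop = FALSE],
                orientation = q)
  saccades <- if (length(sacc_rows)) do.call(rbind, sacc_rows) else
    data.frame(t_start = numeric(), t_peak = numeric(), t_end = numeric(),
               amplitude = numeric(), duration = numeric(),
               gaze_site = integer(), eye = character(),
               frontal = logical())
  saccades <- saccades[saccades$t_end <= duration, , drop = FALSE]
  trials <- if (length(trial_rows)) do.call(rbind, trial_rows) else
    data.frame(trial = integer(), target = integer(), source = integer(),
               t_light_on = numeric(), t_light_off = numeric(),
               reward = logical(), catch = logical(), block = integer())
  # drop trials not completed within the requested duration
  trials <- trials[is.na(trials$t_light_off) |
                     trials$t_light_off <= duration, , drop = FALSE]
  light <- rep(FALSE, length(keep))
  for (iv in light_intervals) {
    i0 <- max(1L, ceiling(iv[1] / dt)); i1 <- min(length(keep),
                                                  floor(iv[2] / dt))
    if (i0 <= i1) light[i0:i1] <- TRUE
  }
  structure(list(
    trace = trace,
    events = list(trials = trials, light = light),
    labels = list(state = state[keep], site = site[keep],
                  gaze_site = gaze_site[keep], gaze_eye = gaze_eye[keep],
                  saccades = saccades),
    arena = arena, beh = beh, task = task, calib = calib,
    rng_seed = rng_seed), class = "synthetic_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
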