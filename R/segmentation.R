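#' Kinematic features for behavioral segmentation
#'
#' Computes from a head-pose trace the inputs of the segmentation HMM:
#' linear speed (finite differences of 3D position), angular speed
#' (geodesic quaternion difference between adjacent frames), head tilt
#' (angle of the head z axis from world vertical), and bounded proximity
#' features to each site and each permitted inter-site path. Both speeds
#' are zero-phase low-pass filtered with a 2nd-order Butterworth filter at
#' `cutoff` Hz.
#'
#' Proximity is a Gaussian kernel of the point-to-site or point-to-segment
#' distance, `exp(-d^2 / (2 * length_scale^2))`; speeds enter the HMM on a
#' `log10(1 + x)` scale so that small and large saccades share a state.
#'
#' @param trace list with `t`, `position` (n x 3 mm), `orientation`
#'   (n x 4 unit quaternions).
#' @param arena an [arena_config()].
#' @param cutoff low-pass cutoff, Hz.
#' @param length_scale proximity kernel scale, mm.
#' @return list of class `kinematic_features`: `t`, `dt`, `linear_speed`,
#'   `angular_speed` (filtered, mm/s and deg/s), `tilt` (deg),
#'   `prox_sites`, `prox_paths`, `paths` (matrix of site index pairs), and
#'   `X`, the assembled observation matrix.
#' @export
compute_kinematic_features <- function(trace, arena, cutoff = 25,
                                       length_scale = 50) {
  t <- trace$t
  dtv <- diff(t)
  dt <- stats::median(dtv)
  if (any(abs(dtv - dt) > 0.25 * dt))
    stop("trace is not uniformly sampled")
  n <- length(t)
  dp <- diff(trace$position)
  lin <- c(0, sqrt(rowSums(dp^2)) / dt)
  ang <- c(0, rad2deg(quat_angle(trace$orientation[-n, , drop = FALSE],
                                 trace$orientation[-1, , drop = FALSE])) / dt)
  bf <- signal::butter(2, cutoff / (0.5 / dt), type = "low")
  lin_f <- pmax(0, signal::filtfilt(bf, lin))
  ang_f <- pmax(0, signal::filtfilt(bf, ang))
  zhead <- quat_rotate(trace$orientation, c(0, 0, 1))
  tilt <- angle_between_deg(zhead, c(0, 0, 1))

  sites <- arena$site_positions
  prox_sites <- sapply(seq_len(nrow(sites)), function(k) {
    d2 <- (trace$position[, 1] - sites[k, 1])^2 +
      (trace$position[, 2] - sites[k, 2])^2
    exp(-d2 / (2 * length_scale^2))
  })
  paths <- arena_paths(arena)
  prox_paths <- sapply(seq_len(nrow(paths)), function(p) {
    d2 <- point_segment_dist2(trace$position[, 1:2, drop = FALSE],
                              sites[paths[p, 1], ], sites[paths[p, 2], ])
    exp(-d2 / (2 * length_scale^2))
  })
  X <- cbind(log10(1 + lin_f), log10(1 + ang_f), tilt, prox_sites,
             prox_paths)
  colnames(X) <- c("log_lin", "log_ang", "tilt",
                   paste0("prox_s", seq_len(ncol(prox_sites))),
                   paste0("prox_p", seq_len(ncol(prox_paths))))
  structure(list(t = t, dt = dt, linear_speed = lin_f,
                 angular_speed = ang_f, tilt = tilt,
                 prox_sites = prox_sites, prox_paths = prox_paths,
                 paths = paths, X = X),
            class = "kinematic_features")
}

# permitted dash paths: center <-> outer for the X layout, all site pairs
# for the pentagon
arena_paths <- function(arena) {
  if (arena$layout == "x_shape") {
    cbind(src = arena$center_site_index, dst = arena$outer_sites)
  } else {
    p <- t(utils::combn(seq_len(nrow(arena$site_positions)), 2))
    colnames(p) <- c("src", "dst")
    p
  }
}

point_segment_dist2 <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  u <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  u <- pmin(1, pmax(0, u))
  (p[, 1] - (a[1] + u * ab[1]))^2 + (p[, 2] - (a[2] + u * ab[2]))^2
}

#' Segmentation HMM specification
#'
#' States are fixation, saccade and feed at each site, plus one dash state
#' per permitted ordered site pair. The observation model is a diagonal
#' Gaussian over the feature space of [compute_kinematic_features()];
#' per-state means are initialized from the arena geometry and kinematic
#' priors (and may be refit with [fit_observation_means()]), while the
#' standard deviations and the transition matrix are fixed. Self-transition
#' probability is `self_p`, with the remainder split over the behaviorally
#' permitted moves (fixation to saccade at the same site and back, fixation
#' to an outgoing dash, dash to feed or fixation at its destination, feed
#' to fixation at the same site).
#'
#' @param arena an [arena_config()].
#' @param features a `kinematic_features` object (supplies the path set).
#' @param self_p self-transition probability.
#' @param speed_priors named list overriding the kinematic prior means
#'   (`lin`, `ang`, `tilt` per state type), natural units.
#' @return list of class `hmm_spec` with `states` (data.frame: `name`,
#'   `type`, `site`, `src`, `dst`), `mu` (K x F), `sd` (F), `log_trans`,
#'   `log_init`.
#' @export
hmm_spec <- function(arena, features, self_p = 0.99, speed_priors = NULL) {
  sp <- list(fixation = c(lin = 40, ang = 15, tilt = 10),
             saccade = c(lin = 40, ang = 600, tilt = 10),
             feed = c(lin = 30, ang = 30, tilt = 50),
             dash = c(lin = 420, ang = 60, tilt = 10))
  if (!is.null(speed_priors)) sp[names(speed_priors)] <- speed_priors
  sites <- arena$site_positions
  ns <- nrow(sites)
  paths <- features$paths
  states <- rbind(
    data.frame(name = paste0("fixation@", 1:ns), type = "fixation",
               site = 1:ns, src = NA_integer_, dst = NA_integer_),
    data.frame(name = paste0("saccade@", 1:ns), type = "saccade",
               site = 1:ns, src = NA_integer_, dst = NA_integer_),
    data.frame(name = paste0("feed@", 1:ns), type = "feed",
               site = 1:ns, src = NA_integer_, dst = NA_integer_))
  for (p in seq_len(nrow(paths))) {
    for (dir in 1:2) {
      s <- if (dir == 1) paths[p, 1] else paths[p, 2]
      d <- if (dir == 1) paths[p, 2] else paths[p, 1]
      states <- rbind(states, data.frame(
        name = paste0("dash@", s, ">", d), type = "dash", site = NA_integer_,
        src = s, dst = d))
    }
  }
  K <- nrow(states)
  F_ <- ncol(features$X)
  length_scale <- 50
  prox_from_point <- function(xy) {
    ds <- exp(-((sites[, 1] - xy[1])^2 + (sites[, 2] - xy[2])^2) /
                (2 * length_scale^2))
    dp <- sapply(seq_len(nrow(paths)), function(q) {
      d2 <- point_segment_dist2(matrix(xy, 1), sites[paths[q, 1], ],
                                sites[paths[q, 2], ])
      exp(-d2 / (2 * length_scale^2))
    })
    c(ds, dp)
  }
  mu <- matrix(0, K, F_)
  sd <- matrix(rep(c(0.35, 0.45, 12, rep(0.25, F_ - 3)), each = K), K, F_)
  for (k in seq_len(K)) {
    ty <- states$type[k]
    if (ty == "dash") {
      # a dash sweeps its whole path: full proximity to its own path,
      # intermediate proximity to its endpoints (the bird starts and ends
      # there), none to anything else
      prox <- prox_from_point((sites[states$src[k], ] +
                                 sites[states$dst[k], ]) / 2)
      prox[c(states$src[k], states$dst[k])] <- 0.5
      own <- which(paths[, 1] == states$src[k] & paths[, 2] == states$dst[k] |
                     paths[, 2] == states$src[k] & paths[, 1] == states$dst[k])
      prox[ns + own] <- 1
    } else {
      prox <- prox_from_point(sites[states$site[k], ])
    }
    mu[k, ] <- c(log10(1 + sp[[ty]]["lin"]), log10(1 + sp[[ty]]["ang"]),
                 sp[[ty]]["tilt"], prox)
  }
  colnames(mu) <- colnames(features$X)

  trans <- matrix(0, K, K)
  idx <- function(type, site = NA, src = NA, dst = NA) {
    which(states$type == type &
            (is.na(site) | states$site %in% site) &
            (is.na(src) | states$src %in% src) &
            (is.na(dst) | states$dst %in% dst))
  }
  for (k in seq_len(K)) {
    ty <- states$type[k]
    to <- switch(ty,
      fixation = c(idx("saccade", states$site[k]),
                   idx("dash", src = states$site[k]),
                   idx("feed", states$site[k])),
      saccade = c(idx("fixation", states$site[k]),
                  idx("feed", states$site[k]),
                  idx("dash", src = states$site[k])),
      feed = c(idx("fixation", states$site[k]),
               idx("saccade", states$site[k])),
      dash = c(idx("feed", states$dst[k]),
               idx("fixation", states$dst[k])))
    trans[k, k] <- self_p
    trans[k, to] <- (1 - self_p) / length(to)
  }
  log_trans <- log(trans)
  structure(list(states = states, mu = mu, sd = sd, log_trans = log_trans,
                 log_init = rep(log(1 / K), K)),
            class = "hmm_spec")
}

#' Most likely state path by Viterbi decoding
#'
#' @param features a `kinematic_features` object, or a plain observation
#'   matrix.
#' @param spec an [hmm_spec()].
#' @return list with `path` (integer state indices per sample), `logp`
#'   (joint log-likelihood of the returned path), `states` (the
#'   specification's state table).
#' @export
viterbi_decode <- function(features, spec) {
  X <- if (is.matrix(features)) features else features$X
  if (ncol(X) != ncol(spec$mu))
    stop("feature dimension does not match HMM specification")
  sdm <- spec$sd
  if (is.null(dim(sdm)))
    sdm <- matrix(rep(sdm, each = nrow(spec$mu)), nrow(spec$mu))
  out <- .viterbi_gauss_cpp(X, spec$mu, sdm, spec$log_trans,
                            spec$log_init)
  out$states <- spec$states
  out
}

#' Refit per-state observation means by Viterbi training
#'
#' Alternates Viterbi decoding and per-state re-estimation of the Gaussian
#' means until the decoded labels stabilize or `max_iter` is reached.
#' Variances and the transition matrix are never altered. A state decoded
#' for fewer than `min_samples` samples keeps its prior mean (with a
#' warning on the first occurrence).
#'
#' @param features a `kinematic_features` object.
#' @param spec an [hmm_spec()] providing the initial means.
#' @param max_iter maximum refit iterations.
#' @param min_samples minimum samples for a state's mean to be refit.
#' @param tol fraction of samples allowed to change label at convergence.
#' @return the updated `hmm_spec` with an added `n_iter` element.
#' @export
fit_observation_means <- function(features, spec, max_iter = 10,
                                  min_samples = 10, tol = 1e-4) {
  X <- features$X
  prev_path <- NULL
  warned <- FALSE
  for (it in seq_len(max_iter)) {
    dec <- viterbi_decode(features, spec)
    if (!is.null(prev_path) &&
        mean(dec$path != prev_path) <= tol) break
    prev_path <- dec$path
    for (k in seq_len(nrow(spec$mu))) {
      sel <- dec$path == k
      if (sum(sel) >= min_samples) {
        spec$mu[k, ] <- colMeans(X[sel, , drop = FALSE])
      } else if (!warned && sum(sel) > 0) {
        warning("some states received too few samples; their prior means were kept")
        warned <- TRUE
      }
    }
  }
  spec$n_iter <- it
  spec
}

#' Segment table from a decoded state path
#'
#' Converts a per-sample Viterbi path into labeled intervals and applies
#' the post-hoc cleanup and endpoint refinement rules, in order: saccades
#' immediately preceding feeding are merged into the feed; saccades
#' immediately following a dash are merged into the dash; feeding
#' immediately after a dash is merged into the dash. Saccade endpoints are
#' then trimmed to the outermost samples where angular speed exceeds
#' `sacc_vel` or absolute angular acceleration exceeds `sacc_acc`; dash
#' stop times are trimmed analogously on linear kinematics (`dash_vel`,
#' `dash_acc`). Per-saccade peak-velocity time, amplitude and duration are
#' computed on the refined interval, and the landing site is the site
#' within `landing_threshold` degrees of an eye's gaze during the
#' following fixation.
#'
#' Saccades immediately followed by a fixation are flagged `eligible`;
#' those that additionally landed on a site and peaked more than 0.5 s
#' before the next dash start are flagged `gaze_included`.
#'
#' @param decoded result of [viterbi_decode()].
#' @param features the `kinematic_features` used for decoding.
#' @param trace the head-pose trace.
#' @param arena an [arena_config()].
#' @param calib an [eye_calibration()].
#' @param sacc_vel,sacc_acc saccade refinement thresholds (deg/s, deg/s^2).
#' @param dash_vel,dash_acc dash refinement thresholds (mm/s, mm/s^2).
#' @param landing_threshold landing-site assignment threshold, degrees.
#' @return data.frame of class `segment_table`: `state`, `site`, `src`,
#'   `dst`, `t_start`, `t_end`, `t_peak`, `amplitude`, `duration`,
#'   `landing_site`, `landing_eye`, `eligible`, `gaze_included`.
#' @export
refine_segments <- function(decoded, features, trace, arena,
                            calib = eye_calibration(),
                            sacc_vel = 400, sacc_acc = 5000,
                            dash_vel = 150, dash_acc = 3000,
                            landing_threshold = 20) {
  st <- decoded$states
  path <- decoded$path
  if (length(path) == 0L) return(empty_segment_table())
  r <- rle(path)
  k <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(state = st$type[k], site = st$site[k], src = st$src[k],
                    dst = st$dst[k], i0 = starts, i1 = ends)
  # cleanup merges, in the stated order
  seg <- merge_runs(seg, function(a, b) a == "saccade" & b == "feed", "next")
  seg <- merge_runs(seg, function(a, b) a == "dash" & b == "saccade", "prev")
  seg <- merge_runs(seg, function(a, b) a == "dash" & b == "feed", "prev")

  dt <- features$dt
  ang <- features$angular_speed
  lin <- features$linear_speed
  angacc <- c(0, diff(ang)) / dt
  linacc <- c(0, diff(lin)) / dt
  n <- length(ang)
  tvec <- features$t

  out <- seg
  out$t_start <- tvec[seg$i0]
  out$t_end <- tvec[seg$i1] + dt
  out$t_peak <- NA_real_
  out$amplitude <- NA_real_
  out$duration <- NA_real_
  out$drop <- FALSE

  is_sacc <- which(seg$state == "saccade")
  for (s in is_sacc) {
    i0 <- max(1L, seg$i0[s] - 1L); i1 <- min(n, seg$i1[s] + 1L)
    idx <- i0:i1
    supra <- ang[idx] >= sacc_vel | abs(angacc[idx]) >= sacc_acc
    if (!any(ang[idx] >= sacc_vel)) supra[] <- FALSE
    if (any(supra)) {
      j0 <- idx[which(supra)[1]]
      j1 <- idx[rev(which(supra))[1]]
    } else {
      # no sample passes either refinement criterion: not a saccade;
      # absorb into the preceding segment
      out$drop[s] <- TRUE
      j0 <- seg$i0[s]; j1 <- seg$i1[s]
    }
    out$i0[s] <- j0; out$i1[s] <- j1
    out$t_start[s] <- tvec[j0]
    out$t_end[s] <- tvec[j1] + dt
    out$duration[s] <- max(dt, (j1 - j0) * dt)
    pk <- j0 + which.max(ang[j0:j1]) - 1L
    out$t_peak[s] <- tvec[pk]
    qa <- trace$orientation[j0:j1, , drop = FALSE]
    out$amplitude[s] <- sum(rad2deg(quat_angle(qa[-nrow(qa), , drop = FALSE],
                                               qa[-1, , drop = FALSE])))
  }
  dash_rows <- which(out$state == "dash")
  for (s in dash_rows) {
    # the stop time is where linear speed and acceleration fall below
    # threshold: trim back if the decoded interval overhangs, extend
    # forward if deceleration was decoded into the following state
    j1 <- out$i1[s]
    while (j1 + 1L <= n &&
           (lin[j1 + 1L] >= dash_vel || abs(linacc[j1 + 1L]) >= dash_acc))
      j1 <- j1 + 1L
    if (j1 == out$i1[s]) {
      idx <- out$i0[s]:j1
      supra <- lin[idx] >= dash_vel | abs(linacc[idx]) >= dash_acc
      if (any(supra)) j1 <- idx[rev(which(supra))[1]]
    }
    out$i1[s] <- j1
    out$t_end[s] <- tvec[j1] + dt
    # shift the start of overlapped following segments
    nx <- s + 1L
    while (nx <= nrow(out) && out$i0[nx] <= j1) {
      if (out$i1[nx] <= j1) {
        out$drop[nx] <- TRUE
        nx <- nx + 1L
      } else {
        out$i0[nx] <- j1 + 1L
        out$t_start[nx] <- tvec[j1 + 1L]
        break
      }
    }
  }

  if (any(out$drop)) {
    for (s in which(out$drop)) {
      nb <- if (s > 1L) s - 1L else s + 1L
      if (nb >= 1L && nb <= nrow(out) && !out$drop[nb]) {
        if (nb < s) out$i1[nb] <- max(out$i1[nb], out$i1[s])
        else out$i0[nb] <- min(out$i0[nb], out$i0[s])
      }
    }
    out <- out[!out$drop, , drop = FALSE]
    is_sacc <- which(out$state == "saccade")
  }
  out$drop <- NULL

  # landing site: eye-gaze deviation during the following fixation
  out$landing_site <- NA_integer_
  out$landing_eye <- NA_character_
  out$eligible <- FALSE
  nseg <- nrow(out)
  for (s in is_sacc) {
    if (s == nseg || out$state[s + 1L] != "fixation") next
    out$eligible[s] <- TRUE
    i <- min(out$i0[s + 1L] + 6L, out$i1[s + 1L])
    rays <- gaze_rays(trace$position[i, , drop = FALSE],
                      quat_normalize(trace$orientation[i, , drop = FALSE]),
                      calib)
    devs <- angular_distances_to_sites(rays, arena)
    dl <- devs$left[1, ]; dr <- devs$right[1, ]
    best <- which.min(pmin(dl, dr))
    if (min(dl[best], dr[best]) < landing_threshold) {
      out$landing_site[s] <- best
      out$landing_eye[s] <- if (dl[best] <= dr[best]) "left" else "right"
    }
  }
  # gaze inclusion: landed on a site, and >0.5 s before the next dash start
  dash_starts <- out$t_start[out$state == "dash"]
  out$gaze_included <- FALSE
  for (s in is_sacc) {
    if (is.na(out$landing_site[s])) next
    nxt <- dash_starts[dash_starts > out$t_peak[s]]
    out$gaze_included[s] <- length(nxt) == 0L ||
      (nxt[1] - out$t_peak[s]) > 0.5
  }
  out$i0 <- NULL; out$i1 <- NULL
  class(out) <- c("segment_table", "data.frame")
  out
}

empty_segment_table <- function() {
  structure(data.frame(state = character(), site = integer(),
                       src = integer(), dst = integer(),
                       t_start = numeric(), t_end = numeric(),
                       t_peak = numeric(), amplitude = numeric(),
                       duration = numeric(), landing_site = integer(),
                       landing_eye = character(), eligible = logical(),
                       gaze_included = logical()),
            class = c("segment_table", "data.frame"))
}

# merge runs where predicate(state[a], state[b]) holds for adjacent rows;
# direction "prev" absorbs row b into a, "next" absorbs a into b
merge_runs <- function(seg, pred, into) {
  repeat {
    if (nrow(seg) < 2L) return(seg)
    a <- seg$state[-nrow(seg)]; b <- seg$state[-1]
    hit <- which(pred(a, b))
    if (length(hit) == 0L) return(seg)
    h <- hit[1]
    if (into == "prev") {
      seg$i1[h] <- seg$i1[h + 1L]
      seg <- seg[-(h + 1L), , drop = FALSE]
    } else {
      seg$i0[h + 1L] <- seg$i0[h]
      seg <- seg[-h, , drop = FALSE]
    }
  }
}

#' Session inclusion decision
#'
#' A session is analyzed only if it contains at least `min_dashes` dashes
#' and at least `min_saccades` gaze-included saccades with each eye to
#' each outer target.
#'
#' @param segments a `segment_table`.
#' @param arena an [arena_config()].
#' @param min_dashes,min_saccades inclusion thresholds.
#' @return list with `include` (logical) and `reason` (character, empty if
#'   included).
#' @export
session_inclusion <- function(segments, arena, min_dashes = 5,
                              min_saccades = 5) {
  n_dash <- sum(segments$state == "dash")
  if (n_dash < min_dashes)
    return(list(include = FALSE,
                reason = sprintf("only %d dashes (need %d)", n_dash,
                                 min_dashes)))
  sac <- segments[segments$state == "saccade" & segments$gaze_included, ]
  for (eye in c("left", "right")) {
    for (s in arena$outer_sites) {
      n <- sum(sac$landing_eye == eye & sac$landing_site == s,
               na.rm = TRUE)
      if (n < min_saccades)
        return(list(include = FALSE,
                    reason = sprintf(
                      "only %d saccades with %s eye to site %d (need %d)",
                      n, eye, s, min_saccades)))
    }
  }
  list(include = TRUE, reason = "")
}

#' Full segmentation pipeline for one session
#'
#' Convenience wrapper: features, HMM construction, mean refitting,
#' Viterbi decoding and refinement.
#'
#' @param trace head-pose trace.
#' @param arena an [arena_config()].
#' @param calib an [eye_calibration()].
#' @param refit whether to refit observation means by Viterbi training.
#' @param ... passed to [refine_segments()].
#' @return a `segment_table`.
#' @export
segment_session <- function(trace, arena, calib = eye_calibration(),
                            refit = TRUE, ...) {
  feats <- compute_kinematic_features(trace, arena)
  spec <- hmm_spec(arena, feats)
  if (refit) spec <- fit_observation_means(feats, spec, max_iter = 3)
  dec <- viterbi_decode(feats, spec)
  refine_segments(dec, feats, trace, arena, calib, ...)
}

#' Inter-saccade intervals during visual search
#'
#' Intervals between the peak-velocity times of successive detected
#' saccades separated only by fixations (periods of visual search);
#' intervals spanning dashes or feeding bouts are excluded. The
#' reciprocal of these intervals is the instantaneous saccade rate.
#'
#' @param segments a `segment_table`.
#' @return numeric vector of intervals, s.
#' @export
search_intervals <- function(segments) {
  st <- segments$state
  sidx <- which(st == "saccade")
  if (length(sidx) < 2) return(numeric(0))
  out <- numeric(0)
  for (k in seq_len(length(sidx) - 1L)) {
    between <- st[seq(sidx[k] + 1L, sidx[k + 1L] - 1L)]
    if (sidx[k + 1L] == sidx[k] + 1L || all(between == "fixation"))
      out <- c(out, segments$t_peak[sidx[k + 1L]] - segments$t_peak[sidx[k]])
  }
  out
}
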