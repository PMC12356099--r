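make_trace <- function(n, pos_fun, quat_fun, dt = 1 / 300) {
  t <- (seq_len(n) - 1) * dt
  list(t = t, position = t(vapply(t, pos_fun, numeric(3))),
       orientation = do.call(rbind, lapply(t, quat_fun)))
}

test_that("kinematic features recover closed-form speeds", {
  arena <- arena_config()
  n <- 300
  # stationary
  tr0 <- make_trace(n, function(t) c(0, 0, 54), function(t) c(1, 0, 0, 0))
  f0 <- compute_kinematic_features(tr0, arena)
  expect_lt(max(f0$linear_speed), 1e-6)
  expect_lt(max(f0$angular_speed), 1e-6)
  # constant linear velocity 100 mm/s
  tr1 <- make_trace(n, function(t) c(100 * t, 0, 54),
                    function(t) c(1, 0, 0, 0))
  f1 <- compute_kinematic_features(tr1, arena)
  mid <- 50:250
  expect_equal(mean(f1$linear_speed[mid]), 100, tolerance = 0.02)
  # pure yaw at 360 deg/s
  tr2 <- make_trace(n, function(t) c(0, 0, 54), function(t)
    c(quat_from_axis_angle(c(0, 0, 1), 2 * pi * t)))
  f2 <- compute_kinematic_features(tr2, arena)
  expect_equal(mean(f2$angular_speed[mid]), 360, tolerance = 0.02)
})

test_that("non-uniform timestamps are rejected", {
  arena <- arena_config()
  tr <- make_trace(100, function(t) c(0, 0, 54), function(t) c(1, 0, 0, 0))
  tr$t[50] <- tr$t[50] + 0.002
  expect_error(compute_kinematic_features(tr, arena), "uniform")
})

test_that("Viterbi matches exhaustive enumeration on small instances", {
  set.seed(11)
  for (rep in 1:20) {
    inst <- random_hmm_instance(n_samples = sample(2:6, 1),
                                n_states = sample(2:4, 1))
    spec <- structure(list(states = data.frame(
      name = paste0("s", seq_len(nrow(inst$mu))), type = "x",
      site = NA, src = NA, dst = NA),
      mu = inst$mu, sd = inst$sd, log_trans = inst$log_trans,
      log_init = inst$log_init), class = "hmm_spec")
    got <- viterbi_decode(inst$X, spec)
    want <- viterbi_brute_force(inst$X, inst$mu, inst$sd, inst$log_trans,
                                inst$log_init)
    expect_equal(got$logp, want$logp, tolerance = 1e-9)
    expect_equal(got$path, want$path)
  }
})

test_that("with uninformative observations the path follows the transition structure", {
  # all states share one observation model; a strongly asymmetric prior
  # plus near-absorbing transitions pins the whole path to state 1
  mu <- rbind(c(0, 0), c(0, 0))
  spec <- structure(list(
    states = data.frame(name = c("a", "b"), type = "x", site = NA,
                        src = NA, dst = NA),
    mu = mu, sd = c(1, 1),
    log_trans = log(rbind(c(0.99, 0.01), c(0.5, 0.5))),
    log_init = log(c(0.9, 0.1))), class = "hmm_spec")
  X <- matrix(rnorm(20), 10, 2)
  got <- viterbi_decode(X, spec)
  expect_true(all(got$path == 1L))
})

test_that("impossible paths raise a decode failure", {
  spec <- structure(list(
    states = data.frame(name = c("a", "b"), type = "x", site = NA,
                        src = NA, dst = NA),
    mu = rbind(c(0, 0), c(5, 5)), sd = c(1, 1),
    log_trans = log(rbind(c(0, 1), c(1, 0))) , # no self transitions
    log_init = log(c(0, 0))),                  # and an impossible prior
    class = "hmm_spec")
  X <- matrix(rnorm(10), 5, 2)
  expect_error(viterbi_decode(X, spec), "zero probability")
})

test_that("mean refitting is a fixed point at the truth and recovers perturbed means", {
  fx <- fixture_session()
  feats <- compute_kinematic_features(fx$session$trace, fx$session$arena)
  spec <- hmm_spec(fx$session$arena, feats)
  fitted <- fit_observation_means(feats, spec, max_iter = 5)
  # fixed point: refitting the converged spec changes paths nowhere
  again <- fit_observation_means(feats, fitted, max_iter = 2)
  p1 <- viterbi_decode(feats, fitted)$path
  p2 <- viterbi_decode(feats, again)$path
  expect_gt(mean(p1 == p2), 0.999)
  # perturbing the kinematic means by 20% still recovers the same
  # decoding after refitting
  pert <- fitted
  pert$mu[, 1:2] <- pert$mu[, 1:2] * 1.2
  re <- fit_observation_means(feats, pert, max_iter = 5)
  p3 <- viterbi_decode(feats, re)$path
  expect_gt(mean(p3 == p1), 0.95)
})

test_that("segmentation recovers ground truth accurately", {
  fx <- fixture_session()
  s <- fx$session
  seg <- fx$segments
  truth <- s$labels$saccades
  det <- seg[seg$state == "saccade", ]
  # count within 5% of ground truth
  expect_lt(abs(nrow(det) / nrow(truth) - 1), 0.05)
  # per-sample state agreement >= 90%
  dt <- 1 / 300
  decoded_state <- rep(NA_character_, length(s$trace$t))
  for (r in seq_len(nrow(seg))) {
    i0 <- max(1L, round(seg$t_start[r] / dt) + 1L)
    i1 <- min(length(decoded_state), round(seg$t_end[r] / dt))
    decoded_state[i0:i1] <- seg$state[r]
  }
  ok <- !is.na(decoded_state)
  expect_gt(mean(decoded_state[ok] == s$labels$state[ok]), 0.90)
  # saccade detection F1 at IoU >= 0.5
  iou <- function(a0, a1, b0, b1) {
    inter <- max(0, min(a1, b1) - max(a0, b0))
    inter / (max(a1, b1) - min(a0, b0))
  }
  matched <- 0
  used <- rep(FALSE, nrow(truth))
  for (r in seq_len(nrow(det))) {
    j <- which(!used & abs(truth$t_peak - det$t_peak[r]) < 0.15)
    if (length(j)) {
      j <- j[which.max(vapply(j, function(jj)
        iou(truth$t_start[jj], truth$t_end[jj], det$t_start[r],
            det$t_end[r]), 0))]
      if (iou(truth$t_start[j], truth$t_end[j], det$t_start[r],
              det$t_end[r]) >= 0.5) {
        matched <- matched + 1
        used[j] <- TRUE
      }
    }
  }
  precision <- matched / nrow(det)
  recall <- matched / nrow(truth)
  f1 <- 2 * precision * recall / (precision + recall)
  expect_gte(f1, 0.90)
  # peak-time error below 2 samples on matched saccades
  j <- vapply(det$t_peak, function(tp) which.min(abs(truth$t_peak - tp)), 0L)
  close <- abs(truth$t_peak[j] - det$t_peak) < 0.05
  expect_lt(mean(abs(truth$t_peak[j][close] - det$t_peak[close])) * 300, 2)
})

test_that("refinement keeps peaks inside refined intervals", {
  fx <- fixture_session()
  det <- fx$segments[fx$segments$state == "saccade", ]
  expect_true(all(det$t_peak >= det$t_start - 1e-9))
  expect_true(all(det$t_peak <= det$t_end + 1e-9))
  expect_true(all(det$duration > 0))
})

test_that("cleanup merge rules absorb misclassified runs", {
  # hand-built decoded path on a 2-site toy state set
  states <- data.frame(
    name = c("fixation@1", "saccade@1", "feed@1", "dash@1>2", "fixation@2"),
    type = c("fixation", "saccade", "feed", "dash", "fixation"),
    site = c(1, 1, 1, NA, 2), src = c(NA, NA, NA, 1, NA),
    dst = c(NA, NA, NA, 2, NA))
  # saccade (state 2) directly before feed (3): merged into feed;
  # saccade directly after dash (4): merged into dash
  path <- c(rep(1, 10), rep(2, 3), rep(3, 10), rep(4, 10), rep(2, 3),
            rep(5, 10))
  n <- length(path)
  dt <- 1 / 300
  trace <- make_trace(n, function(t) c(0, 0, 54), function(t) c(1, 0, 0, 0))
  feats <- list(t = trace$t, dt = dt, angular_speed = rep(0, n),
                linear_speed = rep(0, n))
  dec <- list(path = path, states = states)
  seg <- refine_segments(dec, feats, trace, arena_config())
  expect_false(any(seg$state == "saccade"))
  expect_equal(seg$state, c("fixation", "feed", "dash", "fixation"))
  # the feed interval swallowed the preceding saccade samples
  expect_equal(seg$t_start[seg$state == "feed"], 10 * dt)
})

test_that("session inclusion applies the 5-dash / 5-saccade criteria", {
  arena <- arena_config()
  mk <- function(n_dash, sac_counts) {
    segs <- data.frame()
    if (n_dash > 0)
      segs <- data.frame(state = "dash", site = NA, src = 5, dst = 1,
                         t_start = 1:n_dash, t_end = 1:n_dash + 0.5,
                         t_peak = NA, amplitude = NA, duration = NA,
                         landing_site = NA, landing_eye = NA,
                         eligible = FALSE, gaze_included = FALSE)
    for (eye in names(sac_counts)) {
      for (site in 1:4) {
        k <- sac_counts[[eye]][site]
        if (k > 0)
          segs <- rbind(segs, data.frame(
            state = "saccade", site = 5, src = NA, dst = NA,
            t_start = seq_len(k), t_end = seq_len(k) + 0.1,
            t_peak = seq_len(k) + 0.05, amplitude = 30, duration = 0.08,
            landing_site = site, landing_eye = eye, eligible = TRUE,
            gaze_included = TRUE))
      }
    }
    segs
  }
  good <- mk(5, list(left = rep(5, 4), right = rep(5, 4)))
  expect_true(session_inclusion(good, arena)$include)
  # boundary: 4 saccades with the left eye to one target
  bad <- mk(5, list(left = c(4, 5, 5, 5), right = rep(5, 4)))
  r <- session_inclusion(bad, arena)
  expect_false(r$include)
  expect_match(r$reason, "left eye to site 1")
  few_dash <- mk(4, list(left = rep(5, 4), right = rep(5, 4)))
  expect_false(session_inclusion(few_dash, arena)$include)
  empty <- mk(0, list(left = rep(0, 4), right = rep(0, 4)))
  expect_false(session_inclusion(empty, arena)$include)
})
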