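# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# a 240-s random-task session with segmentation
fixture_session <- function() {
  if (is.null(.fixtures$session)) {
    s <- generate_session(duration = 420, rng_seed = 42)
    .fixtures$session <- s
    .fixtures$segments <- segment_session(s$trace, s$arena, s$calib)
  }
  list(session = .fixtures$session, segments = .fixtures$segments)
}

# a small gaze- and place-tuned excitatory population on the fixture session
fixture_population <- function(n = 12, contra_fraction = 1) {
  key <- paste0("pop", n, "_", contra_fraction)
  if (is.null(.fixtures[[key]])) {
    fx <- fixture_session()
    specs <- lapply(seq_len(n), function(j)
      neuron_spec(baseline_rate = 1, preferred_site = ((j - 1) %% 4) + 1,
                  place_gain = 10, gaze_gain = 10,
                  contra_fraction = contra_fraction))
    .fixtures[[key]] <- generate_spike_population(specs, fx$session,
                                                  rng_seed = 100 + n)
  }
  .fixtures[[key]]
}

# brute-force Viterbi oracle: enumerate all K^n paths
viterbi_brute_force <- function(X, mu, sd, log_trans, log_init) {
  n <- nrow(X); K <- nrow(mu)
  if (is.null(dim(sd))) sd <- matrix(rep(sd, each = K), K)
  emis <- sapply(seq_len(K), function(k)
    rowSums(sapply(seq_len(ncol(X)), function(f)
      dnorm(X[, f], mu[k, f], sd[k, f], log = TRUE))))
  if (n == 1L) emis <- matrix(emis, nrow = 1)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lp <- log_init[p[1]] + emis[1, p[1]]
    if (n > 1) for (t in 2:n)
      lp <- lp + log_trans[p[t - 1], p[t]] + emis[t, p[t]]
    if (lp > best) { best <- lp; best_path <- p }
  }
  list(path = unname(best_path), logp = best)
}

# random small HMM instance for property tests
random_hmm_instance <- function(n_samples, n_states, n_features = 2) {
  tm <- matrix(runif(n_states^2, 0.05, 1), n_states)
  tm <- tm / rowSums(tm)
  list(X = matrix(rnorm(n_samples * n_features), n_samples),
       mu = matrix(rnorm(n_states * n_features, sd = 2), n_states),
       sd = runif(n_features, 0.5, 2),
       log_trans = log(tm),
       log_init = log(rep(1 / n_states, n_states)))
}

# hand-built session with n well-separated saccades, all landing the given
# eye on the given site: isolates single-saccade kernels for latency tests
isolated_saccade_session <- function(n_sacc = 300, eye = "right",
                                     site = 1L, gap = 1.2) {
  arena <- arena_config()
  calib <- eye_calibration()
  axes <- remotegaze:::gaze_axes_head(calib)
  dt <- 1 / 300
  dur <- (n_sacc + 1) * gap
  n <- round(dur / dt)
  t <- (seq_len(n) - 1) * dt
  pos <- matrix(rep(c(0, 0, 54), each = n), n, 3)
  sites3 <- remotegaze:::site_positions_3d(arena)
  q_away <- quat_yaw_pitch(pi / 2)
  q_aim <- remotegaze:::aim_orientation(axes[[eye]], c(0, 0, 54),
                                        sites3[site, ])
  q <- q_away[rep(1, n), ]
  state <- rep("fixation", n)
  t_peaks <- gap * seq_len(n_sacc)
  rows <- lapply(t_peaks, function(tp) {
    i0 <- round((tp - 0.04) * 300); i1 <- round((tp + 0.04) * 300)
    state[i0:i1] <<- "saccade"
    hold <- i0:min(n, round((tp + 0.6) * 300))
    q[hold, ] <<- q_aim[rep(1, length(hold)), ]
    data.frame(t_start = t[i0], t_peak = tp, t_end = t[i1],
               amplitude = 60, duration = 0.08, gaze_site = site,
               eye = eye, frontal = FALSE)
  })
  list(trace = list(t = t, position = pos, orientation = q),
       labels = list(state = state, saccades = do.call(rbind, rows)),
       events = list(light = rep(FALSE, n), trials = data.frame()),
       task = task_config(), arena = arena, calib = calib)
}
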