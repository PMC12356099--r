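#' Specification of a synthetic neuron
#'
#' Parameters of the inhomogeneous-Poisson rate model used by
#' [rate_function()]. Excitatory cells carry a spatial (place) field
#' expressed during dashes and a gaze field expressed as biphasic
#' saccade-locked kernels: an early (predictive) Gaussian bump at
#' `early_latency` after peak saccade velocity and a late (visual) bump at
#' `late_latency`, both scaled by the Gaussian angular closeness
#' `exp(-alpha^2 / (2 tau^2))` of the landing gaze to the preferred site
#' (`tau = gaze_tuning_width`). Gaze drive is read from the contralateral
#' eye with weight `contra_fraction` and the ipsilateral eye with the
#' complement. The late bump is multiplied by `light_modulation` when the
#' target light is on at the time of the bump; the early bump by
#' `prediction_modulation` when the saccade's target is the expected task
#' target. `early_prev_dep` / `early_next_dep` expose the dependence of
#' the early response on the previous and next gaze distances (exponents
#' on the respective closenesses). Interneurons (`inh_peak`, `inh_trough`)
#' instead carry a saccade-locked quasi-oscillatory component whose phase
#' at `late_latency` is `phase_offset` (0 = peak, pi = trough).
#'
#' @param cell_type "excitatory", "inh_peak" or "inh_trough".
#' @param baseline_rate Hz.
#' @param preferred_site site index.
#' @param place_gain,gaze_gain peak rate increases, Hz.
#' @param gaze_tuning_width tau, degrees.
#' @param early_amplitude,late_amplitude relative weights of the two bumps.
#' @param early_latency,late_latency s after peak saccade velocity.
#' @param early_sd,late_sd kernel widths, s.
#' @param light_modulation gain on the late bump when the light is on.
#' @param prediction_modulation gain on the early bump when the target is
#'   expected.
#' @param early_prev_dep,early_next_dep exponents of the early bump on the
#'   previous / next gaze closeness.
#' @param contra_fraction weight of the contralateral eye in [0, 1].
#' @param phase_offset interneuron phase at `late_latency`, radians.
#' @param hemisphere recorded hemisphere ("left" or "right"); the
#'   contralateral eye is the opposite one.
#' @param place_sigma spatial field width, mm.
#' @return object of class `neuron_spec`.
#' @export
neuron_spec <- function(cell_type = c("excitatory", "inh_peak", "inh_trough"),
                        baseline_rate = 1,
                        preferred_site = 1L,
                        place_gain = 10, gaze_gain = 10,
                        gaze_tuning_width = 45,
                        early_amplitude = 1, late_amplitude = 1,
                        early_latency = 0.017, late_latency = 0.187,
                        early_sd = 0.025, late_sd = 0.04,
                        light_modulation = 1, prediction_modulation = 1,
                        early_prev_dep = 0, early_next_dep = 1,
                        contra_fraction = 1,
                        phase_offset = 0,
                        hemisphere = "left",
                        place_sigma = 80) {
  cell_type <- match.arg(cell_type)
  stopifnot(baseline_rate >= 0, gaze_tuning_width > 0,
            contra_fraction >= 0, contra_fraction <= 1,
            early_latency >= -0.1, early_latency <= 0.4,
            late_latency >= -0.1, late_latency <= 0.4)
  structure(as.list(environment()), class = "neuron_spec")
}

contra_eye <- function(hemisphere) if (hemisphere == "left") "right" else "left"

# per-saccade angular distances of each eye's gaze to every site, measured
# during the following fixation (ground-truth saccade table of a synthetic
# session)
saccade_gaze_angles <- function(session) {
  sac <- session$labels$saccades
  tr <- session$trace
  n <- nrow(sac)
  i <- pmin(findInterval(sac$t_end + 0.03, tr$t) + 1L, length(tr$t))
  rays <- gaze_rays(tr$position[i, , drop = FALSE],
                    quat_normalize(tr$orientation[i, , drop = FALSE]),
                    session$calib)
  angular_distances_to_sites(rays, session$arena)
}

#' Firing-rate function of a synthetic neuron
#'
#' Evaluates the rate model of a [neuron_spec()] on the time base of a
#' synthetic session: baseline, plus the spatial field during dashes, plus
#' saccade-locked gaze kernels (excitatory cells) or a saccade-locked
#' quasi-oscillation (interneurons). Negative values are floored at 0.
#'
#' @param spec a [neuron_spec()].
#' @param session a `synthetic_session` from [generate_session()].
#' @return numeric vector of rates (Hz), one per trace sample.
#' @export
rate_function <- function(spec, session) {
  tr <- session$trace
  n <- length(tr$t)
  dt <- tr$t[2] - tr$t[1]
  rate <- rep(spec$baseline_rate, n)
  pref <- spec$preferred_site
  # spatial field, expressed while dashing
  dashing <- session$labels$state == "dash"
  if (spec$cell_type == "excitatory" && any(dashing) && spec$place_gain > 0) {
    d2 <- (tr$position[, 1] - session$arena$site_positions[pref, 1])^2 +
      (tr$position[, 2] - session$arena$site_positions[pref, 2])^2
    rate <- rate + dashing * spec$place_gain * exp(-d2 / (2 * spec$place_sigma^2))
  }
  sac <- session$labels$saccades
  if (nrow(sac) == 0L) return(pmax(rate, 0))
  angles <- saccade_gaze_angles(session)
  tau <- spec$gaze_tuning_width
  ceye <- contra_eye(spec$hemisphere)
  ieye <- setdiff(c("left", "right"), ceye)
  closeness <- spec$contra_fraction * exp(-angles[[ceye]][, pref]^2 / (2 * tau^2)) +
    (1 - spec$contra_fraction) * exp(-angles[[ieye]][, pref]^2 / (2 * tau^2))
  if (spec$cell_type == "excitatory") {
    if (spec$gaze_gain > 0) {
      exp_target <- expected_targets(session, sac)
      light_at <- function(tt) {
        i <- pmin(pmax(round(tt / dt) + 1L, 1L), n)
        session$events$light[i]
      }
      prev_close <- c(NA, closeness[-nrow(sac)])
      for (k in seq_len(nrow(sac))) {
        cl <- closeness[k]
        if (cl < 1e-4) next
        tp <- sac$t_peak[k]
        # early (predictive) bump
        e_amp <- spec$early_amplitude * cl^spec$early_next_dep
        if (spec$early_prev_dep > 0)
          e_amp <- e_amp * (if (is.na(prev_close[k])) 0 else
            prev_close[k])^spec$early_prev_dep
        if (!is.na(exp_target[k]) && exp_target[k] == sac$gaze_site[k])
          e_amp <- e_amp * spec$prediction_modulation
        l_amp <- spec$late_amplitude * cl
        if (light_at(tp + spec$late_latency)) l_amp <- l_amp * spec$light_modulation
        w0 <- max(1L, round((tp - 0.2) / dt))
        w1 <- min(n, round((tp + 0.45) / dt))
        tt <- (w0:w1 - 1L) * dt - tp
        add <- spec$gaze_gain *
          (e_amp * exp(-(tt - spec$early_latency)^2 / (2 * spec$early_sd^2)) +
           l_amp * exp(-(tt - spec$late_latency)^2 / (2 * spec$late_sd^2)))
        rate[w0:w1] <- rate[w0:w1] + add
      }
    }
  } else {
    # interneuron: saccade-entrained quasi-oscillation
    period <- 0.27
    for (k in seq_len(nrow(sac))) {
      tp <- sac$t_peak[k]
      w0 <- max(1L, round((tp - 0.3) / dt))
      w1 <- min(n, round((tp + 0.7) / dt))
      tt <- (w0:w1 - 1L) * dt - tp
      env <- exp(-tt^2 / (2 * 0.25^2))
      rate[w0:w1] <- rate[w0:w1] + spec$gaze_gain * env *
        cos(2 * pi * (tt - spec$late_latency) / period + spec$phase_offset)
    }
  }
  pmax(rate, 0)
}

# which site the bird expects to light up at each saccade (blocked task:
# the block's target except on first-of-block and catch expectations;
# random task: unknown, NA)
expected_targets <- function(session, sac) {
  if (session$task$variant != "blocked")
    return(rep(NA_integer_, nrow(sac)))
  tri <- session$events$trials
  if (nrow(tri) == 0L) return(rep(NA_integer_, nrow(sac)))
  # a trial's target is "expected" from the second trial of its block on
  expected <- ifelse(duplicated(tri$block) , tri$target, NA_integer_)
  idx <- findInterval(sac$t_peak, c(0, tri$t_light_off[-nrow(tri)]))
  expected[pmin(pmax(idx, 1L), nrow(tri))]
}

#' Synthetic mean spike waveforms
#'
#' Parametric average waveform per cell class: a negative trough flanked
#' by two positive peaks, with trough-to-peak width and peak asymmetry set
#' to the class templates (excitatory 0.51 ms, peak-type interneuron
#' 0.27 ms, trough-type 0.33 ms; asymmetries -0.04, 0.55, 0.56).
#'
#' @param cell_type class name.
#' @param dt sample interval, s (default 1/30000).
#' @param jitter relative sd of multiplicative parameter jitter.
#' @return list with `w` (amplitude vector) and `dt`.
#' @export
synth_waveform <- function(cell_type, dt = 1 / 30000, jitter = 0.03) {
  par <- switch(cell_type,
    excitatory = list(width = 0.51e-3, asym = -0.04),
    inh_peak = list(width = 0.27e-3, asym = 0.55),
    inh_trough = list(width = 0.33e-3, asym = 0.56))
  width <- par$width * exp(stats::rnorm(1, 0, jitter))
  tt <- seq(-0.8e-3, 1.6e-3, by = dt)
  a_post <- 0.5 * (1 + par$asym + stats::rnorm(1, 0, jitter / 2))
  a_pre <- max(0.05, a_post - par$asym)
  w <- -exp(-tt^2 / (2 * (0.35 * width)^2)) +
    a_post * exp(-(tt - width)^2 / (2 * (0.6 * width)^2)) +
    a_pre * exp(-(tt + 0.6 * width)^2 / (2 * (0.5 * width)^2))
  list(w = w, dt = dt)
}

#' Generate an inhomogeneous-Poisson spike population
#'
#' Samples spike trains for a list of [neuron_spec()]s against one
#' synthetic session, by per-sample Poisson counts at the (piecewise
#' constant) rate with uniform placement within each sample. Also
#' synthesizes per-cell mean waveforms so that waveform-based
#' classification can be exercised.
#'
#' @param specs list of [neuron_spec()].
#' @param session a `synthetic_session`.
#' @param rng_seed seed for spike sampling.
#' @return list of class `spike_data`: `spikes` (list of sorted spike-time
#'   vectors), `cells` (data.frame with `cell_id`, `cell_type`,
#'   `preferred_site`, `hemisphere`, `n_spikes`), `waveforms` (list of
#'   waveform lists), `duration`.
#' @export
generate_spike_population <- function(specs, session, rng_seed = 1L) {
  set.seed(rng_seed)
  tr <- session$trace
  dt <- tr$t[2] - tr$t[1]
  spikes <- vector("list", length(specs))
  wfs <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    r <- rate_function(specs[[j]], session)
    cnt <- stats::rpois(length(r), r * dt)
    idx <- rep.int(seq_along(cnt), cnt)
    st <- tr$t[idx] + stats::runif(length(idx), 0, dt)
    spikes[[j]] <- sort(st)
    wfs[[j]] <- synth_waveform(specs[[j]]$cell_type)
  }
  cells <- data.frame(
    cell_id = seq_along(specs),
    cell_type = vapply(specs, `[[`, "", "cell_type"),
    preferred_site = vapply(specs, function(s) as.integer(s$preferred_site), 0L),
    hemisphere = vapply(specs, `[[`, "", "hemisphere"),
    n_spikes = vapply(spikes, length, 0L))
  structure(list(spikes = spikes, cells = cells, waveforms = wfs,
                 duration = max(tr$t) + dt),
            class = "spike_data")
}
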