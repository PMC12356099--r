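#' Gaussian angular basis value
#'
#' `x = exp(-alpha^2 / (2 tau^2))` by default; setting
#' `denom_2tau2 = FALSE` uses `exp(-alpha^2 / tau^2)` for sensitivity
#' checks against the alternative reading of the basis formula.
#'
#' @param alpha angular distance, degrees.
#' @param tau length constant, degrees.
#' @param denom_2tau2 logical, see above.
#' @return basis values in (0, 1].
#' @export
gaussian_basis <- function(alpha, tau, denom_2tau2 = TRUE) {
  if (tau <= 0) stop("tau must be positive")
  if (denom_2tau2) exp(-alpha^2 / (2 * tau^2)) else exp(-alpha^2 / tau^2)
}

#' Design matrix of the gaze GLM
#'
#' One row per included saccade (the gaze-analysis inclusion set:
#' `gaze_included` saccades). The response `y` is the spike count in the
#' `[-0.1, +0.3]` s window around peak saccade velocity. The regressors
#' are the Gaussian basis values of the angular distances of each of the
#' four outer sites from the contralateral eye's gaze (columns c1..c4)
#' and from the ipsilateral eye's gaze (i1..i4), measured during the
#' landing fixation. Both eyes' angles enter every row: simultaneous
#' two-site gaze is exactly what the model separates.
#'
#' @param spike_times sorted spike times of one cell.
#' @param segments a `segment_table`.
#' @param trace head-pose trace.
#' @param arena an [arena_config()].
#' @param calib an [eye_calibration()].
#' @param hemisphere recorded hemisphere ("left"/"right").
#' @param tau basis length constant, degrees.
#' @param window count window, s relative to peak velocity.
#' @param denom_2tau2 basis convention switch.
#' @return list of class `glm_design`: `X` (n x 8), `y` (counts),
#'   `t_peak`, `site` (landing site), `tau`.
#' @export
build_gaze_design <- function(spike_times, segments, trace, arena, calib,
                              hemisphere = "left", tau = 45,
                              window = c(-0.1, 0.3), denom_2tau2 = TRUE) {
  if (tau <= 0) stop("tau must be positive")
  s <- segments[segments$state == "saccade" & segments$gaze_included, ,
                drop = FALSE]
  if (nrow(s) == 0L) stop("no included saccades")
  dt <- trace$t[2] - trace$t[1]
  i <- pmin(findInterval(s$t_end + 0.03, trace$t) + 1L, length(trace$t))
  rays <- gaze_rays(trace$position[i, , drop = FALSE],
                    quat_normalize(trace$orientation[i, , drop = FALSE]),
                    calib)
  ang <- angular_distances_to_sites(rays, arena)
  ceye <- contra_eye(hemisphere)
  ieye <- setdiff(c("left", "right"), ceye)
  outer_sites <- arena$outer_sites
  X <- cbind(gaussian_basis(ang[[ceye]][, outer_sites, drop = FALSE], tau,
                            denom_2tau2),
             gaussian_basis(ang[[ieye]][, outer_sites, drop = FALSE], tau,
                            denom_2tau2))
  colnames(X) <- c(paste0("c", seq_along(outer_sites)),
                   paste0("i", seq_along(outer_sites)))
  y <- findInterval(s$t_peak + window[2], spike_times) -
    findInterval(s$t_peak + window[1], spike_times)
  structure(list(X = X, y = y, t_peak = s$t_peak, site = s$landing_site,
                 tau = tau), class = "glm_design")
}

#' Poisson lasso fit of the gaze GLM
#'
#' Minimizes the Poisson negative log-likelihood plus an L1 penalty
#' `lambda` on the eight basis coefficients (intercept unpenalized,
#' regressors not standardized: the basis is already bounded in (0, 1]).
#'
#' @param design a `glm_design` (or list with `X`, `y`).
#' @param lambda L1 penalty (default 0.005).
#' @param min_rows minimum number of saccades required.
#' @return list of class `glm_fit`: `beta0` (intercept), `beta` (named
#'    8-vector), `c` and `i` (per-site contralateral/ipsilateral
#'   coefficients), `deviance`, `lambda`.
#' @export
fit_poisson_lasso <- function(design, lambda = 0.005, min_rows = 20) {
  X <- design$X; y <- design$y
  if (length(y) < min_rows)
    stop(sprintf("need >= %d saccades, got %d", min_rows, length(y)))
  if (any(y < 0) || any(y != round(y)))
    stop("y must contain non-negative integer counts")
  if (all(y == 0)) {
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    nh <- ncol(X) / 2
    return(structure(list(beta0 = -Inf, beta = beta,
                          c = beta[seq_len(nh)], i = beta[nh + seq_len(nh)],
                          deviance = 0, lambda = lambda),
                     class = "glm_fit"))
  }
  fit <- glmnet::glmnet(X, y, family = "poisson", alpha = 1,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  beta <- as.numeric(fit$beta[, 1])
  names(beta) <- rownames(fit$beta)
  if (any(!is.finite(beta)))
    stop("Poisson lasso did not converge to finite coefficients")
  nh <- ncol(X) / 2
  structure(list(beta0 = as.numeric(fit$a0), beta = beta,
                 c = beta[seq_len(nh)], i = beta[nh + seq_len(nh)],
                 deviance = (1 - fit$dev.ratio) * fit$nulldev,
                 lambda = lambda),
            class = "glm_fit")
}

#' Normalized contralateral-ipsilateral difference
#'
#' `(c - i) / (c + i)`, in [-1, 1] for non-negative coefficients;
#' undefined (NA) when `c + i = 0`.
#'
#' @param c,i contralateral and ipsilateral coefficients.
#' @return numeric vector.
#' @export
normalized_difference <- function(c, i) {
  out <- (c - i) / (c + i)
  out[c + i == 0] <- NA_real_
  out
}

#' Fit the gaze GLM for every cell of a population
#'
#' @param population a `spike_data`.
#' @param segments a `segment_table`.
#' @param trace head-pose trace.
#' @param arena an [arena_config()]; `calib` an [eye_calibration()].
#' @param calib an [eye_calibration()].
#' @param tau,lambda basis length constant and penalty.
#' @return data.frame: per cell `beta0`, `c1..c4`, `i1..i4`,
#'   `preferred_site` (largest contralateral coefficient), `norm_diff`
#'   (normalized difference at the preferred site), `deviance`.
#' @export
gaze_glm_population <- function(population, segments, trace, arena, calib,
                                tau = 45, lambda = 0.005) {
  rows <- lapply(seq_along(population$spikes), function(j) {
    des <- build_gaze_design(population$spikes[[j]], segments, trace,
                             arena, calib,
                             hemisphere = population$cells$hemisphere[j],
                             tau = tau)
    fit <- fit_poisson_lasso(des, lambda = lambda)
    pref <- which.max(fit$c)
    out <- data.frame(cell_id = population$cells$cell_id[j],
                      beta0 = fit$beta0, deviance = fit$deviance,
                      preferred_site = pref,
                      norm_diff = normalized_difference(fit$c[pref],
                                                        fit$i[pref]))
    cf <- as.data.frame(as.list(fit$beta))
    cbind(out, cf)
  })
  do.call(rbind, rows)
}

#' GLM control for light-state tuning
#'
#' Poisson GLM of per-saccade spike counts on gaze-site identity and the
#' state of the viewed light cue, with two-sided log-likelihood-ratio
#' tests for each factor against the nested model without it.
#'
#' @param counts per-saccade spike counts.
#' @param site gaze-site factor per saccade.
#' @param light logical light state per saccade.
#' @param alpha significance level.
#' @return list with `p_site`, `p_light`, `sig_site`, `sig_light`.
#' @export
light_tuning_glm <- function(counts, site, light, alpha = 0.05) {
  if (length(unique(light)) < 2)
    stop("both light states must be represented")
  d <- data.frame(y = counts, site = factor(site), light = light)
  full <- stats::glm(y ~ site + light, family = stats::poisson(), data = d)
  no_site <- stats::glm(y ~ light, family = stats::poisson(), data = d)
  no_light <- stats::glm(y ~ site, family = stats::poisson(), data = d)
  lrt <- function(small, big, df) {
    stat <- 2 * (as.numeric(stats::logLik(big)) -
                   as.numeric(stats::logLik(small)))
    stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  }
  p_site <- lrt(no_site, full, df = nlevels(d$site) - 1)
  p_light <- lrt(no_light, full, df = 1)
  list(p_site = p_site, p_light = p_light,
       sig_site = p_site < alpha, sig_light = p_light < alpha)
}

#' Source and target tuning in the all-to-all task
#'
#' Baseline-subtracted responses in the pentagon arena: dash response is
#' the mean rate in a +/-0.5 s window centered on the dash end minus the
#' mean rate from -2 s to -1 s; saccade response is the mean rate 0 to
#' +0.3 s after peak velocity minus the mean from -1 s to -0.2 s.
#' Five-point tuning curves are formed by the target site and by the
#' source site, for dashes (place) and saccades (gaze); selectivity is
#' the curve maximum minus the curve mean. Cells lacking `min_per_pair`
#' saccades and dashes for every ordered source-target pair are excluded.
#'
#' @param spike_times one cell's spike times.
#' @param segments a `segment_table` from a pentagon session.
#' @param arena pentagon [arena_config()].
#' @param min_per_pair minimum events per source-target pair.
#' @return list with `included`, `reason`, and when included: `target`
#'   and `source` lists each holding `dash` and `gaze` 5-point curves,
#'   plus `selectivity` (data.frame).
#' @export
all_to_all_analysis <- function(spike_times, segments, arena,
                                min_per_pair = 4) {
  d <- segments[segments$state == "dash", , drop = FALSE]
  s <- segments[segments$state == "saccade" & segments$gaze_included, ,
                drop = FALSE]
  # source of a saccade = site the bird sits on (the site of the
  # enclosing fixation bout); use the nearest preceding dash destination
  sac_src <- vapply(s$t_peak, function(tp) {
    prior <- d[d$t_end <= tp, , drop = FALSE]
    if (nrow(prior) == 0L) NA_integer_ else prior$dst[nrow(prior)]
  }, 0L)
  pairs <- expand.grid(src = seq_len(nrow(arena$site_positions)),
                       dst = seq_len(nrow(arena$site_positions)))
  pairs <- pairs[pairs$src != pairs$dst, ]
  for (r in seq_len(nrow(pairs))) {
    nd <- sum(d$src == pairs$src[r] & d$dst == pairs$dst[r], na.rm = TRUE)
    ns <- sum(sac_src == pairs$src[r] & s$landing_site == pairs$dst[r],
              na.rm = TRUE)
    if (nd < min_per_pair || ns < min_per_pair)
      return(list(included = FALSE,
                  reason = sprintf("pair %d->%d has %d dashes / %d saccades",
                                   pairs$src[r], pairs$dst[r], nd, ns)))
  }
  mean_rate <- function(t0, t1) {
    if (t1 <= t0) return(0)
    sum(spike_times >= t0 & spike_times < t1) / (t1 - t0)
  }
  dash_resp <- vapply(d$t_end, function(te)
    mean_rate(te - 0.5, te + 0.5) - mean_rate(te - 2, te - 1), 0)
  gaze_resp <- vapply(s$t_peak, function(tp)
    mean_rate(tp, tp + 0.3) - mean_rate(tp - 1, tp - 0.2), 0)
  sites <- seq_len(nrow(arena$site_positions))
  curve <- function(resp, lab) vapply(sites, function(k)
    mean(resp[lab == k], na.rm = TRUE), 0)
  target <- list(dash = curve(dash_resp, d$dst),
                 gaze = curve(gaze_resp, s$landing_site))
  source <- list(dash = curve(dash_resp, d$src),
                 gaze = curve(gaze_resp, sac_src))
  sely <- function(v) max(v) - mean(v)
  selectivity <- data.frame(
    axis = c("target", "target", "source", "source"),
    modality = c("dash", "gaze", "dash", "gaze"),
    selectivity = c(sely(target$dash), sely(target$gaze),
                    sely(source$dash), sely(source$gaze)),
    peak = c(max(target$dash), max(target$gaze),
             max(source$dash), max(source$gaze)))
  list(included = TRUE, reason = "", target = target, source = source,
       selectivity = selectivity)
}

#' Population Gaussian decay of gaze responses with distance
#'
#' Pools per-saccade responses across cells as a function of the angular
#' distance between the contralateral eye's gaze and each cell's
#' preferred site, averages normalized responses in distance bins, and
#' fits a Gaussian decay `a exp(-d^2 / (2 tau^2)) + c`. The fitted
#' length constant estimates the gaze-tuning width.
#'
#' @param population a `spike_data`.
#' @param segments a `segment_table`.
#' @param trace head-pose trace.
#' @param arena an [arena_config()].
#' @param calib an [eye_calibration()].
#' @param preferred_sites per-cell preferred site indices (as measured by
#'   the tuning pipeline).
#' @param breaks distance bin edges, degrees.
#' @param window count window, s relative to peak saccade velocity.
#' @return list with `tau` (degrees), `curve` (data.frame of bin centers
#'   and mean normalized responses), `fit` (the `nls` object).
#' @export
population_gaussian_decay <- function(population, segments, trace, arena,
                                      calib, preferred_sites,
                                      breaks = seq(0, 180, by = 10),
                                      window = c(-0.1, 0.3)) {
  s <- segments[segments$state == "saccade" & segments$gaze_included, ,
                drop = FALSE]
  if (nrow(s) == 0L) stop("no included saccades")
  i <- pmin(findInterval(s$t_end + 0.03, trace$t) + 1L, length(trace$t))
  rays <- gaze_rays(trace$position[i, , drop = FALSE],
                    quat_normalize(trace$orientation[i, , drop = FALSE]),
                    calib)
  ang <- angular_distances_to_sites(rays, arena)
  ctr <- (breaks[-1] + breaks[-length(breaks)]) / 2
  curves <- matrix(NA_real_, length(population$spikes), length(ctr))
  nbin <- rep(0, length(ctr))
  for (j in seq_along(population$spikes)) {
    st <- population$spikes[[j]]
    ceye <- contra_eye(population$cells$hemisphere[j])
    d <- ang[[ceye]][, preferred_sites[j]]
    cnt <- findInterval(s$t_peak + window[2], st) -
      findInterval(s$t_peak + window[1], st)
    b <- cut(d, breaks, right = FALSE)
    m <- tapply(cnt, b, mean)
    nbin <- nbin + as.numeric(table(b))
    mx <- max(m, na.rm = TRUE)
    if (is.finite(mx) && mx > 0) curves[j, ] <- as.numeric(m) / mx
  }
  y <- colMeans(curves, na.rm = TRUE)
  ok <- is.finite(y)
  # weight bins by how many saccades they hold: sparse bins carry little
  # evidence and are dominated by landing-measurement noise
  df <- data.frame(d = ctr[ok], y = y[ok], w = nbin[ok])
  fit <- stats::nls(y ~ a * exp(-d^2 / (2 * tau^2)) + c0, data = df,
                    start = list(a = max(df$y) - min(df$y), tau = 30,
                                 c0 = min(df$y)),
                    weights = df$w,
                    control = stats::nls.control(maxiter = 200))
  list(tau = abs(stats::coef(fit)[["tau"]]), curve = df, fit = fit)
}
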