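#' Site information statistic
#'
#' Information about site identity conveyed by a cell's firing, in
#' bits/spike: `I = sum_x (lambda(x)/lbar) log2(lambda(x)/lbar) p(x)` with
#' `lbar = sum_x lambda(x) p(x)`, using the convention `0 log 0 = 0`. If
#' the overall mean rate is zero the statistic is undefined and `NA` is
#' returned with attribute `uninformative = TRUE`.
#'
#' @param lambda mean rate per site, Hz (non-negative).
#' @param p visit probability per site (sums to 1).
#' @return information in bits/spike (>= 0), or flagged `NA`.
#' @export
site_information <- function(lambda, p) {
  stopifnot(length(lambda) == length(p), all(lambda >= 0), all(p >= 0),
            abs(sum(p) - 1) < 1e-8)
  lbar <- sum(lambda * p)
  if (lbar == 0) {
    out <- NA_real_
    attr(out, "uninformative") <- TRUE
    return(out)
  }
  ratio <- lambda / lbar
  terms <- ifelse(ratio > 0, ratio * log2(ratio) * p, 0)
  sum(terms)
}

#' Per-event responses for dash (place) tuning
#'
#' Mean firing rate of one cell in a +/- `half_window` s window centered
#' on the end of each dash to an outer site.
#'
#' @param spike_times sorted spike times, s.
#' @param segments a `segment_table`.
#' @param arena an [arena_config()].
#' @param half_window window half width, s.
#' @return data.frame with `site` and `rate` (Hz), one row per dash.
#' @export
dash_responses <- function(spike_times, segments, arena, half_window = 1) {
  d <- segments[segments$state == "dash" &
                  segments$dst %in% arena$outer_sites, , drop = FALSE]
  if (nrow(d) == 0L) return(data.frame(site = integer(), rate = numeric()))
  rate <- (findInterval(d$t_end + half_window, spike_times) -
             findInterval(d$t_end - half_window, spike_times)) /
    (2 * half_window)
  data.frame(site = d$dst, rate = rate)
}

#' Per-event responses for gaze tuning
#'
#' Spike counts of one cell in the `[-0.1, +0.3]` s window around peak
#' saccade velocity, for saccades that landed on a site (within 20 degrees
#' of visual angle) and occurred more than 0.5 s before the next dash
#' (`gaze_included` saccades), optionally restricted to one landing eye.
#'
#' @param spike_times sorted spike times.
#' @param segments a `segment_table`.
#' @param eye `NULL` for both eyes, or "left"/"right".
#' @param window response window relative to peak velocity, s.
#' @return data.frame with `site`, `eye`, `t_peak`, `count` and `rate`.
#' @export
gaze_responses <- function(spike_times, segments, eye = NULL,
                           window = c(-0.1, 0.3)) {
  s <- segments[segments$state == "saccade" & segments$gaze_included, ,
                drop = FALSE]
  if (!is.null(eye)) s <- s[!is.na(s$landing_eye) & s$landing_eye == eye, ,
                            drop = FALSE]
  if (nrow(s) == 0L)
    return(data.frame(site = integer(), eye = character(),
                      t_peak = numeric(), count = integer(),
                      rate = numeric()))
  cnt <- findInterval(s$t_peak + window[2], spike_times) -
    findInterval(s$t_peak + window[1], spike_times)
  data.frame(site = s$landing_site, eye = s$landing_eye, t_peak = s$t_peak,
             count = cnt, rate = cnt / diff(window))
}

#' Tuning curve over sites from per-event responses
#'
#' @param responses data.frame with `site` and `rate`.
#' @param sites site indices the curve is defined over.
#' @return list with `lambda` (mean rate per site), `p` (visit
#'   probabilities), `n` (events per site).
#' @export
tuning_curve <- function(responses, sites) {
  n <- vapply(sites, function(s) sum(responses$site == s), 0)
  lambda <- vapply(sites, function(s) {
    r <- responses$rate[responses$site == s]
    if (length(r)) mean(r) else 0
  }, 0)
  list(lambda = lambda, p = if (sum(n) > 0) n / sum(n) else rep(0, length(n)),
       n = n, sites = sites)
}

#' Shuffle test for site information
#'
#' Permutes event site labels across events (per-site event counts
#' preserved), recomputing the information statistic `n_shuffles` times.
#' A cell is significant when its actual information exceeds the
#' `1 - alpha` fraction of the shuffled samples; normalized information is
#' the actual value divided by the shuffle mean.
#'
#' @param responses data.frame with `site` and `rate` per event.
#' @param sites site set.
#' @param n_shuffles permutations (200 by default).
#' @param alpha significance level (0.01).
#' @return list of class `information_result`: `information`,
#'   `normalized_information`, `p_value` (computed as
#'   `(1 + #\{shuffles >= actual\}) / (n_shuffles + 1)`), `significant`,
#'   `shuffle_mean`, `shuffle_q99`, `n_events`.
#' @export
shuffle_significance <- function(responses, sites, n_shuffles = 200,
                                 alpha = 0.01) {
  if (length(unique(responses$site)) < 2)
    stop("shuffle test requires events at >= 2 distinct sites")
  tc <- tuning_curve(responses, sites)
  actual <- site_information(tc$lambda, tc$p)
  shuf <- numeric(n_shuffles)
  r <- responses
  for (b in seq_len(n_shuffles)) {
    r$site <- sample(responses$site)
    tcb <- tuning_curve(r, sites)
    shuf[b] <- site_information(tcb$lambda, tcb$p)
  }
  ok <- !is.na(shuf)
  pval <- (1 + sum(shuf[ok] >= actual)) / (sum(ok) + 1)
  structure(list(information = actual,
                 normalized_information =
                   if (mean(shuf[ok]) > 0) actual / mean(shuf[ok]) else NA_real_,
                 p_value = pval,
                 significant = !is.na(actual) &&
                   mean(shuf[ok] < actual) > 1 - alpha,
                 shuffle_mean = mean(shuf[ok]),
                 shuffle_q99 = stats::quantile(shuf[ok], 0.99, names = FALSE),
                 n_events = nrow(responses)),
            class = "information_result")
}

#' Selectivity index
#'
#' Responses are normalized by the largest response; the index is the
#' normalized difference between the largest and second-largest response,
#' `1 - r2`, in [0, 1].
#'
#' @param responses per-site responses (>= 2 sites).
#' @return list with `index`, `preferred` (lowest index on ties), `r2`.
#' @export
selectivity_index <- function(responses) {
  stopifnot(length(responses) >= 2)
  m <- max(responses)
  if (m <= 0) {
    return(list(index = NA_real_, preferred = NA_integer_, r2 = NA_real_,
                undefined = TRUE))
  }
  r <- responses / m
  preferred <- which.max(r)   # which.max takes the lowest index on ties
  r2 <- max(r[-preferred])
  list(index = 1 - r2, preferred = preferred, r2 = r2, undefined = FALSE)
}

#' Preferred-site match statistics
#'
#' Fraction of cells whose preferred place site equals their preferred
#' gaze site, with a chance distribution obtained by scrambling cell
#' identities between the two preference lists.
#'
#' @param pref_place,pref_gaze integer vectors of preferred sites.
#' @param n_scrambles number of identity scrambles.
#' @return list with `match_fraction`, `chance` (vector of scrambled
#'   match fractions), `chance_mean`.
#' @export
preferred_match_stats <- function(pref_place, pref_gaze,
                                  n_scrambles = 1000) {
  stopifnot(length(pref_place) == length(pref_gaze),
            length(pref_place) > 0)
  match_fraction <- mean(pref_place == pref_gaze)
  chance <- vapply(seq_len(n_scrambles), function(b)
    mean(pref_place == sample(pref_gaze)), 0)
  list(match_fraction = match_fraction, chance = chance,
       chance_mean = mean(chance))
}

#' Correlation of place and gaze tuning curves
#'
#' Pearson correlation of each cell's two curves over the same sites,
#' with a null distribution from scrambling cell identities (pairing each
#' cell's place curve with another cell's gaze curve). Zero-variance
#' curves yield `NA` and are excluded from summaries.
#'
#' @param place_curves,gaze_curves matrices, cells x sites.
#' @param n_scrambles identity scrambles for the null.
#' @return list with `r` (per-cell), `null` (scrambled correlations,
#'   pooled), `n_excluded`.
#' @export
tuning_correlation <- function(place_curves, gaze_curves,
                               n_scrambles = 100) {
  stopifnot(all(dim(place_curves) == dim(gaze_curves)))
  rowcor <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      x <- a[i, ]; y <- b[i, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
      else stats::cor(x, y)
    }, 0)
  }
  r <- rowcor(place_curves, gaze_curves)
  null <- unlist(lapply(seq_len(n_scrambles), function(b)
    rowcor(place_curves, gaze_curves[sample(nrow(gaze_curves)), ,
                                     drop = FALSE])))
  list(r = r, null = null[!is.na(null)], n_excluded = sum(is.na(r)))
}

# ---- rate maps -------------------------------------------------------------

hamming_kernel2d <- function(k) {
  h <- 0.54 - 0.46 * cos(2 * pi * seq(0, k - 1) / (k - 1))
  K <- outer(h, h)
  K / sum(K)
}

# 2D convolution with kernel renormalized over a validity mask (edge and
# out-of-arena handling)
conv2d_masked <- function(M, K, mask) {
  n <- nrow(M); m <- ncol(M); hk <- (nrow(K) - 1) / 2
  out <- matrix(0, n, m)
  Mm <- M * mask
  for (i in seq_len(n)) {
    i0 <- max(1, i - hk); i1 <- min(n, i + hk)
    ki <- (i0:i1) - i + hk + 1
    for (j in seq_len(m)) {
      j0 <- max(1, j - hk); j1 <- min(m, j + hk)
      kj <- (j0:j1) - j + hk + 1
      Ksub <- K[ki, kj, drop = FALSE]
      w <- sum(Ksub * mask[i0:i1, j0:j1])
      if (w > 0)
        out[i, j] <- sum(Ksub * Mm[i0:i1, j0:j1]) / w
    }
  }
  out
}

arena_bin_index <- function(xy, arena, n_bins = 40) {
  half <- arena$arena_side / 2
  edges <- seq(-half, half, length.out = n_bins + 1)
  ix <- findInterval(xy[, 1], edges, rightmost.closed = TRUE)
  iy <- findInterval(xy[, 2], edges, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= n_bins & iy >= 1 & iy <= n_bins
  list(ix = ix, iy = iy, ok = ok)
}

#' Place rate map from dash trajectories
#'
#' Spike counts and occupancy accumulated on a 40 x 40 grid over the
#' arena, restricted to dashes plus a +/-1 s window around each dash, each
#' smoothed with an 11 x 11 Hamming kernel (unit sum, renormalized over
#' visited bins at edges) and divided. The spike train is shifted by each
#' candidate offset in `offsets` and the offset maximizing the map's
#' spatial information is kept.
#'
#' @param spike_times sorted spike times.
#' @param trace head-pose trace.
#' @param segments a `segment_table`.
#' @param arena an [arena_config()].
#' @param offsets candidate spike-behavior delays, s.
#' @param n_bins grid size.
#' @param kernel smoothing kernel size (odd).
#' @return list of class `rate_map`: `rate`, `occupancy`, `count`
#'   (matrices), `mask` (visited bins), `offset` (chosen delay),
#'   `information` (bits/spike at the chosen offset).
#' @export
place_rate_map <- function(spike_times, trace, segments, arena,
                           offsets = seq(-0.3, 0.3, by = 1 / 30),
                           n_bins = 40, kernel = 11) {
  d <- segments[segments$state == "dash", , drop = FALSE]
  if (nrow(d) == 0L) stop("place map requires at least one dash")
  dt <- trace$t[2] - trace$t[1]
  sel <- rep(FALSE, length(trace$t))
  for (k in seq_len(nrow(d))) {
    i0 <- max(1L, floor((d$t_start[k] - 1) / dt) + 1L)
    i1 <- min(length(sel), ceiling((d$t_end[k] + 1) / dt))
    sel[i0:i1] <- TRUE
  }
  if (!any(sel)) stop("zero occupancy in the dash windows")
  bi <- arena_bin_index(trace$position[sel, 1:2, drop = FALSE], arena,
                        n_bins)
  occ <- matrix(0, n_bins, n_bins)
  occ_idx <- cbind(bi$ix[bi$ok], bi$iy[bi$ok])
  for (r in seq_len(nrow(occ_idx)))
    occ[occ_idx[r, 1], occ_idx[r, 2]] <- occ[occ_idx[r, 1], occ_idx[r, 2]] + dt
  mask <- occ > 0
  K <- hamming_kernel2d(kernel)
  occ_s <- conv2d_masked(occ, K, mask)
  best <- NULL
  sel_t <- trace$t[sel]
  for (off in offsets) {
    st <- spike_times - off
    i <- findInterval(st, trace$t)
    i <- i[i >= 1 & i <= length(sel)]
    i <- i[sel[i]]
    cnt <- matrix(0, n_bins, n_bins)
    if (length(i)) {
      bs <- arena_bin_index(trace$position[i, 1:2, drop = FALSE], arena,
                            n_bins)
      ci <- cbind(bs$ix[bs$ok], bs$iy[bs$ok])
      for (r in seq_len(nrow(ci)))
        cnt[ci[r, 1], ci[r, 2]] <- cnt[ci[r, 1], ci[r, 2]] + 1
    }
    cnt_s <- conv2d_masked(cnt, K, mask)
    rate <- matrix(0, n_bins, n_bins)
    rate[mask & occ_s > 0] <- cnt_s[mask & occ_s > 0] / occ_s[mask & occ_s > 0]
    info <- map_information(rate, occ_s, mask)
    if (is.null(best) || (!is.na(info) && info > best$information))
      best <- list(rate = rate, occupancy = occ_s, count = cnt_s,
                   mask = mask, offset = off, information = info)
  }
  class(best) <- "rate_map"
  best
}

map_information <- function(rate, occ, mask) {
  p <- occ[mask] / sum(occ[mask])
  site_information(rate[mask], p)
}

#' Gaze rate map from cone-projected fixations
#'
#' During gaze fixations made at the center site, a cone of
#' `cone_radius` degrees around the selected eye's gaze is projected on
#' the floor; occupancy and spike counts are accumulated over the
#' intersected bins (unit weight per sample split uniformly), smoothed
#' with a 9 x 9 Hamming kernel and divided.
#'
#' @param spike_times sorted spike times.
#' @param trace head-pose trace.
#' @param segments a `segment_table`.
#' @param arena an [arena_config()] (x_shape).
#' @param calib an [eye_calibration()].
#' @param eye "left" or "right".
#' @param cone_radius cone half-angle, degrees.
#' @param n_bins grid size; `kernel` smoothing size.
#' @param stride sample stride for occupancy accumulation (>= 1).
#' @param kernel smoothing kernel size (odd).
#' @return a `rate_map` (no offset search).
#' @export
gaze_rate_map <- function(spike_times, trace, segments, arena, calib,
                          eye = "left", cone_radius = 10, n_bins = 40,
                          kernel = 9, stride = 2L) {
  f <- segments[segments$state == "fixation" &
                  segments$site %in% arena$center_site_index, ,
                drop = FALSE]
  if (nrow(f) == 0L) stop("gaze map requires fixations at the center site")
  dt <- trace$t[2] - trace$t[1]
  sel <- rep(FALSE, length(trace$t))
  for (k in seq_len(nrow(f))) {
    i0 <- max(1L, floor(f$t_start[k] / dt) + 1L)
    i1 <- min(length(sel), ceiling(f$t_end[k] / dt))
    sel[i0:i1] <- TRUE
  }
  idx <- which(sel)
  idx_occ <- idx[seq(1, length(idx), by = stride)]
  rays <- gaze_rays(trace$position[idx_occ, , drop = FALSE],
                    quat_normalize(trace$orientation[idx_occ, , drop = FALSE]),
                    calib)[[eye]]
  occ <- matrix(0, n_bins, n_bins)
  for (r in seq_along(idx_occ)) {
    w <- project_gaze_to_floor(rays$origin[r, ], rays$direction[r, ],
                               cone_radius, arena, n_bins)
    occ <- occ + w * dt * stride
  }
  # spikes assigned to the cone of their containing sample
  cnt <- matrix(0, n_bins, n_bins)
  si <- findInterval(spike_times, trace$t)
  si <- si[si >= 1 & si <= length(sel)]
  si <- si[sel[si]]
  if (length(si)) {
    rays_s <- gaze_rays(trace$position[si, , drop = FALSE],
                        quat_normalize(trace$orientation[si, , drop = FALSE]),
                        calib)[[eye]]
    for (r in seq_along(si)) {
      w <- project_gaze_to_floor(rays_s$origin[r, ], rays_s$direction[r, ],
                                 cone_radius, arena, n_bins)
      cnt <- cnt + w
    }
  }
  mask <- occ > 0
  K <- hamming_kernel2d(kernel)
  occ_s <- conv2d_masked(occ, K, mask)
  cnt_s <- conv2d_masked(cnt, K, mask)
  rate <- matrix(0, n_bins, n_bins)
  rate[mask & occ_s > 0] <- cnt_s[mask & occ_s > 0] / occ_s[mask & occ_s > 0]
  structure(list(rate = rate, occupancy = occ_s, count = cnt_s,
                 mask = mask, offset = 0,
                 information = map_information(rate, occ_s, mask)),
            class = "rate_map")
}

#' Per-cell place and gaze tuning summary
#'
#' Runs the dash- and gaze-response tuning analyses for every cell of a
#' spike population against one segmented session: tuning curves over the
#' outer sites, information with shuffle significance, selectivity, and
#' preferred sites (contralateral eye for gaze).
#'
#' @param population a `spike_data`.
#' @param segments a `segment_table`.
#' @param arena an [arena_config()].
#' @param n_shuffles shuffle repetitions.
#' @return data.frame, one row per cell, with place/gaze information,
#'   normalized information, p-values, significance flags, preferred
#'   sites and selectivity indices; tuning curves as attribute `curves`
#'   (list of `place` and `gaze` matrices).
#' @export
tuning_summary <- function(population, segments, arena, n_shuffles = 200) {
  sites <- arena$outer_sites
  nc <- length(population$spikes)
  place_m <- matrix(NA_real_, nc, length(sites))
  gaze_m <- matrix(NA_real_, nc, length(sites))
  rows <- vector("list", nc)
  for (j in seq_len(nc)) {
    st <- population$spikes[[j]]
    hemi <- population$cells$hemisphere[j]
    ceye <- contra_eye(hemi)
    dr <- dash_responses(st, segments, arena)
    gr <- gaze_responses(st, segments, eye = ceye)
    tc_p <- tuning_curve(dr, sites)
    tc_g <- tuning_curve(gr, sites)
    place_m[j, ] <- tc_p$lambda
    gaze_m[j, ] <- tc_g$lambda
    sp <- shuffle_significance(dr, sites, n_shuffles)
    sg <- shuffle_significance(gr, sites, n_shuffles)
    sel_p <- selectivity_index(tc_p$lambda)
    sel_g <- selectivity_index(tc_g$lambda)
    rows[[j]] <- data.frame(
      cell_id = population$cells$cell_id[j],
      I_place = sp$information, norm_I_place = sp$normalized_information,
      p_place = sp$p_value, sig_place = sp$significant,
      I_gaze = sg$information, norm_I_gaze = sg$normalized_information,
      p_gaze = sg$p_value, sig_gaze = sg$significant,
      preferred_place = sel_p$preferred, preferred_gaze = sel_g$preferred,
      select_place = sel_p$index, select_gaze = sel_g$index)
  }
  out <- do.call(rbind, rows)
  attr(out, "curves") <- list(place = place_m, gaze = gaze_m)
  out
}
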