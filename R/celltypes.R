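#' Waveform features for cell-type classification
#'
#' The four electrophysiological characteristics used to separate
#' putative excitatory from inhibitory cells: log-transformed mean spike
#' rate, spike width (time from the trough of the mean waveform to the
#' subsequent peak), spike asymmetry (relative height of the two positive
#' peaks flanking the trough, `(post - pre) / (post + pre)`), and the
#' log-transformed ratio of the peak to the trough amplitude of the
#' waveform derivative.
#'
#' @param waveform mean waveform amplitudes (trough negative).
#' @param dt waveform sample interval, s.
#' @param mean_rate session mean firing rate, Hz.
#' @param n_spikes spike count (cells with fewer than `min_spikes` are
#'   flagged excluded).
#' @param min_spikes exclusion threshold (500).
#' @return list of class `waveform_features`: `log_rate`, `spike_width`
#'   (s), `asymmetry`, `log_deriv_ratio`, `excluded`.
#' @export
extract_waveform_features <- function(waveform, dt, mean_rate,
                                      n_spikes = Inf, min_spikes = 500) {
  n <- length(waveform)
  it <- which.min(waveform)
  if (it == 1L || it == n || waveform[it] >= 0)
    stop("waveform has no detectable trough")
  after <- waveform[(it + 1L):n]
  ip <- it + which.max(after)
  if (ip <= it || after[ip - it] <= waveform[it])
    stop("waveform has no peak after the trough")
  width <- (ip - it) * dt
  a_post <- max(after)
  a_pre <- max(waveform[1:(it - 1L)])
  asym <- (a_post - a_pre) / (a_post + a_pre)
  dw <- diff(waveform)
  log_dr <- log10(max(dw) / abs(min(dw)))
  structure(list(log_rate = log10(max(mean_rate, 1e-3)),
                 spike_width = width, asymmetry = asym,
                 log_deriv_ratio = log_dr,
                 excluded = n_spikes < min_spikes),
            class = "waveform_features")
}

features_matrix <- function(features) {
  do.call(rbind, lapply(features, function(f)
    c(log_rate = f$log_rate, spike_width = f$spike_width * 1e3,
      asymmetry = f$asymmetry, log_deriv_ratio = f$log_deriv_ratio)))
}

#' Excitatory/inhibitory classification by Gaussian mixture
#'
#' Fits a two-component Gaussian mixture in the 4D waveform-feature space
#' on a curated fit set, then assigns every cell to the nearer component.
#' Cells whose Mahalanobis distance from both components exceeds
#' `dist_threshold` are labelled unclassified. The component with the
#' lower mean log rate is labelled excitatory.
#'
#' @param fit_features list of `waveform_features` used for fitting.
#' @param all_features list of `waveform_features` to classify.
#' @param dist_threshold Mahalanobis distance cutoff.
#' @return data.frame: `class` ("excitatory", "inhibitory",
#'   "unclassified"), `dist_e`, `dist_i` (Mahalanobis distances),
#'   `excluded` (too few spikes).
#' @export
classify_ei_gmm <- function(fit_features, all_features = fit_features,
                            dist_threshold = 3) {
  Xf <- features_matrix(fit_features)
  X <- features_matrix(all_features)
  gm <- Mclust(Xf, G = 2, modelNames = "VVV", verbose = FALSE)
  if (is.null(gm)) {
    # small or degenerate fit sets: fall back to simpler covariances
    gm <- Mclust(Xf, G = 2, modelNames = c("VVI", "EEI", "EII"),
                 verbose = FALSE)
    if (is.null(gm)) stop("too few cells to fit the Gaussian mixture")
    warning("full-covariance GMM was degenerate; simpler model used")
  }
  mu <- gm$parameters$mean           # 4 x 2
  sig <- gm$parameters$variance$sigma # 4 x 4 x 2
  e_comp <- which.min(mu["log_rate", ])
  i_comp <- setdiff(1:2, e_comp)
  maha <- function(X, m, S) {
    Sr <- S + diag(1e-9, nrow(S))
    d <- sweep(X, 2, m)
    sqrt(rowSums((d %*% solve(Sr)) * d))
  }
  d_e <- maha(X, mu[, e_comp], sig[, , e_comp])
  d_i <- maha(X, mu[, i_comp], sig[, , i_comp])
  cls <- ifelse(pmin(d_e, d_i) > dist_threshold, "unclassified",
                ifelse(d_e <= d_i, "excitatory", "inhibitory"))
  data.frame(class = cls, dist_e = d_e, dist_i = d_i,
             excluded = vapply(all_features, `[[`, TRUE, "excluded"))
}

#' Instantaneous phase of the saccade response at the late latency
#'
#' Mean-subtracts the saccade-aligned mean firing rate over the analysis
#' window, computes the analytic signal (Hilbert transform via FFT) and
#' returns its instantaneous phase at `at` seconds after peak saccade
#' velocity.
#'
#' @param psth a `psth` aligned to peak saccade velocity.
#' @param at phase readout time, s (0.187).
#' @return phase in (-pi, pi], or flagged `NA` for a constant rate.
#' @export
interneuron_phase <- function(psth, at = 0.187) {
  x <- psth$rate - mean(psth$rate)
  if (all(abs(x) < 1e-12)) {
    out <- NA_real_
    attr(out, "constant") <- TRUE
    return(out)
  }
  a <- analytic_signal(x)
  i <- which.min(abs(psth$t - at))
  Arg(a[i])
}

# analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Circular k-means clustering of response phases
#'
#' Lloyd iterations on the circle: assignment by maximal `cos(theta -
#' center)`, centers re-estimated as circular means; the objective
#' `sum(1 - cos(theta - center))` never increases. Best of `restarts`
#' random initializations is kept. A stability score (mean agreement of
#' cluster partitions across restarts, adjusted for label swaps) flags
#' degenerate phase distributions.
#'
#' @param phases angles, radians.
#' @param k number of clusters.
#' @param restarts random restarts.
#' @param max_iter per-restart iteration cap.
#' @return list with `cluster` (assignments), `centers` (radians),
#'   `objective`, `stability`.
#' @export
circular_kmeans <- function(phases, k = 2, restarts = 10, max_iter = 100) {
  n <- length(phases)
  if (k > n) stop("more clusters than observations")
  circ_mean <- function(th) atan2(mean(sin(th)), mean(cos(th)))
  one_run <- function() {
    centers <- phases[sample(n, k)]
    assign <- rep(1L, n)
    for (it in seq_len(max_iter)) {
      d <- outer(phases, centers, function(a, b) 1 - cos(a - b))
      new_assign <- max.col(-d)
      # re-seed any empty cluster at the worst-fit point
      for (c in seq_len(k)) {
        if (!any(new_assign == c)) {
          worst <- which.max(d[cbind(seq_len(n), new_assign)])
          centers[c] <- phases[worst]
          new_assign[worst] <- c
        }
      }
      if (all(new_assign == assign) && it > 1) break
      assign <- new_assign
      for (c in seq_len(k)) centers[c] <- circ_mean(phases[assign == c])
    }
    obj <- sum(1 - cos(phases - centers[assign]))
    list(cluster = assign, centers = centers, objective = obj)
  }
  runs <- lapply(seq_len(restarts), function(i) one_run())
  objs <- vapply(runs, `[[`, 0, "objective")
  best <- runs[[which.min(objs)]]
  agree <- vapply(runs, function(r) {
    a <- mean(r$cluster == best$cluster)
    max(a, 1 - a)
  }, 0)
  best$stability <- mean(agree)
  best
}

#' Classify interneurons into peak and trough subtypes
#'
#' Computes each interneuron's saccade-aligned phase at the late latency,
#' clusters the phases with circular k-means (k = 2), and labels the
#' cluster whose mean response at the late latency is higher as "peak".
#'
#' @param psths list of saccade-aligned `psth` objects (interneurons).
#' @param at readout latency, s.
#' @return data.frame with `phase`, `subtype` ("peak"/"trough"),
#'   `cluster`; attribute `centers` holds the cluster centers.
#' @export
interneuron_subtypes <- function(psths, at = 0.187) {
  phases <- vapply(psths, interneuron_phase, 0, at = at)
  km <- circular_kmeans(phases, k = 2)
  resp_at <- vapply(psths, function(p) {
    i <- which.min(abs(p$t - at))
    (p$rate[i] - mean(p$rate)) / max(1e-9, stats::sd(p$rate))
  }, 0)
  m1 <- mean(resp_at[km$cluster == 1])
  m2 <- mean(resp_at[km$cluster == 2])
  peak_cluster <- if (m1 >= m2) 1L else 2L
  out <- data.frame(phase = phases,
                    subtype = ifelse(km$cluster == peak_cluster, "peak",
                                     "trough"),
                    cluster = km$cluster)
  attr(out, "centers") <- km$centers
  attr(out, "stability") <- km$stability
  out
}
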