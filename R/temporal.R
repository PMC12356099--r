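#' Event-aligned firing rate (PSTH)
#'
#' Spikes are binned at the behavioral acquisition resolution (3.33 ms
#' bins by default) around each event, averaged across events, converted
#' to Hz and smoothed with a Gaussian kernel (sd `sigma`, truncated at
#' +/-4 sd and renormalized at the window edges so that total area is
#' preserved). The SEM is computed across events from the smoothed
#' per-event traces.
#'
#' @param spike_times sorted spike times.
#' @param event_times alignment times, s.
#' @param window time window around each event, s.
#' @param bin bin width, s (default 1/300).
#' @param sigma Gaussian smoothing sd, s (0.030 for gaze, 0.100 for dash
#'   responses); 0 disables smoothing.
#' @return list of class `psth`: `t` (bin centers relative to event),
#'   `rate`, `sem` (Hz), `raw` (unsmoothed mean rate), `n_events`, `bin`,
#'   `sigma`.
#' @export
event_aligned_rate <- function(spike_times, event_times,
                               window = c(-0.5, 0.7), bin = 1 / 300,
                               sigma = 0.030) {
  if (length(event_times) == 0L) stop("at least one event is required")
  edges <- seq(window[1], window[2], by = bin)
  nb <- length(edges) - 1L
  M <- matrix(0, length(event_times), nb)
  for (e in seq_along(event_times)) {
    rel <- spike_times - event_times[e]
    rel <- rel[rel >= window[1] & rel < edges[nb + 1L]]
    if (length(rel))
      M[e, ] <- tabulate(findInterval(rel, edges), nbins = nb)
  }
  M <- M / bin
  raw <- colMeans(M)
  if (sigma > 0) M <- t(apply(M, 1, smooth_gauss, bin = bin, sigma = sigma))
  rate <- colMeans(M)
  sem <- apply(M, 2, stats::sd) / sqrt(nrow(M))
  structure(list(t = (edges[-1] + edges[-(nb + 1L)]) / 2, rate = rate,
                 sem = sem, raw = raw,
                 n_events = length(event_times), bin = bin, sigma = sigma),
            class = "psth")
}

# Gaussian smoothing with kernel truncated at 4 sigma; edges handled by
# renormalizing the kernel over in-window samples
smooth_gauss <- function(x, bin, sigma) {
  hw <- max(1L, ceiling(4 * sigma / bin))
  k <- stats::dnorm(seq(-hw, hw) * bin, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, hw), x, rep(0, hw))
  sm <- stats::filter(xp, k, sides = 2)[(hw + 1):(hw + n)]
  # renormalize near edges where the kernel was truncated
  wp <- c(rep(0, hw), rep(1, n), rep(0, hw))
  wn <- stats::filter(wp, k, sides = 2)[(hw + 1):(hw + n)]
  as.numeric(sm / wn)
}

#' Early and late response peaks
#'
#' Peak firing rate within +/- `half` s windows centered on the early
#' (17 ms) and late (187 ms) response latencies of the saccade-aligned
#' PSTH, and their difference (the population sort key).
#'
#' @param psth a `psth` aligned to peak saccade velocity.
#' @param early_center,late_center window centers, s.
#' @param half window half width, s.
#' @return list with `early_peak`, `late_peak` (Hz), `difference`.
#' @export
early_late_peaks <- function(psth, early_center = 0.017,
                             late_center = 0.187, half = 0.05) {
  need <- c(early_center - half, late_center + half)
  if (min(psth$t) > need[1] + 1e-9 || max(psth$t) < need[2] - 1e-9)
    stop("PSTH window does not cover the early/late response windows")
  pk <- function(center) {
    sel <- psth$t >= center - half & psth$t <= center + half
    max(psth$rate[sel])
  }
  e <- pk(early_center); l <- pk(late_center)
  list(early_peak = e, late_peak = l, difference = e - l)
}

#' Population early/late summary and sorting
#'
#' @param psths list of `psth` objects (one per cell).
#' @param ... passed to [early_late_peaks()].
#' @return data.frame with `early_peak`, `late_peak`, `difference` and
#'   `order` (row order sorted by decreasing difference, the display
#'   convention); attribute `normalized` holds the rate matrix with each
#'   row scaled 0 to its maximum.
#' @export
early_late_population <- function(psths, ...) {
  res <- do.call(rbind, lapply(psths, function(p)
    as.data.frame(early_late_peaks(p, ...))))
  res$order <- order(res$difference, decreasing = TRUE)
  M <- do.call(rbind, lapply(psths, function(p) {
    m <- max(p$rate)
    if (m > 0) p$rate / m else p$rate
  }))
  attr(res, "normalized") <- M
  res
}

#' Bivariate early-response matrix
#'
#' Mean early response as a function of the angular distances to the
#' preferred target of the gazes preceding and following each saccade,
#' in 10-degree bins, with marginals and the conditional slice where the
#' previous gaze was 30-40 degrees from the target.
#'
#' @param early per-saccade early-response rates.
#' @param prev_dist,next_dist per-saccade angular distances, degrees.
#' @param breaks bin edges, degrees.
#' @return list with `matrix` (prev-bin x next-bin means, empty bins NA),
#'   `n` (counts), `prev_marginal`, `next_marginal`, `conditional`
#'   (means by next-bin for prev in [30, 40)), `breaks`.
#' @export
bivariate_early_matrix <- function(early, prev_dist, next_dist,
                                   breaks = seq(0, 90, by = 10)) {
  stopifnot(length(early) == length(prev_dist),
            length(early) == length(next_dist))
  pb <- cut(prev_dist, breaks, right = FALSE)
  nb <- cut(next_dist, breaks, right = FALSE)
  ok <- !is.na(pb) & !is.na(nb) & is.finite(early)
  M <- tapply(early[ok], list(pb[ok], nb[ok]), mean)
  N <- table(pb[ok], nb[ok])
  cond_sel <- ok & prev_dist >= 30 & prev_dist < 40
  conditional <- tapply(early[cond_sel], nb[cond_sel], mean)
  list(matrix = M, n = N,
       prev_marginal = tapply(early[ok], pb[ok], mean),
       next_marginal = tapply(early[ok], nb[ok], mean),
       conditional = conditional, breaks = breaks)
}

#' Condition-split PSTHs
#'
#' Computes one PSTH per condition label, dropping (with a warning)
#' conditions with no events, and normalizing rates per cell to the peak
#' rate of a reference condition when given.
#'
#' @param spike_times sorted spike times.
#' @param event_times alignment times.
#' @param labels condition label per event.
#' @param reference optional reference condition name for normalization.
#' @param ... passed to [event_aligned_rate()].
#' @return named list of `psth` objects; when `reference` is given each
#'   has an extra `norm_rate` element (rate / reference peak).
#' @export
condition_psth <- function(spike_times, event_times, labels,
                           reference = NULL, ...) {
  stopifnot(length(event_times) == length(labels))
  out <- list()
  for (lv in unique(as.character(labels))) {
    ev <- event_times[labels == lv]
    if (length(ev) == 0L) {
      warning(sprintf("condition '%s' has no events; omitted", lv))
      next
    }
    out[[lv]] <- event_aligned_rate(spike_times, ev, ...)
  }
  if (!is.null(reference) && reference %in% names(out)) {
    ref_peak <- max(out[[reference]]$rate)
    if (ref_peak > 0)
      for (lv in names(out)) out[[lv]]$norm_rate <- out[[lv]]$rate / ref_peak
  }
  out
}

#' Linear model of the early response
#'
#' Fits per-saccade early-response rates on eight covariates - the
#' horizontal and vertical gaze deviations from the target before and
#' after the saccade and their squares - with a per-cell intercept
#' (fixed-effect dummies). Coefficient p-values are Bonferroni-adjusted
#' over the eight covariates.
#'
#' @param early per-saccade early rates (stacked across cells).
#' @param covariates data.frame or matrix with eight columns
#'   (h_prev, v_prev, h_prev2, v_prev2, h_next, v_next, h_next2,
#'   v_next2).
#' @param cell cell identifier per row.
#' @return data.frame with `term`, `estimate`, `se`, `p`, `p_adj`,
#'   `significant` for the eight covariates.
#' @export
early_response_model <- function(early, covariates, cell) {
  covariates <- as.data.frame(covariates)
  stopifnot(ncol(covariates) == 8, length(early) == nrow(covariates),
            length(cell) == length(early))
  if (length(unique(cell)) < 2) stop("at least two cells are required")
  d <- cbind(data.frame(early = early, cell = factor(cell)), covariates)
  fml <- stats::as.formula(paste("early ~ cell +",
                                 paste(colnames(covariates),
                                       collapse = " + ")))
  qrx <- qr(stats::model.matrix(fml, d))
  if (qrx$rank < ncol(stats::model.matrix(fml, d))) {
    mm <- stats::model.matrix(fml, d)
    bad <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) %in% colnames(covariates)
  out <- data.frame(term = rownames(sm)[keep],
                    estimate = sm[keep, 1], se = sm[keep, 2],
                    p = sm[keep, 4])
  out$p_adj <- pmin(1, out$p * 8)
  out$significant <- out$p_adj < 0.05
  rownames(out) <- NULL
  out
}
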